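#' Read a BED track of binary annotation intervals
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' internal 1-based inclusive convention on read, so a SNP at position `pos`
#' overlaps a BED record `(start, end)` iff `start < pos <= end`.
#'
#' @param path BED file (first three columns chrom, start, end; no header).
#' @return a `GRanges` of the intervals.
#' @export
read_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           select = 1:3, col.names = c("chrom", "start", "end"))
  GenomicRanges::GRanges(
    seqnames = norm_chrom(bed$chrom),
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end))
}

#' Read a quantitative score track
#'
#' Tab-delimited with header `chrom, start, end, score`; coordinates 1-based
#' inclusive (unlike BED). Scores must be non-negative.
#'
#' @param path file path.
#' @return a `GRanges` with a `score` metadata column.
#' @export
read_score_track <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(tab)))
  if (any(tab$score < 0)) stopf("track scores must be non-negative")
  gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(tab$chrom),
    ranges = IRanges::IRanges(start = tab$start, end = tab$end))
  gr$score <- tab$score
  gr
}

variants_to_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(variants$chrom, variants$id),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
}

#' Build an annotation matrix from track files
#'
#' A track is one of: a `GRanges` (binary: 1 if the SNP falls in any
#' interval), a `GRanges` with a `score` column (quantitative: the average
#' score over overlapping blocks — sum of scores divided by the number of
#' overlapping blocks — 0 when none overlap, the standard treatment of
#' per-block conservation scores), or a data.frame `(id, score)` of per-SNP
#' scores (absent ids scored 0).
#'
#' @param variants data.frame with `id`, `chrom`, `pos`.
#' @param tracks named list of tracks as above.
#' @param clump_groups optional named character vector mapping feature name
#'   to clump group.
#' @return an [annotation_matrix()] over the variants.
#' @export
build_annotation_matrix <- function(variants, tracks, clump_groups = NULL) {
  stopifnot(length(names(tracks)) == length(tracks), !is.null(names(tracks)))
  vgr <- variants_to_granges(variants)
  n <- nrow(variants)
  vals <- matrix(0, nrow = n, ncol = length(tracks),
                 dimnames = list(variants$id, names(tracks)))
  modes <- character(length(tracks))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    if (methods::is(tr, "GRanges")) {
      if ("score" %in% names(S4Vectors::mcols(tr))) {
        hits <- GenomicRanges::findOverlaps(vgr, tr)
        s <- tapply(tr$score[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
        vals[as.integer(names(s)), j] <- as.numeric(s)
        modes[j] <- "quantitative"
      } else {
        vals[, j] <- as.numeric(GenomicRanges::countOverlaps(vgr, tr) > 0)
        modes[j] <- "binary"
      }
    } else if (is.data.frame(tr)) {
      stopifnot(all(c("id", "score") %in% names(tr)))
      if (any(tr$score < 0)) stopf("per-SNP scores must be non-negative")
      m <- match(variants$id, tr$id)
      vals[!is.na(m), j] <- tr$score[m[!is.na(m)]]
      modes[j] <- "quantitative"
    } else stopf("unsupported track type for '%s'", names(tracks)[j])
  }
  cg <- rep(NA_character_, length(tracks))
  if (!is.null(clump_groups)) {
    m <- match(names(tracks), names(clump_groups))
    cg[!is.na(m)] <- clump_groups[m[!is.na(m)]]
  }
  annotation_matrix(vals, feature_defs(names(tracks), modes, cg))
}
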