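#' The MHC region on genome build 37
#'
#' chr6:29,624,809-33,160,245, conventionally excluded from annotation-driven
#' prioritization because of its atypical LD and gene density.
#'
#' @return a one-row region `data.frame` (chrom, start, end; 1-based inclusive).
#' @export
mhc_region <- function() {
  data.frame(chrom = "6", start = 29624809L, end = 33160245L,
             stringsAsFactors = FALSE)
}

#' Exclude variants in regions and on sex chromosomes
#'
#' Coordinates are 1-based and region bounds inclusive, so a variant at the
#' region start or end is removed.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based).
#' @param regions data.frame with `chrom`, `start`, `end` (1-based inclusive);
#'   may be `NULL` or empty.
#' @param drop_sex drop chromosomes X and Y.
#' @return the filtered variant data.frame.
#' @export
exclude_regions <- function(variants, regions = NULL, drop_sex = TRUE) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(variants)))
  if (any(variants$pos < 1)) stopf("positions must be >= 1")
  ch <- norm_chrom(variants$chrom, variants$id)
  keep <- rep(TRUE, nrow(variants))
  if (drop_sex) keep <- keep & !(ch %in% c("X", "Y"))
  if (!is.null(regions) && nrow(regions) > 0) {
    rch <- norm_chrom(regions$chrom)
    for (i in seq_len(nrow(regions))) {
      if (regions$start[i] > regions$end[i]) stopf("region start > end")
      keep <- keep & !(ch == rch[i] &
                         variants$pos >= regions$start[i] &
                         variants$pos <= regions$end[i])
    }
  }
  variants[keep, , drop = FALSE]
}

#' Select GWAS hits from a catalog at a significance tier
#'
#' Catalog SNPs absent from the variant universe are dropped; duplicate
#' catalog entries for one SNP keep their minimum reported p-value (the most
#' significant report governs the tier). Rows with malformed p-values
#' (non-numeric, outside (0, 1]) are rejected with a warning giving the count.
#'
#' @param catalog data.frame with columns `id`, `p_value` and optionally
#'   `phenotype`.
#' @param universe variant ids (or a table with an `id` column).
#' @param tier `"weak"` keeps p < 1e-5, `"strong"` keeps p < 5e-8.
#' @param phenotype restrict to one phenotype label, or `"all"`.
#' @return character vector of hit ids (unique, in universe order of first
#'   appearance in the catalog).
#' @export
label_hits <- function(catalog, universe, tier = c("weak", "strong"),
                       phenotype = "all") {
  tier <- match.arg(tier)
  stopifnot(all(c("id", "p_value") %in% names(catalog)))
  universe <- as_id_vector(universe)
  p <- suppressWarnings(as.numeric(catalog$p_value))
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad)) {
    warnf("dropping %d catalog rows with malformed p-values", sum(bad))
    catalog <- catalog[!bad, , drop = FALSE]
    p <- p[!bad]
  }
  if (phenotype != "all") {
    if (!"phenotype" %in% names(catalog))
      stopf("catalog has no phenotype column")
    keep <- catalog$phenotype == phenotype
    catalog <- catalog[keep, , drop = FALSE]
    p <- p[keep]
  }
  # most significant report per SNP governs its tier
  pmin_by_id <- tapply(p, as.character(catalog$id), min)
  thr <- if (tier == "weak") 1e-5 else 5e-8
  ids <- names(pmin_by_id)[pmin_by_id < thr]
  ids[ids %in% universe]
}

#' Define GWAS non-hits
#'
#' Non-hits are universe variants that are neither hits nor in high LD
#' (r2 >= threshold, inclusive) with any hit.
#'
#' @param universe variant ids (or a table with an `id` column).
#' @param hits hit ids.
#' @param proxies a [proxy_map()] or `NULL`.
#' @param r2_threshold LD exclusion threshold (default 0.8).
#' @return character vector of non-hit ids.
#' @export
define_nonhits <- function(universe, hits, proxies = NULL, r2_threshold = 0.8) {
  universe <- as_id_vector(universe)
  hits <- as_id_vector(hits)
  ld <- ld_partners(proxies, hits, r2_threshold)
  setdiff(universe, union(hits, ld))
}

#' Propagate annotations across LD proxies
#'
#' Each index variant receives, per feature, the maximum value observed over
#' itself and all of its LD proxies — a proxy carrying an annotation makes
#' the index variant carry it too, since the association signal is shared
#' across the LD block. The output is restricted to the index variants.
#'
#' Proxy ids absent from the matrix are treated as all-zero rows (logged via
#' `message`). Propagation never decreases a value, and is idempotent when
#' proxies are satellite variants (off-array ids not themselves index rows),
#' the usual situation when proxies come from a sequencing reference panel.
#'
#' @param am an [annotation_matrix()] whose rows cover the index variants
#'   (and any proxies that are present).
#' @param proxies a [proxy_map()].
#' @param index_ids ids to propagate onto; defaults to all rows of `am`.
#' @return an `annot_matrix` with rows `index_ids`.
#' @export
propagate_annotations <- function(am, proxies, index_ids = NULL) {
  if (is.null(index_ids)) index_ids <- rownames(am$values)
  index_ids <- as_id_vector(index_ids)
  miss_idx <- setdiff(index_ids, rownames(am$values))
  if (length(miss_idx)) stopf("index id '%s' missing from matrix", miss_idx[1])

  if (is.null(proxies) || nrow(proxies$edges) == 0)
    return(subset_variants(am, index_ids))

  e <- proxies$edges[proxies$edges$id_a %in% index_ids]
  members <- data.table::rbindlist(list(
    data.table::data.table(index = index_ids, member = index_ids),
    data.table::data.table(index = e$id_a, member = e$id_b)))
  absent <- setdiff(unique(members$member), rownames(am$values))
  if (length(absent)) {
    message(sprintf("propagate_annotations: %d proxy ids absent from matrix, treated as all-zero",
                    length(absent)))
    members <- members[!members$member %in% absent]
  }
  vals <- am$values[members$member, , drop = FALSE]
  dt <- data.table::as.data.table(vals)
  dt[, `_index` := members$index]
  agg <- dt[, lapply(.SD, max), by = "_index"]
  out <- as.matrix(agg[, -1])
  rownames(out) <- agg$`_index`
  out <- out[index_ids, , drop = FALSE]
  colnames(out) <- colnames(am$values)
  annotation_matrix(out, am$features)
}

#' Collapse clumped features into summary indicators
#'
#' For each clump group in the feature table, emits a single binary column
#' equal to the per-variant maximum of the member columns ("any TFBS", "any
#' of the eQTL experiments", one indicator per histone mark across cell
#' types, ...). Ungrouped columns — including all quantitative ones — pass
#' through unchanged. Column order: first member's position for each group.
#'
#' @param am an [annotation_matrix()] whose features carry `clump_group`.
#' @return an `annot_matrix` with clumped columns.
#' @export
clump_features <- function(am) {
  f <- am$features
  bad <- !is.na(f$clump_group) & f$mode != "binary"
  if (any(bad))
    stopf("clump group '%s' contains quantitative feature '%s'",
          f$clump_group[bad][1], f$name[bad][1])
  groups <- unique(f$clump_group[!is.na(f$clump_group)])
  keep_first <- !duplicated(ifelse(is.na(f$clump_group), f$name, f$clump_group))
  ord <- which(keep_first)
  cols <- vector("list", length(ord))
  out_names <- character(length(ord))
  out_modes <- character(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    g <- f$clump_group[i]
    if (is.na(g)) {
      cols[[k]] <- am$values[, i]
      out_names[k] <- f$name[i]
      out_modes[k] <- f$mode[i]
    } else {
      member <- which(!is.na(f$clump_group) & f$clump_group == g)
      cols[[k]] <- as.numeric(
        apply(am$values[, member, drop = FALSE], 1, max))
      out_names[k] <- g
      out_modes[k] <- "binary"
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(am$values)
  colnames(out) <- out_names
  annotation_matrix(out, feature_defs(out_names, out_modes))
}
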