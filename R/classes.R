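#' Feature definition table
#'
#' Describes the columns of an [annotation_matrix()]: the feature name, its
#' mode (`"binary"` presence/absence or `"quantitative"` non-negative score,
#' e.g. a conservation score), and an optional clump group used by
#' [clump_features()] to collapse related binary features (for example, one
#' histone mark measured across many cell types) into a single indicator.
#'
#' @param name character vector of unique feature names.
#' @param mode `"binary"` or `"quantitative"`, recycled.
#' @param clump_group optional character vector; `NA` means the feature is
#'   never clumped. All members of one group must be binary.
#' @return a `data.frame` with columns `name`, `mode`, `clump_group`.
#' @export
feature_defs <- function(name, mode = "binary", clump_group = NA_character_) {
  name <- as.character(name)
  if (anyDuplicated(name)) stopf("duplicate feature names")
  mode <- rep_len(match.arg(mode, c("binary", "quantitative"), several.ok = TRUE),
                  length(name))
  clump_group <- rep_len(as.character(clump_group), length(name))
  bad <- !is.na(clump_group) & mode != "binary"
  if (any(bad))
    stopf("clump_group '%s' contains quantitative feature '%s'",
          clump_group[bad][1], name[bad][1])
  data.frame(name = name, mode = mode, clump_group = clump_group,
             stringsAsFactors = FALSE)
}

#' Variant-by-feature annotation matrix
#'
#' The central container: one row per variant, one column per functional
#' feature. Binary features are coded 0/1; quantitative features are
#' non-negative scores with 0 meaning "no annotation". There are no missing
#' cells by construction.
#'
#' @param values numeric matrix with variant ids as rownames and feature
#'   names as colnames.
#' @param features a [feature_defs()] table matching the columns; if omitted,
#'   all columns are taken as binary.
#' @return an object of class `annot_matrix`.
#' @export
annotation_matrix <- function(values, features = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stopf("values must have variant ids as rownames")
  if (is.null(features)) features <- feature_defs(colnames(values))
  if (!identical(colnames(values), features$name))
    stopf("colnames(values) must equal features$name")
  if (anyNA(values)) stopf("annotation matrix must have no missing cells")
  if (any(values < 0)) stopf("annotation values must be non-negative")
  bin <- features$mode == "binary"
  if (any(bin) && !all(values[, bin, drop = FALSE] %in% c(0, 1)))
    stopf("binary features must be coded 0/1")
  structure(list(values = values, features = features), class = "annot_matrix")
}

#' @export
print.annot_matrix <- function(x, ...) {
  cat(sprintf("annotation matrix: %d variants x %d features (%d binary, %d quantitative)\n",
              nrow(x$values), ncol(x$values),
              sum(x$features$mode == "binary"),
              sum(x$features$mode == "quantitative")))
  invisible(x)
}

#' @export
dim.annot_matrix <- function(x) dim(x$values)

#' Subset an annotation matrix by variant ids
#' @param am an `annot_matrix`.
#' @param ids variant ids to keep (must all be present).
#' @return an `annot_matrix` restricted to `ids`, in the given order.
#' @export
subset_variants <- function(am, ids) {
  ids <- as_id_vector(ids)
  miss <- setdiff(ids, rownames(am$values))
  if (length(miss)) stopf("%d ids missing from matrix (e.g. '%s')", length(miss), miss[1])
  annotation_matrix(am$values[ids, , drop = FALSE], am$features)
}

#' LD proxy map
#'
#' A symmetric r-squared relation between variants, thresholded at
#' `r2_threshold` (inclusive, r2 >= threshold). The self relation (r2 = 1)
#' is implicit and never stored. Built from a long table of pairs such as a
#' PLINK/VCFtools `.ld` file (see [read_ld_table()]).
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `r2`.
#' @param r2_threshold minimum r2 retained; pairs below it are dropped.
#' @return an object of class `proxy_map`.
#' @export
proxy_map <- function(pairs = NULL, r2_threshold = 0.8) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    edges <- data.table::data.table(id_a = character(), id_b = character(),
                                    r2 = numeric())
  } else {
    if (!all(c("id_a", "id_b", "r2") %in% names(pairs)))
      stopf("pairs must have columns id_a, id_b, r2")
    dt <- data.table::as.data.table(pairs)[, list(
      id_a = as.character(id_a), id_b = as.character(id_b), r2 = as.numeric(r2))]
    if (any(dt$r2 < 0 | dt$r2 > 1)) stopf("r2 must lie in [0, 1]")
    dt <- dt[r2 >= r2_threshold & id_a != id_b]
    # r2 is symmetric: store both directions, keep the max on duplicates
    edges <- data.table::rbindlist(list(
      dt, dt[, list(id_a = id_b, id_b = id_a, r2 = r2)]))
    edges <- edges[, list(r2 = max(r2)), by = c("id_a", "id_b")]
    data.table::setkeyv(edges, "id_a")
  }
  structure(list(edges = edges, r2_threshold = r2_threshold),
            class = "proxy_map")
}

#' @export
print.proxy_map <- function(x, ...) {
  cat(sprintf("proxy map: %d directed edges (r2 >= %g), %d index ids\n",
              nrow(x$edges), x$r2_threshold,
              length(unique(x$edges$id_a))))
  invisible(x)
}

#' Proxies of a set of variants
#'
#' @param pm a [proxy_map()].
#' @param ids index variant ids.
#' @param r2_threshold optional stricter threshold; defaults to the map's own.
#' @param include_self include the ids themselves (their implicit r2 = 1 self
#'   relation).
#' @return character vector of unique partner ids.
#' @export
ld_partners <- function(pm, ids, r2_threshold = NULL, include_self = FALSE) {
  ids <- as_id_vector(ids)
  if (is.null(pm) || nrow(pm$edges) == 0) {
    return(if (include_self) unique(ids) else character())
  }
  thr <- if (is.null(r2_threshold)) pm$r2_threshold else r2_threshold
  e <- pm$edges[pm$edges$id_a %in% ids & pm$edges$r2 >= thr]
  out <- unique(e$id_b)
  if (include_self) out <- unique(c(ids, out))
  out
}

#' Hit/non-hit labeling of a variant universe
#'
#' Partitions a variant universe into GWAS hits, non-hits, and LD-excluded
#' variants (non-hits are required not to be LD proxies, at the map's r2
#' threshold, of any hit).
#'
#' @param universe variant ids (or a variant table with an `id` column).
#' @param hits ids of GWAS hits; must be a subset of the universe.
#' @param proxies optional [proxy_map()] used to exclude LD partners of hits.
#' @param tier `"weak"` (p < 1e-5) or `"strong"` (p < 5e-8); descriptive.
#' @param phenotype phenotype label, `"all"` for the full catalog.
#' @param r2_threshold threshold for LD exclusion (default the map's own).
#' @return an object of class `hit_labeling` with `hit_ids`, `nonhit_ids`,
#'   `ld_excluded_ids`, `tier`, `phenotype`.
#' @export
hit_labeling <- function(universe, hits, proxies = NULL,
                         tier = c("weak", "strong"), phenotype = "all",
                         r2_threshold = NULL) {
  tier <- match.arg(tier)
  universe <- as_id_vector(universe)
  hits <- intersect(as_id_vector(hits), universe)
  ld <- setdiff(intersect(ld_partners(proxies, hits, r2_threshold), universe), hits)
  nonhits <- setdiff(universe, c(hits, ld))
  structure(list(hit_ids = hits, nonhit_ids = nonhits, ld_excluded_ids = ld,
                 tier = tier, phenotype = phenotype),
            class = "hit_labeling")
}

#' @export
print.hit_labeling <- function(x, ...) {
  cat(sprintf("hit labeling (%s tier, phenotype '%s'): %d hits, %d non-hits, %d LD-excluded\n",
              x$tier, x$phenotype, length(x$hit_ids), length(x$nonhit_ids),
              length(x$ld_excluded_ids)))
  invisible(x)
}
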