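#' Dichotomize a quantitative score vector
#'
#' Quantitative annotations (conservation scores) are summarized for
#' enrichment counting as presence of any score: 1 where value > 0, else 0.
#'
#' @param values non-negative numeric vector.
#' @return integer 0/1 vector.
#' @export
dichotomize_quantitative <- function(values) {
  if (any(values < 0)) stopf("quantitative values must be non-negative")
  out <- as.integer(values > 0)
  names(out) <- names(values)
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass rule: with margins fixed,
#' the p-value is the sum of hypergeometric probabilities of all tables at
#' least as extreme (probability no larger) than the observed one. A small
#' relative tolerance guards against ties lost to floating point, as in
#' `stats::fisher.test`.
#'
#' @param a,b,c,d cell counts: a = hits with feature, b = hits without,
#'   c = non-hits with, d = non-hits without. Alternatively `a` may be a
#'   2x2 matrix.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cell counts must be non-negative integers")
  m1 <- a + b; m2 <- c + d; k1 <- a + c; k2 <- b + d
  if (m1 == 0 || m2 == 0 || k1 == 0 || k2 == 0) {
    warnf("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  support <- max(0, k1 - m2):min(k1, m1)
  dens <- stats::dhyper(support, m1, m2, k1)
  p_obs <- stats::dhyper(a, m1, m2, k1)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = ad/bc. If any cell is zero, the Haldane-Anscombe correction adds 0.5
#' to every cell before both the OR and the interval. The CI is the Woolf
#' normal interval on the log odds ratio,
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams fisher_exact
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric: `odds_ratio`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(a, b = NULL, c = NULL, d = NULL, level = 0.95) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  stopifnot(level > 0, level < 1)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stopf("cell counts must be non-negative")
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(odds_ratio = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

#' Per-feature enrichment of annotations in hits vs non-hits
#'
#' For every feature (quantitative ones dichotomized as presence of a score
#' first), counts carriers among hits and non-hits, and reports class
#' frequencies, the two-sided Fisher exact p-value, and the odds ratio with
#' its Woolf confidence interval — the per-feature summary table of a
#' hits-vs-non-hits enrichment analysis.
#'
#' @param am an [annotation_matrix()] covering hits and non-hits.
#' @param labels a [hit_labeling()].
#' @param level confidence level for the OR interval.
#' @return data.frame with one row per feature, in input feature order:
#'   `feature, n_hits_with, n_nonhits_with, freq_hits, freq_nonhits, p_value,
#'   odds_ratio, ci_low, ci_high, flagged` (`flagged` marks features absent,
#'   or fixed, in the pooled data so the corrected OR is unstable).
#' @export
enrichment_table <- function(am, labels, level = 0.95) {
  hits <- labels$hit_ids; nonhits <- labels$nonhit_ids
  miss <- setdiff(c(hits, nonhits), rownames(am$values))
  if (length(miss)) stopf("matrix missing %d labeled variants", length(miss))
  n1 <- length(hits); n0 <- length(nonhits)
  res <- lapply(seq_len(ncol(am$values)), function(j) {
    x <- am$values[, j]
    if (am$features$mode[j] == "quantitative") x <- dichotomize_quantitative(x)
    a <- sum(x[hits]); c_ <- sum(x[nonhits])
    or <- odds_ratio_ci(a, n1 - a, c_, n0 - c_, level = level)
    data.frame(
      feature = am$features$name[j],
      n_hits_with = a, n_nonhits_with = c_,
      freq_hits = a / n1, freq_nonhits = c_ / n0,
      p_value = fisher_exact(a, n1 - a, c_, n0 - c_),
      odds_ratio = or[["odds_ratio"]],
      ci_low = or[["ci_low"]], ci_high = or[["ci_high"]],
      flagged = (a + c_) %in% c(0, n1 + n0),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise Pearson correlation of annotation features
#'
#' Symmetric with unit diagonal. Constant columns (zero variance) have no
#' defined correlation; their off-diagonal entries are set to 0 and the
#' column names recorded in the `constant_features` attribute.
#'
#' @param am an [annotation_matrix()] with at least two variants.
#' @return correlation matrix with attribute `constant_features`.
#' @export
feature_correlation <- function(am) {
  v <- am$values
  if (nrow(v) < 2) stopf("need at least two variants")
  sds <- apply(v, 2, stats::sd)
  const <- colnames(v)[sds == 0]
  cc <- suppressWarnings(stats::cor(v))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  attr(cc, "constant_features") <- const
  cc
}

#' Mean annotation score per variant
#'
#' The mean, over the given variants, of the per-variant count of carried
#' features (quantitative features counted as carried when score > 0) —
#' a single-number summary of how annotated a class of SNPs is.
#'
#' @param am an [annotation_matrix()].
#' @param ids variant ids (non-empty, all present in the matrix).
#' @return the mean per-variant feature count.
#' @export
mean_annotation_score <- function(am, ids) {
  ids <- as_id_vector(ids)
  if (length(ids) == 0) stopf("ids must be non-empty")
  sub <- subset_variants(am, ids)
  v <- sub$values
  quant <- sub$features$mode == "quantitative"
  for (j in which(quant)) v[, j] <- dichotomize_quantitative(v[, j])
  mean(rowSums(v))
}

#' Greedy LD pruning of a variant set
#'
#' Optional pre-filter for enrichment: walks variants in genomic order and
#' keeps each one unless it is in LD (r2 >= threshold) with an already kept
#' variant, so the retained set is mutually below the threshold.
#'
#' @param variants data.frame with `id`, `chrom`, `pos`.
#' @param proxies a [proxy_map()].
#' @param r2_threshold pruning threshold (default the map's own).
#' @return character vector of retained ids.
#' @export
prune_by_ld <- function(variants, proxies, r2_threshold = NULL) {
  ord <- order(norm_chrom(variants$chrom, variants$id), variants$pos)
  ids <- as.character(variants$id)[ord]
  if (is.null(proxies) || nrow(proxies$edges) == 0) return(ids)
  thr <- if (is.null(r2_threshold)) proxies$r2_threshold else r2_threshold
  excluded <- new.env(hash = TRUE, parent = emptyenv())
  kept <- character(0)
  for (id in ids) {
    if (!is.null(excluded[[id]])) next
    kept <- c(kept, id)
    for (p in ld_partners(proxies, id, thr)) excluded[[p]] <- TRUE
  }
  kept
}
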