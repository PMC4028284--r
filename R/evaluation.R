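#' ROC curve and AUC
#'
#' The AUC is the probability that a random hit outscores a random non-hit,
#' with ties counted half — the Mann-Whitney form, equal to the trapezoidal
#' area under the ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels aligned with `scores`; both classes must
#'   be present.
#' @return an object of class `roc_curve`: `thresholds` (descending unique
#'   scores), `sensitivity`, `specificity`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  structure(list(thresholds = thr, sensitivity = tp / n1,
                 specificity = 1 - fp / n0, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Positive predictive value at score thresholds
#'
#' Per threshold t, `PPV = #(hits with score > t) / #(variants with
#' score > t)`. A PPV is only reported when at least `min_positives` hits
#' are correctly identified above the threshold (default 11); otherwise the
#' row is marked insufficient and the PPV is `NA`, since a PPV estimated
#' from a handful of positives is unreliable.
#'
#' @param scores,labels as in [roc_auc()].
#' @param thresholds score cutoffs in (0, 1).
#' @param min_positives minimum hits above threshold for a reported PPV.
#' @return data.frame `threshold, n_above, n_hits_above, ppv, sufficient`.
#' @export
ppv_at_thresholds <- function(scores, labels,
                              thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              min_positives = 11) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  rows <- lapply(thresholds, function(t) {
    above <- scores > t
    n_above <- sum(above)
    n_hits <- sum(above & labels == 1)
    ok <- n_hits >= min_positives
    data.frame(threshold = t, n_above = n_above, n_hits_above = n_hits,
               ppv = if (ok) n_hits / n_above else NA_real_,
               sufficient = ok)
  })
  do.call(rbind, rows)
}

#' Per-class score histograms and summaries
#'
#' Counts of scores in equal-width bins on \[0, 1\], separately for hits and
#' non-hits, plus per-class mean, SD and median — the class-separation view
#' of a fitted model.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_bins number of equal-width bins (>= 2, default 20).
#' @return list with `breaks`, `counts` (matrix classes x bins) and
#'   `summary` (per-class mean, sd, median, n).
#' @export
score_histograms <- function(scores, labels, n_bins = 20) {
  stopifnot(n_bins >= 2)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scores, breaks, include.lowest = TRUE)
  counts <- rbind(nonhit = table(bin[labels == 0]),
                  hit = table(bin[labels == 1]))
  summ <- do.call(rbind, lapply(c(nonhit = 0, hit = 1), function(cl) {
    s <- scores[labels == cl]
    data.frame(mean = mean(s), sd = stats::sd(s), median = stats::median(s),
               n = length(s))
  }))
  list(breaks = breaks, counts = counts, summary = summ)
}

#' Stratified QQ statistics of p-values by prediction-score bin
#'
#' Bins variants by prediction score (default: quintiles) and, within each
#' bin, lays sorted observed -log10 p against the expected -log10 of
#' uniform order statistics at plotting position `(i - 0.5) / n`. A
#' genomic-inflation-style summary (median observed chi-square over median
#' expected) is reported per bin. An informative model shows the top score
#' bin lifting away from the identity line.
#'
#' @param p_values p-values in (0, 1\].
#' @param scores prediction scores aligned with `p_values`.
#' @param bin_edges explicit score bin edges; default `n_bins`
#'   equal-frequency (quantile) bins.
#' @param n_bins number of quantile bins when `bin_edges` is `NULL`.
#' @return object of class `stratified_qq`: a list of strata, each with
#'   `label`, `n`, `expected`, `observed` (both -log10, observed sorted
#'   descending), `lambda_gc`. Empty bins are omitted with a warning.
#' @export
stratified_qq <- function(p_values, scores, bin_edges = NULL, n_bins = 5) {
  stopifnot(length(p_values) == length(scores))
  if (any(p_values <= 0 | p_values > 1)) stopf("p-values must lie in (0, 1]")
  if (is.null(bin_edges))
    bin_edges <- unique(stats::quantile(scores, seq(0, 1, length.out = n_bins + 1)))
  if (length(bin_edges) < 2) bin_edges <- c(min(scores) - 1e-9, max(scores))
  bin <- cut(scores, bin_edges, include.lowest = TRUE)
  strata <- list()
  for (lev in levels(bin)) {
    pv <- p_values[!is.na(bin) & bin == lev]
    n <- length(pv)
    if (n == 0) {
      warnf("empty score bin %s omitted", lev)
      next
    }
    obs <- sort(-log10(pv), decreasing = TRUE)
    expd <- -log10((seq_len(n) - 0.5) / n)
    lambda_gc <- stats::median(stats::qchisq(pv, df = 1, lower.tail = FALSE)) /
      stats::qchisq(0.5, df = 1)
    strata[[lev]] <- list(label = lev, n = n, expected = expd,
                          observed = obs, lambda_gc = lambda_gc)
  }
  structure(strata, class = "stratified_qq")
}

#' @export
print.stratified_qq <- function(x, ...) {
  cat("stratified QQ:\n")
  for (s in x)
    cat(sprintf("  %s: n = %d, lambda_GC = %.3f, max -log10 p = %.2f\n",
                s$label, s$n, s$lambda_gc, max(s$observed)))
  invisible(x)
}
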