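#' Annotation Bayes factor from a prediction score
#'
#' With hits and non-hits weighted to equal mass, the fitted odds of hit
#' status are themselves the annotation Bayes factor:
#' `BF_annot = score / (1 - score)`.
#'
#' @param score probabilities strictly inside (0, 1).
#' @return positive numeric vector of Bayes factors.
#' @export
bf_annot_from_score <- function(score) {
  if (any(score <= 0 | score >= 1))
    stopf("scores must lie strictly in (0, 1); odds are infinite at 0 or 1")
  score / (1 - score)
}

#' Wakefield approximate Bayes factor from summary statistics
#'
#' The alternative-over-null Bayes factor under a Normal(0, W) prior on the
#' true effect and a Normal(beta_hat; theta, V) likelihood approximation:
#' `BF = sqrt(V / (V + W)) * exp(z^2 / 2 * W / (V + W))` with `z = beta / se`
#' and `V = se^2`. This equals the ratio of the Normal(0, V + W) to
#' Normal(0, V) densities at `beta_hat`. Larger BF means more evidence for
#' association (the reciprocal of Wakefield's null-over-alternative form).
#'
#' If `se` is missing, `z` is recovered from the two-sided p-value with the
#' sign of `beta` and `V = (beta / z)^2`.
#'
#' @param beta effect estimates.
#' @param se standard errors (> 0), or `NULL` to recover from `p`.
#' @param p two-sided p-values (only used when `se` is `NULL`).
#' @param prior_sd prior standard deviation of the effect (`W = prior_sd^2`);
#'   default 0.2.
#' @param log return the log Bayes factor.
#' @return numeric vector of Bayes factors (or their logs).
#' @export
wakefield_bf_assoc <- function(beta, se = NULL, p = NULL, prior_sd = 0.2,
                               log = FALSE) {
  if (prior_sd < 0) stopf("prior_sd must be >= 0")
  if (is.null(se)) {
    if (is.null(p)) stopf("provide either se or p")
    z <- sign(beta) * stats::qnorm(p / 2, lower.tail = FALSE)
    if (any(!is.finite(z) | z == 0))
      stopf("cannot recover z from p (p = 1 or beta = 0); supply se")
    se <- abs(beta / z)
  }
  if (any(se <= 0)) stopf("se must be > 0")
  z <- beta / se
  V <- se^2
  W <- prior_sd^2
  log_bf <- 0.5 * log(V / (V + W)) + z^2 / 2 * W / (V + W)
  if (log) log_bf else exp(log_bf)
}

#' Combine association and annotation evidence
#'
#' Under conditional independence of annotation and association data given
#' causality, `BF_combined = BF_assoc * BF_annot`; with a prior odds the
#' posterior odds are `o_prior * BF_combined`.
#'
#' @param bf_assoc,bf_annot positive Bayes factors (vectorized).
#' @param o_prior optional positive prior odds of causality.
#' @return list with `bf_combined` and `o_post` (`NULL` when no prior odds
#'   are given).
#' @export
combine_evidence <- function(bf_assoc, bf_annot, o_prior = NULL) {
  if (any(bf_assoc <= 0) || any(bf_annot <= 0))
    stopf("Bayes factors must be positive")
  bf <- bf_assoc * bf_annot
  list(bf_combined = bf,
       o_post = if (is.null(o_prior)) NULL else o_prior * bf)
}

#' Rank variants by Bayes factor
#'
#' Larger Bayes factors get smaller ranks (rank 1 = strongest evidence);
#' ties receive the average of their rank span.
#'
#' @param bf finite positive values.
#' @return numeric rank vector aligned with `bf`.
#' @export
rank_variants <- function(bf) {
  if (any(!is.finite(bf))) stopf("Bayes factors must be finite")
  rank(-bf, ties.method = "average")
}

#' Per-variant Bayes factor table from scores and summary statistics
#'
#' Joins prediction scores with GWAS summary statistics, computes
#' `BF_annot`, `BF_assoc`, their product, and the two rankings (by
#' association alone and by the combined Bayes factor).
#'
#' @param scores named numeric vector (or data.frame `id, score`).
#' @param sumstats data.frame with `id`, `beta`, and `se` and/or `p`.
#' @param prior_sd Wakefield prior SD, see [wakefield_bf_assoc()].
#' @return data.frame `id, score, bf_annot, bf_assoc, bf_combined,
#'   rank_assoc, rank_combined`.
#' @export
compute_bayes_factors <- function(scores, sumstats, prior_sd = 0.2) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$id)
  stopifnot(all(c("id", "beta") %in% names(sumstats)))
  ids <- intersect(names(scores), as.character(sumstats$id))
  if (length(ids) == 0) stopf("no shared ids between scores and sumstats")
  m <- match(ids, sumstats$id)
  se <- if ("se" %in% names(sumstats)) sumstats$se[m] else NULL
  p <- if ("p" %in% names(sumstats)) sumstats$p[m] else NULL
  bf_assoc <- wakefield_bf_assoc(sumstats$beta[m], se = se, p = p,
                                 prior_sd = prior_sd)
  bf_annot <- bf_annot_from_score(scores[ids])
  bf_comb <- combine_evidence(bf_assoc, bf_annot)$bf_combined
  data.frame(id = ids, score = unname(scores[ids]),
             bf_annot = unname(bf_annot), bf_assoc = bf_assoc,
             bf_combined = unname(bf_comb),
             rank_assoc = rank_variants(bf_assoc),
             rank_combined = rank_variants(unname(bf_comb)),
             stringsAsFactors = FALSE)
}

#' Rank improvement of a hit set after adding annotation evidence
#'
#' Compares ranks by `BF_assoc` alone against ranks by
#' `BF_assoc * BF_annot` for a set of variants of interest. A positive
#' `delta_rank_sum` means the combined ranking places the set better
#' (smaller rank sum).
#'
#' @param hit_ids ids of the variants of interest.
#' @param bf a [compute_bayes_factors()] table (columns `id`, `rank_assoc`,
#'   `rank_combined`).
#' @return list with `n_improved` (hits whose rank strictly improved) and
#'   `delta_rank_sum` (`sum rank_assoc - sum rank_combined` over the hits).
#' @export
rank_improvement <- function(hit_ids, bf) {
  hit_ids <- as_id_vector(hit_ids)
  m <- match(hit_ids, bf$id)
  if (anyNA(m)) stopf("hit id '%s' missing from Bayes factor table",
                      hit_ids[which(is.na(m))[1]])
  ra <- bf$rank_assoc[m]; rc <- bf$rank_combined[m]
  list(n_improved = sum(rc < ra), delta_rank_sum = sum(ra) - sum(rc))
}

#' Sample control sets matched to hits on p-value
#'
#' Draws `n_sets` negative-control sets of `set_size` variants each:
#' controls are never hits nor LD partners (r2 >= threshold) of any hit, and
#' each control's -log10 p lies within `tol` of its matched hit's. When a
#' hit has no match at the current tolerance, the tolerance is widened in
#' steps of `widen_by` (with a warning) up to `max_widen` times, then the
#' call fails. Controls are sampled without replacement within a set;
#' distinct sets are independent draws.
#'
#' @param hit_ids ids of the hits to match.
#' @param pool data.frame with `id` and `p` (candidate controls; hits and
#'   their LD partners are removed internally).
#' @param proxies a [proxy_map()] or `NULL`.
#' @param n_sets number of control sets (default 12).
#' @param set_size controls per set (default one per hit).
#' @param r2_threshold LD exclusion threshold (default the map's own).
#' @param tol initial |delta -log10 p| tolerance (default 0.25, i.e. the
#'   same half-decade).
#' @param widen_by,max_widen tolerance widening step (default a half-decade,
#'   0.5) and maximum number of widenings.
#' @param seed integer seed.
#' @return list of `n_sets` character vectors of control ids.
#' @export
sample_matched_controls <- function(hit_ids, pool, proxies = NULL,
                                    n_sets = 12, set_size = length(hit_ids),
                                    r2_threshold = NULL, tol = 0.25,
                                    widen_by = 0.5, max_widen = 8, seed = 1) {
  hit_ids <- as_id_vector(hit_ids)
  stopifnot(all(c("id", "p") %in% names(pool)))
  m <- match(hit_ids, pool$id)
  if (anyNA(m)) stopf("hit '%s' missing from pool", hit_ids[which(is.na(m))[1]])
  mlp_hits <- -log10(pool$p[m])
  banned <- union(hit_ids, ld_partners(proxies, hit_ids, r2_threshold))
  cand <- pool[!pool$id %in% banned, , drop = FALSE]
  mlp <- -log10(cand$p)
  targets <- rep_len(mlp_hits, set_size)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      chosen <- character(0)
      for (t in targets) {
        tol_t <- tol
        widened <- 0L
        repeat {
          ok <- which(abs(mlp - t) <= tol_t & !cand$id %in% chosen)
          if (length(ok)) break
          if (widened >= max_widen)
            stopf("no control matches -log10 p = %.3g even at tolerance %.3g",
                  t, tol_t)
          tol_t <- tol_t + widen_by
          widened <- widened + 1L
          warnf("widening p-value matching tolerance to %.3g for -log10 p = %.3g",
                tol_t, t)
        }
        chosen <- c(chosen, cand$id[ok[sample.int(length(ok), 1)]])
      }
      chosen
    })
  })
}
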