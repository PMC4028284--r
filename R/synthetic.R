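#' Configuration for the synthetic GWAS universe
#'
#' The defaults state a desk-scale world shaped like the real clumped
#' analysis: 14 features whose background frequencies are the published
#' non-hit frequencies of the clumped annotation set; two quantitative
#' conservation-like scores forming one highly correlated latent block
#' (rho = 0.8); a regulatory block (three histone marks plus TFBS,
#' rho = 0.6); a true logistic model whose largest coefficient sits on the
#' nonsynonymous-like feature (~1.0) with several mid-size effects
#' (0.2-0.4) and the rare features null; a 5% hit fraction; association
#' summary statistics at an effective sample size giving se = 0.01 with hit
#' effects of SD 0.05 (typical genome-wide-significant territory); and LD
#' proxies (mean 2 per variant, r2 uniform on \[0.8, 1\]) as satellite
#' reference-panel ids.
#'
#' @param n_variants number of variants.
#' @param feature_freqs named marginal carrier frequencies in (0, 1).
#' @param quantitative names of features emitted as truncated-Gaussian
#'   non-negative scores instead of 0/1.
#' @param correlation_blocks list of `list(features =, rho =)` with
#'   rho in \[0, 1): within-block latent (tetrachoric) correlation.
#' @param true_coefficients named true logistic coefficients.
#' @param true_intercept intercept, or `NULL` to solve it numerically so the
#'   expected hit fraction equals `hit_fraction_target`.
#' @param hit_fraction_target target hit fraction in (0, 0.5).
#' @param effect_sd_hits SD of true association effects at hits.
#' @param n_eff effective sample size; summary-statistic se = 1/sqrt(n_eff).
#' @param proxies_per_variant mean number of LD proxies (Poisson).
#' @param r2_range proxy r2 range, within \[0.8, 1\].
#' @param seed integer seed recorded in the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(
    n_variants = 30000,
    feature_freqs = c(splice = 0.002, nonsyn = 0.007, dnase = 0.141,
                      eqtl_gtex = 0.007, eqtl_brain = 0.081,
                      ucsc_gene = 0.357, phylop = 0.172, phastcons = 0.202,
                      h3k4me1 = 0.566, h3k4me3 = 0.434, h3k27ac = 0.503,
                      tfbs = 0.456, mirna = 7e-5, tss = 0.002),
    quantitative = c("phylop", "phastcons"),
    correlation_blocks = list(
      list(features = c("phylop", "phastcons"), rho = 0.8),
      list(features = c("h3k4me1", "h3k4me3", "h3k27ac", "tfbs"), rho = 0.6)),
    true_coefficients = c(splice = 0, nonsyn = 1.0, dnase = 0.3,
                          eqtl_gtex = 0.4, eqtl_brain = 0.3,
                          ucsc_gene = 0.25, phylop = 0.3, phastcons = 0.2,
                          h3k4me1 = 0.25, h3k4me3 = 0.2, h3k27ac = 0.3,
                          tfbs = 0.2, mirna = 0, tss = 0),
    true_intercept = NULL,
    hit_fraction_target = 0.05,
    effect_sd_hits = 0.05,
    n_eff = 10000,
    proxies_per_variant = 2,
    r2_range = c(0.8, 1),
    seed = 1) {
  stopifnot(n_variants >= 2,
            all(feature_freqs > 0 & feature_freqs < 1),
            !is.null(names(feature_freqs)),
            all(quantitative %in% names(feature_freqs)),
            all(names(true_coefficients) %in% names(feature_freqs)),
            hit_fraction_target > 0, hit_fraction_target < 0.5,
            effect_sd_hits >= 0, n_eff >= 1, proxies_per_variant >= 0,
            r2_range[1] >= 0.8, r2_range[2] <= 1, r2_range[1] <= r2_range[2])
  for (b in correlation_blocks) {
    if (!all(b$features %in% names(feature_freqs)))
      stopf("correlation block names unknown feature '%s'",
            setdiff(b$features, names(feature_freqs))[1])
    if (b$rho < 0 || b$rho >= 1)
      stopf("block correlation rho must lie in [0, 1)")
  }
  structure(list(n_variants = n_variants, feature_freqs = feature_freqs,
                 quantitative = quantitative,
                 correlation_blocks = correlation_blocks,
                 true_coefficients = true_coefficients,
                 true_intercept = true_intercept,
                 hit_fraction_target = hit_fraction_target,
                 effect_sd_hits = effect_sd_hits, n_eff = n_eff,
                 proxies_per_variant = proxies_per_variant,
                 r2_range = r2_range, seed = seed),
            class = "sim_config")
}

#' Simulate a correlated annotation matrix with known hit labels
#'
#' Binary features come from thresholding a latent Gaussian with the
#' configured block structure (`L_j = sqrt(rho) U_block + sqrt(1 - rho)
#' eps_j`) at the quantile matching each marginal frequency, which gives
#' tetrachoric within-block correlation `rho`. Quantitative features are
#' the positive part of the centered latent (`max(L - threshold, 0)`), so
#' their carrier frequency is the configured one. Hit labels are Bernoulli
#' draws from `logistic(intercept + x' beta)` on the emitted feature values;
#' when the intercept is unset it is solved numerically so the mean hit
#' probability equals the target fraction.
#'
#' @param cfg a [sim_config()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return list: `matrix` (an [annotation_matrix()]), `truth` (data.frame
#'   `id, prob, label`), `intercept` (the intercept used), `variants`
#'   (data.frame `id, chrom, pos` with synthetic placeholder coordinates).
#' @export
simulate_annotations <- function(cfg, seed = cfg$seed) {
  n <- cfg$n_variants
  feats <- names(cfg$feature_freqs)
  with_seed(seed, {
    lat <- matrix(stats::rnorm(n * length(feats)), nrow = n,
                  dimnames = list(NULL, feats))
    for (b in cfg$correlation_blocks) {
      u <- stats::rnorm(n)
      for (f in b$features)
        lat[, f] <- sqrt(b$rho) * u + sqrt(1 - b$rho) * lat[, f]
    }
    thr <- stats::qnorm(1 - cfg$feature_freqs)
    x <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
    for (j in seq_along(feats)) {
      f <- feats[j]
      x[, j] <- if (f %in% cfg$quantitative) pmax(lat[, f] - thr[f], 0)
      else as.numeric(lat[, f] > thr[f])
    }
    beta <- stats::setNames(numeric(length(feats)), feats)
    beta[names(cfg$true_coefficients)] <- cfg$true_coefficients
    eta <- drop(x %*% beta)
    b0 <- cfg$true_intercept
    if (is.null(b0)) {
      b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                             cfg$hit_fraction_target,
                           lower = -30, upper = 30, tol = 1e-10)$root
    }
    prob <- stats::plogis(b0 + eta)
    label <- stats::rbinom(n, 1, prob)
    ids <- sprintf("snp%06d", seq_len(n))
    rownames(x) <- ids
    modes <- ifelse(feats %in% cfg$quantitative, "quantitative", "binary")
    # placeholder coordinates: variants spread along the autosomes
    chrom <- as.character(rep_len(1:22, n))
    pos <- as.integer(seq_len(n) * 1000L)
    list(matrix = annotation_matrix(x, feature_defs(feats, modes)),
         truth = data.frame(id = ids, prob = prob, label = label,
                            stringsAsFactors = FALSE),
         intercept = b0,
         variants = data.frame(id = ids, chrom = chrom, pos = pos,
                               stringsAsFactors = FALSE))
  })
}

#' Simulate GWAS summary statistics for labeled variants
#'
#' Non-hits are null: `z ~ Normal(0, 1)`, `beta_hat = z * se` with
#' `se = 1 / sqrt(n_eff)`. Hits carry a true effect
#' `theta ~ Normal(0, effect_sd_hits^2)` and `beta_hat ~ Normal(theta,
#' se^2)`. Two-sided p-values from the normal tail.
#'
#' @param truth data.frame with `id` and binary `label` (1 = hit), as
#'   returned by [simulate_annotations()].
#' @param cfg a [sim_config()].
#' @param seed seed (defaults to `cfg$seed + 1`).
#' @return data.frame `id, beta, se, p`.
#' @export
simulate_gwas_summary <- function(truth, cfg, seed = cfg$seed + 1L) {
  n <- nrow(truth)
  se <- 1 / sqrt(cfg$n_eff)
  with_seed(seed, {
    theta <- ifelse(truth$label == 1,
                    stats::rnorm(n, 0, cfg$effect_sd_hits), 0)
    beta <- stats::rnorm(n, theta, se)
    z <- beta / se
    data.frame(id = truth$id, beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
}

#' Simulate an LD proxy map with satellite proxy ids
#'
#' Each variant receives a Poisson number of proxies with r2 uniform in the
#' configured range. Proxy ids are fresh satellite ids (`<id>_px<k>`),
#' emulating off-array reference-panel variants, so annotation propagation
#' over this map is idempotent. The map is symmetric.
#'
#' @param cfg a [sim_config()].
#' @param ids index variant ids.
#' @param seed seed (defaults to `cfg$seed + 2`).
#' @return a [proxy_map()].
#' @export
simulate_ld_proxies <- function(cfg, ids, seed = cfg$seed + 2L) {
  ids <- as_id_vector(ids)
  with_seed(seed, {
    k <- stats::rpois(length(ids), cfg$proxies_per_variant)
    if (sum(k) == 0) return(proxy_map(NULL, r2_threshold = cfg$r2_range[1]))
    idx <- rep(seq_along(ids), k)
    pairs <- data.frame(
      id_a = ids[idx],
      id_b = sprintf("%s_px%d", ids[idx],
                     unlist(lapply(k[k > 0], seq_len), use.names = FALSE)),
      r2 = stats::runif(sum(k), cfg$r2_range[1], cfg$r2_range[2]),
      stringsAsFactors = FALSE)
    proxy_map(pairs, r2_threshold = cfg$r2_range[1])
  })
}
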