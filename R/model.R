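#' Class weights balancing hits against non-hits
#'
#' Hits are weighted by `(N_hits + N_nonhits) / (2 * N_hits)` and non-hits
#' by `(N_hits + N_nonhits) / (2 * N_nonhits)`, so each class carries exactly
#' half the total weight: `w_hit * N_hits = w_nonhit * N_nonhits =
#' (N_hits + N_nonhits) / 2`. With this weighting the fitted odds of the
#' logistic model can be read directly as an annotation Bayes factor.
#'
#' @param n_hits,n_nonhits class counts, both >= 1.
#' @return an object of class `class_weights` (`w_hit`, `w_nonhit`,
#'   `n_hits`, `n_nonhits`).
#' @export
compute_class_weights <- function(n_hits, n_nonhits) {
  if (n_hits < 1 || n_nonhits < 1) stopf("both class counts must be >= 1")
  n <- n_hits + n_nonhits
  structure(list(w_hit = n / (2 * n_hits), w_nonhit = n / (2 * n_nonhits),
                 n_hits = n_hits, n_nonhits = n_nonhits),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("class weights: w_hit = %.6g (n = %d), w_nonhit = %.6g (n = %d)\n",
              x$w_hit, x$n_hits, x$w_nonhit, x$n_nonhits))
  invisible(x)
}

split_class <- function(ids, fractions, seed_done) {
  n <- length(ids)
  ids <- sample(ids)
  n_take <- round(cumsum(fractions) * n)
  out <- list()
  lo <- 0L
  for (k in seq_along(n_take)) {
    out[[k]] <- ids[(lo + 1L):n_take[k]]
    lo <- n_take[k]
  }
  out[[length(n_take) + 1L]] <- if (lo < n) ids[(lo + 1L):n] else character(0)
  out
}

#' Stratified train/test split of a labeled universe
#'
#' `simple_60_40`: 60% training, 40% test. `nested_70_30`: 70% development
#' split further into 60%/40% (42%/28% of the whole) for coefficient
#' training and hyperparameter tuning, with the remaining 30% held out for
#' testing. Splits are stratified by class and fully determined by the seed.
#'
#' @param labels a [hit_labeling()] (or list with `hit_ids`, `nonhit_ids`).
#' @param scheme `"simple_60_40"` or `"nested_70_30"`.
#' @param seed integer seed.
#' @param n_folds smallest class must have at least this many members
#'   (default 10), so cross-validation folds are feasible downstream.
#' @return an object of class `data_split` with `train_ids`, `test_ids`,
#'   and for the nested scheme `tune_ids`.
#' @export
split_data <- function(labels, scheme = c("simple_60_40", "nested_70_30"),
                       seed, n_folds = 10) {
  scheme <- match.arg(scheme)
  if (missing(seed)) stopf("seed must be given explicitly")
  classes <- list(hit = labels$hit_ids, nonhit = labels$nonhit_ids)
  if (any(lengths(classes) < n_folds))
    stopf("each class needs at least %d members", n_folds)
  fr <- if (scheme == "simple_60_40") 0.6 else c(0.42, 0.28)
  parts <- with_seed(seed, lapply(classes, split_class, fractions = fr))
  take <- function(k) as.character(unlist(lapply(parts, `[[`, k), use.names = FALSE))
  out <- if (scheme == "simple_60_40") {
    list(train_ids = take(1), test_ids = take(2))
  } else {
    list(train_ids = take(1), tune_ids = take(2), test_ids = take(3))
  }
  structure(c(out, list(scheme = scheme, seed = seed)), class = "data_split")
}

# Stratified fold assignment: within each class, folds are dealt round-robin
# after a seeded shuffle.
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    foldid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    foldid
  })
}

resolve_xy <- function(am, labels) {
  ids <- c(labels$hit_ids, labels$nonhit_ids)
  x <- subset_variants(am, ids)$values
  y <- c(rep(1L, length(labels$hit_ids)), rep(0L, length(labels$nonhit_ids)))
  list(x = x, y = y, ids = ids)
}

#' Tune elastic-net hyperparameters by cross-validation
#'
#' Grid search over the L1 share `alpha`, with the penalty strength `lambda`
#' selected per alpha by k-fold cross-validation minimizing mean weighted
#' binomial deviance (glmnet's deviance measure). Folds are stratified by
#' class and seed-determined; grid points with non-finite deviance are
#' disqualified.
#'
#' @param x numeric feature matrix (or an [annotation_matrix()]).
#' @param y binary 0/1 labels.
#' @param weights a [compute_class_weights()] object, or `NULL` to compute
#'   from `y`.
#' @param alpha_grid alphas in \[0, 1\] (default 0, 0.1, ..., 1).
#' @param lambda_grid optional explicit lambda sequence; by default glmnet's
#'   own log-spaced 100-point path from lambda_max downward, per alpha.
#' @param n_folds folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param standardize standardize predictors inside glmnet (default TRUE).
#' @return list with `alpha`, `lambda`, `cv_deviance`, and the full
#'   `cv_path` table (alpha, lambda, cv_deviance).
#' @export
tune_hyperparameters <- function(x, y, weights = NULL,
                                 alpha_grid = seq(0, 1, by = 0.1),
                                 lambda_grid = NULL, n_folds = 10, seed = 1,
                                 standardize = TRUE) {
  if (inherits(x, "annot_matrix")) x <- x$values
  stopifnot(length(alpha_grid) >= 1)
  if (is.null(weights)) weights <- compute_class_weights(sum(y == 1), sum(y == 0))
  w <- ifelse(y == 1, weights$w_hit, weights$w_nonhit)
  foldid <- stratified_folds(y, n_folds, seed)
  fit_lambda <- lambda_grid
  if (!is.null(fit_lambda)) {
    fit_lambda <- sort(unique(fit_lambda), decreasing = TRUE)
    if (length(fit_lambda) == 1)  # glmnet needs a path; pad and select after
      fit_lambda <- c(fit_lambda * 10, fit_lambda)
  }
  path <- list()
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", weights = w,
                            foldid = foldid, alpha = a, lambda = fit_lambda,
                            type.measure = "deviance",
                            standardize = standardize)
    lam <- cv$lambda; dev <- cv$cvm
    if (!is.null(lambda_grid)) {
      keep <- lam %in% lambda_grid
      lam <- lam[keep]; dev <- dev[keep]
    }
    bad <- !is.finite(dev)
    if (any(bad)) {
      message(sprintf("tune_hyperparameters: %d grid points with non-finite deviance disqualified (alpha = %g)",
                      sum(bad), a))
      dev[bad] <- Inf
    }
    path[[length(path) + 1L]] <-
      data.frame(alpha = a, lambda = lam, cv_deviance = dev)
  }
  path <- do.call(rbind, path)
  best <- which.min(path$cv_deviance)
  list(alpha = path$alpha[best], lambda = path$lambda[best],
       cv_deviance = path$cv_deviance[best], cv_path = path)
}

#' Fit the class-weighted elastic-net logistic model
#'
#' Minimizes the weighted negative Bernoulli log-likelihood plus
#' `lambda * (alpha * sum |beta_j| + (1 - alpha)/2 * sum beta_j^2)` with an
#' unpenalized intercept (glmnet). When `standardize = TRUE` the penalty
#' acts on the standardized scale and coefficients are reported on the
#' original feature scale. Constant feature columns are excluded from the
#' fit (coefficient 0) and recorded in `constant_features`.
#'
#' @param x numeric matrix or [annotation_matrix()] of features.
#' @param y binary 0/1 labels.
#' @param alpha L1 share in \[0, 1\].
#' @param lambda penalty strength >= 0.
#' @param weights a [compute_class_weights()] object, or `NULL` to compute
#'   from `y`.
#' @param standardize standardize predictors before penalizing.
#' @param thresh coordinate-descent convergence threshold (default 1e-7).
#' @return an object of class `fit_result`: `intercept`, named
#'   `coefficients`, `alpha`, `lambda`, `weights`, `standardize`,
#'   `constant_features`.
#' @export
fit_elastic_net <- function(x, y, alpha, lambda, weights = NULL,
                            standardize = TRUE, thresh = 1e-7) {
  if (inherits(x, "annot_matrix")) x <- x$values
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0, all(y %in% c(0, 1)))
  if (any(!is.finite(x))) stopf("feature matrix must be finite")
  if (is.null(weights)) weights <- compute_class_weights(sum(y == 1), sum(y == 0))
  w <- ifelse(y == 1, weights$w_hit, weights$w_nonhit)
  padded <- ncol(x) == 1  # glmnet requires >= 2 columns
  if (padded) x <- cbind(x, `..pad` = 0)
  const <- which(apply(x, 2, function(col) length(unique(col)) == 1))
  const_names <- setdiff(colnames(x)[const], "..pad")
  if (length(const_names))
    message(sprintf("fit_elastic_net: %d constant feature(s) excluded: %s",
                    length(const_names), paste(const_names, collapse = ", ")))
  # Fit along a decreasing path ending at the requested lambda; warm starts
  # make the solution at the path end accurate even for lambda near 0.
  init <- glmnet::glmnet(x, y, family = "binomial", weights = w,
                         alpha = alpha, standardize = standardize,
                         exclude = const, nlambda = 5)
  lmax <- max(init$lambda)
  path <- if (lambda >= lmax) {
    c(lambda * 1.5, lambda)
  } else if (lambda > 0) {
    exp(seq(log(lmax), log(lambda), length.out = 100))
  } else {
    c(exp(seq(log(lmax), log(lmax * 1e-8), length.out = 99)), 0)
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", weights = w,
                        alpha = alpha, lambda = path,
                        standardize = standardize, thresh = thresh,
                        exclude = const, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit, s = lambda))
  beta <- cf[-1]
  names(beta) <- colnames(x)
  beta[const] <- 0
  if (padded) beta <- beta[names(beta) != "..pad"]
  structure(list(intercept = cf[1], coefficients = beta, alpha = alpha,
                 lambda = lambda, weights = weights,
                 standardize = standardize, thresh = thresh,
                 constant_features = const_names),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("elastic-net logistic fit: alpha = %g, lambda = %.4g, %d/%d non-zero coefficients, intercept = %.4g\n",
              x$alpha, x$lambda, nz, length(x$coefficients), x$intercept))
  invisible(x)
}

#' Predicted probability of hit status (the prediction score)
#'
#' `logistic(intercept + sum_j beta_j x_j)` per variant.
#'
#' @param fit a [fit_elastic_net()] result.
#' @param x numeric matrix or [annotation_matrix()]; must contain every
#'   feature of the fit (extra columns are ignored).
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, x) {
  if (inherits(x, "annot_matrix")) x <- x$values
  feats <- names(fit$coefficients)
  miss <- setdiff(feats, colnames(x))
  if (length(miss))
    stopf("matrix is missing model feature(s): %s", paste(miss, collapse = ", "))
  eta <- drop(x[, feats, drop = FALSE] %*% fit$coefficients) + fit$intercept
  stats::plogis(eta)
}

#' Train the full prioritization model on a labeled annotation matrix
#'
#' Orchestrates the standard procedure: stratified split, class weights on
#' the training portion, hyperparameter tuning by cross-validation on the
#' training portion (on the tuning portion for the nested scheme), a fit on
#' the training data for held-out evaluation, and — for Bayes-factor
#' calculation — a refit with the tuned `(alpha, lambda)` on the full
#' labeled data with weights recomputed on it.
#'
#' @param am an [annotation_matrix()] covering all labeled variants.
#' @param labels a [hit_labeling()].
#' @param scheme split scheme, see [split_data()].
#' @param alpha_grid,lambda_grid,n_folds passed to [tune_hyperparameters()].
#' @param seed integer seed controlling split and folds.
#' @param standardize passed through to the fits.
#' @return list with `fit_train`, `fit_full`, `split`, `tuned`,
#'   `test_scores` (predictions on the held-out test set) and `test_labels`.
#' @export
train_prioritizer <- function(am, labels, scheme = "simple_60_40",
                              alpha_grid = seq(0, 1, by = 0.25),
                              lambda_grid = NULL, n_folds = 10, seed = 1,
                              standardize = TRUE) {
  split <- split_data(labels, scheme, seed = seed, n_folds = n_folds)
  lab_of <- function(ids) {
    hit_labeling(ids, intersect(ids, labels$hit_ids),
                 tier = labels$tier, phenotype = labels$phenotype)
  }
  train <- resolve_xy(am, lab_of(split$train_ids))
  w_train <- compute_class_weights(sum(train$y == 1), sum(train$y == 0))
  tune_on <- if (is.null(split$tune_ids)) train else
    resolve_xy(am, lab_of(split$tune_ids))
  w_tune <- compute_class_weights(sum(tune_on$y == 1), sum(tune_on$y == 0))
  tuned <- tune_hyperparameters(tune_on$x, tune_on$y, w_tune,
                                alpha_grid = alpha_grid,
                                lambda_grid = lambda_grid,
                                n_folds = n_folds, seed = seed,
                                standardize = standardize)
  fit_train <- fit_elastic_net(train$x, train$y, tuned$alpha, tuned$lambda,
                               w_train, standardize = standardize)
  full <- resolve_xy(am, labels)
  w_full <- compute_class_weights(sum(full$y == 1), sum(full$y == 0))
  fit_full <- fit_elastic_net(full$x, full$y, tuned$alpha, tuned$lambda,
                              w_full, standardize = standardize)
  test <- resolve_xy(am, lab_of(split$test_ids))
  list(fit_train = fit_train, fit_full = fit_full, split = split,
       tuned = tuned,
       test_scores = predict_probability(fit_train, test$x),
       test_labels = stats::setNames(test$y, test$ids))
}
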