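test_that("compute_class_weights balances the classes exactly", {
  w <- compute_class_weights(100, 900)
  expect_equal(w$w_hit, 5.0)
  expect_equal(w$w_nonhit, 1000 / 1800)
  w2 <- compute_class_weights(37, 37)
  expect_equal(c(w2$w_hit, w2$w_nonhit), c(1, 1))
  # identities: equal class mass, total mass preserved
  set.seed(2)
  for (i in 1:20) {
    h <- sample(1:5000, 1); m <- sample(1:50000, 1)
    w <- compute_class_weights(h, m)
    expect_equal(w$w_hit * h, w$w_nonhit * m)
    expect_equal(w$w_hit * h, (h + m) / 2)
    expect_equal(w$w_hit * h + w$w_nonhit * m, h + m)
  }
  expect_error(compute_class_weights(0, 10), ">= 1")
})

test_that("split_data produces stratified, seed-determined splits of the right size", {
  ids <- sprintf("v%04d", 1:1000)
  lab <- hit_labeling(ids, ids[1:100])
  s <- split_data(lab, "simple_60_40", seed = 7)
  expect_equal(length(s$train_ids), 600, tolerance = 1)
  expect_equal(length(s$test_ids), 400, tolerance = 1)
  expect_length(intersect(s$train_ids, s$test_ids), 0)
  expect_setequal(c(s$train_ids, s$test_ids), ids)
  # stratification: class proportions preserved
  expect_equal(mean(s$train_ids %in% lab$hit_ids), 0.1, tolerance = 0.01)
  # determinism
  expect_identical(split_data(lab, "simple_60_40", seed = 7), s)
  expect_false(identical(split_data(lab, "simple_60_40", seed = 8)$train_ids,
                         s$train_ids))

  n <- split_data(lab, "nested_70_30", seed = 7)
  expect_equal(length(n$train_ids), 420, tolerance = 2)
  expect_equal(length(n$tune_ids), 280, tolerance = 2)
  expect_equal(length(n$test_ids), 300, tolerance = 2)
  expect_setequal(c(n$train_ids, n$tune_ids, n$test_ids), ids)

  tiny <- hit_labeling(ids[1:50], ids[1:5])
  expect_error(split_data(tiny, "simple_60_40", seed = 1), "at least 10")
  expect_error(split_data(lab, "simple_60_40"), "seed")
})

test_that("tune_hyperparameters returns a single-point grid unchanged and prefers
           strong penalty on noise, weak penalty on signal", {
  set.seed(1)
  n <- 300
  X <- matrix(rbinom(n * 6, 1, 0.3), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, 0.3)
  one <- tune_hyperparameters(X, y, alpha_grid = 0.5, lambda_grid = 0.03,
                              n_folds = 5, seed = 1)
  expect_equal(one$alpha, 0.5)
  expect_equal(one$lambda, 0.03)

  grid <- 10^seq(-4, 0.5, length.out = 12)
  picks <- t(sapply(1:10, function(s) {
    set.seed(s)
    Xs <- matrix(rbinom(400 * 6, 1, 0.3), 400, dimnames = list(NULL, paste0("f", 1:6)))
    y_noise <- rbinom(400, 1, 0.3)
    y_sig <- rbinom(400, 1, plogis(-1.5 + Xs %*% c(2, 1.5, -2, 1, 0, 0)))
    c(noise = tune_hyperparameters(Xs, y_noise, alpha_grid = 0.5,
                                   lambda_grid = grid, n_folds = 5, seed = s)$lambda,
      sig = tune_hyperparameters(Xs, y_sig, alpha_grid = 0.5,
                                 lambda_grid = grid, n_folds = 5, seed = s)$lambda)
  }))
  # pure noise: the null model (largest grid lambda) preferred in most replicates
  expect_gt(sum(picks[, "noise"] == max(grid)), 5)
  # planted signal: penalty backs off the grid maximum in most replicates
  expect_gt(sum(picks[, "sig"] < max(grid)), 5)
})

test_that("fit_elastic_net at lambda ~ 0 matches the Newton-Raphson weighted MLE", {
  for (s in c(7, 21)) {
    set.seed(s)
    n <- 400
    X <- matrix(rbinom(n * 5, 1, 0.3), n, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(n, 1, plogis(-1 + X %*% c(1, 0.5, -0.5, 0, 0.3)))
    w <- compute_class_weights(sum(y), sum(1 - y))
    fit <- fit_elastic_net(X, y, alpha = 0.5, lambda = 1e-8, weights = w,
                           thresh = 1e-12)
    mle <- oracle_weighted_mle(X, y, ifelse(y == 1, w$w_hit, w$w_nonhit))
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) - mle)), 1e-3)
  }
})

test_that("saturated penalty zeroes all coefficients with intercept at the weighted class mean", {
  set.seed(5)
  n <- 300
  X <- matrix(rbinom(n * 4, 1, 0.4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, plogis(-1 + X[, 1]))
  w <- compute_class_weights(sum(y), sum(1 - y))
  fit <- fit_elastic_net(X, y, alpha = 0.5, lambda = 1e6, weights = w)
  expect_equal(unname(fit$coefficients), rep(0, 4))
  wv <- ifelse(y == 1, w$w_hit, w$w_nonhit)
  expect_equal(fit$intercept, qlogis(sum(wv * y) / sum(wv)), tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)  # class weights balance exactly
})

test_that("lasso splits a duplicated feature's weight without changing the total", {
  set.seed(6)
  n <- 500
  x1 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * x1))
  Xs <- cbind(f1 = x1)
  Xd <- cbind(f1 = x1, f1b = x1)
  single <- fit_elastic_net(Xs, y, alpha = 1, lambda = 0.01)
  dup <- fit_elastic_net(Xd, y, alpha = 1, lambda = 0.01)
  expect_equal(sum(dup$coefficients), unname(single$coefficients["f1"]),
               tolerance = 0.02)
})

test_that("constant features are excluded; refits are row-order invariant; penalty path shrinks", {
  set.seed(13)
  n <- 400
  X <- cbind(matrix(rbinom(n * 4, 1, 0.3), n), const = rep(1, n))
  colnames(X) <- c(paste0("f", 1:4), "const")
  y <- rbinom(n, 1, plogis(-1 + X[, 1]))
  expect_message(fit <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0.01),
                 "constant")
  expect_equal(unname(fit$coefficients["const"]), 0)
  expect_equal(fit$constant_features, "const")

  perm <- sample(n)
  fit_p <- suppressMessages(fit_elastic_net(X[perm, ], y[perm], alpha = 0.5,
                                            lambda = 0.01))
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-6)

  # optimal penalized objective is non-decreasing in lambda; ||beta||_1 -> 0
  w <- compute_class_weights(sum(y), sum(1 - y))
  wv <- ifelse(y == 1, w$w_hit, w$w_nonhit)
  obj <- function(f, lam) {
    eta <- f$intercept + drop(X[, 1:4] %*% f$coefficients[1:4])
    nll <- -sum(wv * (y * eta - log1p(exp(eta)))) / n
    nll + lam * (0.5 * sum(abs(f$coefficients)) +
                   0.25 * sum(f$coefficients^2))
  }
  lams <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
  fits <- lapply(lams, function(l)
    suppressMessages(fit_elastic_net(X, y, alpha = 0.5, lambda = l,
                                     standardize = FALSE, thresh = 1e-10)))
  objs <- mapply(obj, fits, lams)
  expect_true(all(diff(objs) > -1e-8))
  l1 <- sapply(fits, function(f) sum(abs(f$coefficients)))
  expect_true(all(diff(l1) <= 1e-8))
  expect_equal(l1[length(l1)], 0)
})

test_that("predict_probability is the logistic of the linear predictor", {
  fit <- structure(list(intercept = 0,
                        coefficients = c(f1 = 0, f2 = 0),
                        alpha = 0.5, lambda = 1, standardize = TRUE),
                   class = "fit_result")
  X <- cbind(f1 = c(0, 1), f2 = c(1, 0))
  expect_equal(unname(predict_probability(fit, X)), c(0.5, 0.5))
  fit$intercept <- log(9)
  expect_equal(unname(predict_probability(fit, X * 0)), c(0.9, 0.9))
  # monotone in a positive-coefficient feature
  fit$coefficients <- c(f1 = 2, f2 = -1)
  lo <- predict_probability(fit, cbind(f1 = 0.2, f2 = 1))
  hi <- predict_probability(fit, cbind(f1 = 0.9, f2 = 1))
  expect_gt(hi, lo)
  expect_error(predict_probability(fit, cbind(f1 = 1)), "missing")
})

test_that("train_prioritizer wires split, tuning, and the full-data refit together", {
  cfg <- sim_config(n_variants = 1500, seed = 30)
  sim <- simulate_annotations(cfg)
  lab <- hit_labeling(sim$truth$id, sim$truth$id[sim$truth$label == 1])
  tr <- suppressMessages(train_prioritizer(sim$matrix, lab, alpha_grid = c(0, 1),
                                           n_folds = 5, seed = 3))
  expect_s3_class(tr$fit_train, "fit_result")
  expect_setequal(names(tr$test_scores), tr$split$test_ids)
  expect_true(all(tr$test_scores > 0 & tr$test_scores < 1))
  # full-data refit recomputes the weights on the full labeling
  expect_equal(tr$fit_full$weights$n_hits, length(lab$hit_ids))
  # nested scheme tunes on the tuning portion
  tr2 <- suppressMessages(train_prioritizer(sim$matrix, lab, scheme = "nested_70_30",
                                            alpha_grid = 0.5, n_folds = 5, seed = 3))
  expect_length(intersect(tr2$split$tune_ids, tr2$split$train_ids), 0)
})
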