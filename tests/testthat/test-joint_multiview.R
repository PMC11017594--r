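test_that("optimal scores are zero-sum and unit-norm for any class balance", {
  ys <- optimal_scores(c("a", "a", "b", "b"))
  expect_equal(ys, c(1, 1, -1, -1) * sqrt(2 / 8), tolerance = 1e-12)
  for (n1 in c(2, 3, 7, 12)) for (n2 in c(2, 5, 9)) {
    y <- rep(0:1, c(n1, n2))
    s <- optimal_scores(y)
    expect_equal(sum(s), 0, tolerance = 1e-12)
    expect_equal(sum(s^2), 1, tolerance = 1e-12)
  }
  expect_error(optimal_scores(rep(1, 5)), class = "degenerate_labels_error")
})

test_that("at alpha = 0 the joint fit decouples into per-view lasso solutions", {
  library(glmnet)
  set.seed(61)
  for (seed in 1:5) {
    pl <- make_planted_views(seed, n = 16, p = c(25, 20, 15), k = 3)
    Xs <- lapply(pl$views, std_mat)
    lmax <- mvconsensus:::jaca_lambda_max(Xs, pl$y, 0)
    lam <- 0.4 * lmax
    fit <- fit_jaca(Xs, pl$y, alpha = 0, lambda = lam, tol = 1e-12)
    ytil <- optimal_scores(pl$y)
    for (d in seq_along(Xs)) {
      lams <- exp(seq(log(lmax[d]), log(lam[d]), length.out = 60))
      g <- glmnet(Xs[[d]], ytil, family = "gaussian", alpha = 1, lambda = lams,
                  standardize = FALSE, intercept = FALSE, thresh = 1e-16,
                  maxit = 1e7)
      expect_lt(max(abs(unname(fit$w[[d]]) - as.numeric(g$beta[, ncol(g$beta)]))),
                1e-6)
    }
  }
})

test_that("the joint objective never increases and vanishes above lambda_max", {
  set.seed(71)
  for (seed in 1:20) {
    pl <- make_planted_views(seed, n = 14, p = c(12, 10), k = 2,
                             effect = runif(1, 0, 3))
    Xs <- lapply(pl$views, std_mat)
    alpha <- runif(1, 0, 0.9)
    lmax <- mvconsensus:::jaca_lambda_max(Xs, pl$y, alpha)
    fit <- fit_jaca(Xs, pl$y, alpha = alpha, lambda = runif(1, 0.1, 0.9) * lmax)
    expect_true(all(diff(fit$objective) <= 1e-8 * (abs(fit$objective[-length(fit$objective)]) + 1e-12)))
    # every view zeroed at its ceiling
    fit0 <- fit_jaca(Xs, pl$y, alpha = alpha, lambda = lmax * 1.0000001)
    expect_true(all(vapply(fit0$w, function(w) all(w == 0), logical(1))))
  }
})

test_that("two identical views with equal penalties get identical coefficients", {
  set.seed(81)
  pl <- make_planted_views(81, n = 16, p = c(20, 20), k = 3)
  X <- std_mat(pl$views$view1)
  Xs <- list(a = X, b = X)
  lmax <- mvconsensus:::jaca_lambda_max(Xs, pl$y, 0.5)
  fit <- fit_jaca(Xs, pl$y, alpha = 0.5, lambda = rep(0.3 * lmax[1], 2),
                  tol = 1e-12)
  expect_equal(unname(fit$w$a), unname(fit$w$b), tolerance = 1e-6)
  # identical matrices and coefficients give score correlation 1
  sc <- score_correlations(fit)
  expect_equal(sc$correlations$r, 1, tolerance = 1e-9)
})

test_that("degenerate configurations are rejected before any computation", {
  pl <- make_planted_views(1, n = 10, p = c(8, 6), k = 2)
  Xs <- lapply(pl$views, std_mat)
  expect_error(fit_jaca(Xs, pl$y, alpha = 1, lambda = c(1, 1)),
               class = "config_error")
  expect_error(fit_jaca(Xs[1], pl$y, alpha = 0.5, lambda = 1),
               class = "config_error")
  expect_error(fit_jaca(list(a = Xs[[1]], b = Xs[[2]][1:5, ]), pl$y,
                        alpha = 0.5, lambda = c(1, 1)),
               class = "alignment_error")
})

test_that("joint classification uses pooled scores with centroid midpoint", {
  set.seed(91)
  for (seed in 1:8) {
    pl <- make_planted_views(seed, n = 18, p = c(20, 15, 10), k = 4, effect = 4,
                             separable = TRUE)
    Xs <- lapply(pl$views, std_mat)
    lmax <- mvconsensus:::jaca_lambda_max(Xs, pl$y, 0.5)
    fit <- fit_jaca(Xs, pl$y, alpha = 0.5, lambda = 0.3 * lmax)
    expect_identical(as.numeric(jaca_classify(fit, Xs)), as.numeric(pl$y))
  }
  # all-zero fit predicts the majority class everywhere
  pl <- make_planted_views(3, n = 12, p = c(10, 8), k = 2)
  Xs <- lapply(pl$views, std_mat)
  lmax <- mvconsensus:::jaca_lambda_max(Xs, pl$y, 0.5)
  fit0 <- fit_jaca(Xs, pl$y, alpha = 0.5, lambda = 2 * lmax)
  expect_identical(unique(jaca_classify(fit0, Xs)), fit0$majority)
  expect_error(jaca_classify(fit0, lapply(Xs, function(X) X[, 1:3])),
               class = "alignment_error")
})

test_that("score correlations respond to sign flips and reject flat scores", {
  set.seed(101)
  pl <- make_planted_views(5, n = 16, p = c(15, 12), k = 3)
  Xs <- lapply(pl$views, std_mat)
  lmax <- mvconsensus:::jaca_lambda_max(Xs, pl$y, 0.5)
  fit <- fit_jaca(Xs, pl$y, alpha = 0.5, lambda = 0.3 * lmax)
  sc <- score_correlations(fit, Xs)
  flipped <- fit
  flipped$w$view1 <- -flipped$w$view1
  sc2 <- score_correlations(flipped, Xs)
  expect_equal(sc2$correlations$r, -sc$correlations$r, tolerance = 1e-12)
  # independent null views give weak score correlation on average
  rs <- numeric(20)
  for (seed in 1:20) {
    pl0 <- make_planted_views(seed + 400, n = 18, p = c(30, 30), k = 2, effect = 0, rho = 0)
    X0 <- lapply(pl0$views, std_mat)
    l0 <- mvconsensus:::jaca_lambda_max(X0, pl0$y, 0.5)
    f0 <- fit_jaca(X0, pl0$y, alpha = 0.5, lambda = 0.4 * l0)
    rs[seed] <- if (all(vapply(f0$w, function(w) any(w != 0), logical(1))))
      abs(score_correlations(f0, X0)$correlations$r) else NA
  }
  expect_lt(mean(rs, na.rm = TRUE), 0.9) # far from the planted-signal regime
  zero <- fit
  zero$scores$view1 <- rep(0, length(zero$scores$view1))
  expect_error(score_correlations(zero), class = "degenerate_score_error")
})

test_that("LOO penalty selection returns boundary fits and recovers planted signal", {
  pl <- make_planted_views(111, n = 18, p = c(25, 20, 15), k = 4, effect = 4,
                           separable = TRUE)
  # one-point grid keeps the ceiling penalty: the full-data fit is
  # all-zero (folds may fit non-empty models at the full-data ceiling)
  f1 <- jaca_loocv(pl$views, pl$y, alpha = 0.5, grid_size = 1)
  expect_true(all(vapply(f1$w, function(w) all(w == 0), logical(1))))
  expect_equal(f1$loocv_mcr, f1$cv$loo_miscl[1] / length(pl$y))
  expect_gte(f1$loocv_mcr, 0)
  expect_lte(f1$loocv_mcr, 1)
  # a strongly shared signal reaches zero held-out error at some penalty
  f <- jaca_loocv(pl$views, pl$y, alpha = 0.5, grid_size = 12)
  expect_identical(min(f$cv$loo_miscl), 0L)
  expect_equal(f$loocv_mcr, 0)
})
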