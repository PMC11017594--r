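test_that("discriminant inputs follow their closed-form construction", {
  # p = 1, groups (0,0) vs (1,1): within-variance 0, ridge fallback
  X <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "f1"))
  y <- c("a", "a", "b", "b")
  inp <- build_inputs(X, y)
  expect_equal(unname(inp$d), sqrt(4) / 4 * 1) # 0.5
  expect_equal(unname(inp$W[1, 1]), 1e-4) # pure ridge
  # identical group means give a zero contrast
  X2 <- matrix(rep(c(1, 2), 4), 4, 2, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(build_inputs(X2, y)$d), c(0, 0))
  # swapping the class labels flips d and leaves W unchanged
  set.seed(5)
  X3 <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y3 <- rep(0:1, each = 3)
  a <- build_inputs(X3, y3)
  b <- build_inputs(X3, 1 - y3)
  expect_equal(a$d, -b$d, tolerance = 1e-12)
  expect_equal(a$W, b$W, tolerance = 1e-12)
  expect_error(build_inputs(X3, c(0, 1, 1, 1, 1, 1)),
               class = "degenerate_labels_error")
})

test_that("the l1 discriminant matches soft-threshold closed forms", {
  inp <- structure(list(W = diag(2), d = c(0.8, 0.1),
                        group_means = rbind(c(0, 0), c(1, 1)),
                        n1 = 2L, n2 = 2L, gamma = 0, classes = c(0, 1),
                        feature_ids = c("a", "b")),
                   class = "discriminant_inputs")
  f <- fit_sparse_lda(inp, 0.5)
  expect_equal(unname(f$v), c(0.3, 0), tolerance = 1e-9)
  expect_identical(f$selected, "a")
  # lambda at or above max|d| gives the empty model exactly
  f0 <- fit_sparse_lda(inp, 0.8)
  expect_true(all(f0$v == 0))
  expect_length(f0$selected, 0)
  # homogeneity: scaling d and lambda scales the solution
  inp2 <- inp
  inp2$d <- 3 * inp$d
  f3 <- fit_sparse_lda(inp2, 3 * 0.5)
  expect_equal(unname(f3$v), 3 * c(0.3, 0), tolerance = 1e-8)
})

test_that("KKT conditions hold and the objective is monotone on random instances", {
  set.seed(303)
  for (i in 1:40) {
    p <- sample(2:20, 1)
    W <- random_spd(p)
    d <- rnorm(p)
    lambda <- runif(1, 0.05, 1) * max(abs(d))
    sol <- mvconsensus:::cd_quad_lasso(W, d, lambda, numeric(p),
                                       tol = 1e-12, max_sweeps = 10000L,
                                       trace = TRUE)
    expect_lte(kkt_violation(W, d, lambda, as.numeric(sol$v)), 1e-6)
    expect_true(all(diff(sol$objective) <= 1e-10))
  }
})

test_that("coordinate descent agrees with an independent quadratic-program oracle", {
  library(glmnet)
  set.seed(404)
  for (i in 1:12) {
    p <- sample(3:10, 1)
    W <- random_spd(p)
    d <- rnorm(p)
    lambda <- runif(1, 0.1, 0.8) * max(abs(d))
    sol <- mvconsensus:::cd_quad_lasso(W, d, lambda, numeric(p),
                                       tol = 1e-12, max_sweeps = 50000L)
    oracle <- glmnet_quad_oracle(W, d, lambda)
    expect_equal(as.numeric(sol$v), oracle, tolerance = 1e-6)
  }
})

test_that("the Gram-form solver agrees with the explicit quadratic solver", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    p <- sample(5:40, 1)
    X <- matrix(rnorm(n * p), n, p)
    ridge <- runif(1, 1e-4, 1e-2)
    A <- crossprod(X) / n + diag(ridge, p)
    b <- rnorm(p)
    lambda <- runif(1, 0.05, 0.5) * max(abs(b))
    s1 <- mvconsensus:::cd_quad_lasso(A, b, lambda, numeric(p),
                                      tol = 1e-12, max_sweeps = 50000L)
    s2 <- mvconsensus:::cd_gram_lasso(X, b, lambda, numeric(p),
                                      scale = 1, ridge = ridge,
                                      tol = 1e-12, max_sweeps = 50000L)
    expect_equal(as.numeric(s1$v), as.numeric(s2$v), tolerance = 1e-7)
  }
})

test_that("classification follows the midpoint rule and its conventions", {
  set.seed(21)
  for (seed in 1:10) {
    pl <- make_planted_views(seed, n = 18, p = c(20, 10), k = 3, effect = 3,
                             separable = TRUE)
    Xs <- std_mat(pl$views$view1)
    inp <- build_inputs(Xs, pl$y)
    f <- fit_sparse_lda(inp, 0.3 * max(abs(inp$d)))
    expect_identical(as.numeric(classify(f, Xs)), as.numeric(pl$y)) # separable
    # a sample sitting exactly on a group mean belongs to that group
    expect_identical(classify(f, inp$group_means[1, , drop = FALSE]),
                     f$classes[1])
    expect_identical(classify(f, inp$group_means[2, , drop = FALSE]),
                     f$classes[2])
  }
  # all-zero fit falls back to the majority (tie -> lower label)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(0:1, each = 5)
  inp <- build_inputs(std_mat(X), y)
  f0 <- fit_sparse_lda(inp, 2 * max(abs(inp$d)))
  expect_identical(unique(classify(f0, X)), 0L)
  expect_error(classify(f0, X[, 1:2]), class = "alignment_error")
})

test_that("the LOO penalty path has its boundary and separable behaviour", {
  set.seed(31)
  n <- 18
  y <- rep(0:1, each = 9)
  X <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, sprintf("f%02d", 1:40)))
  X[, 7] <- y * 8 + rnorm(n, sd = 0.05) # single separating feature
  path <- lambda_path_loocv(X, y, grid_size = 25)
  expect_identical(min(path$loo_mcr), 0) # separable case reaches zero
  expect_identical(path$n_selected[1], 0L) # empty at lambda_max
  expect_true(all(path$loo_mcr >= 0 & path$loo_mcr <= 1))
  # single-penalty path: empty full-data model; the LOO error is at
  # least the chance rate (balanced-data LOO majority prediction is
  # anti-correlated with the held-out label, so it can exceed 0.5)
  p1 <- lambda_path_loocv(X, y, grid_size = 1)
  expect_length(p1$lambda_grid, 1)
  expect_identical(p1$n_selected, 0L)
  expect_gte(p1$loo_mcr, 0.5)
  expect_lte(p1$loo_mcr, 1)
})

test_that("model selection policies break ties as documented", {
  fake_fit <- function(k) structure(list(v = setNames(rep(1, k), paste0("f", seq_len(max(k, 1))[seq_len(k)])),
                                         lambda = NA, selected = paste0("f", seq_len(k)),
                                         threshold = 0, orientation = 1,
                                         classes = 0:1, majority = 0,
                                         converged = TRUE, sweeps = 1L),
                                    class = "discriminant_fit")
  path <- structure(list(lambda_grid = c(0.8, 0.4, 0.2, 0.1),
                         n_selected = c(1L, 2L, 4L, 9L),
                         selected = lapply(c(1, 2, 4, 9), function(k) paste0("f", seq_len(k))),
                         loo_miscl = c(8L, 4L, 4L, 6L),
                         loo_mcr = c(0.4, 0.2, 0.2, 0.3),
                         fits = lapply(c(1, 2, 4, 9), fake_fit),
                         n = 20L),
                    class = "path_fit")
  # sparsest minimiser = larger penalty among the two tied at 0.2
  expect_identical(select_model(path)$lambda, path$fits[[2]]$lambda)
  expect_length(select_model(path, "min_mcr_sparsest")$selected, 2)
  expect_length(select_model(path, "min_mcr")$selected, 4)
  expect_length(select_model(path, "fixed_size", size = 1)$selected, 1)
  expect_length(select_model(path, "fixed_size", size = 5)$selected, 4)
  expect_equal(select_model(path, "fixed_size", size = 1)$loo_mcr, 0.4)
  # tie in |n_selected - size| goes to the larger penalty
  expect_length(select_model(path, "fixed_size", size = 3)$selected, 2)
})

test_that("correlated expansion finds duplicates and ignores independent noise", {
  set.seed(51)
  n <- 18
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, sprintf("f%02d", 1:30)))
  X[, 2] <- X[, 1] # exact duplicate of the anchor
  out <- correlated_expansion(X, "f01", threshold = 0.95)
  expect_true("f02" %in% names(out))
  expect_equal(unname(out["f02"]), 1)
  # independent noise features virtually never clear 0.95 at n = 18
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed + 1000)
    Z <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("g%02d", 1:20)))
    hits <- hits + length(correlated_expansion(Z, "g01", threshold = 0.95))
  }
  expect_lte(hits, 1)
  expect_length(correlated_expansion(X, "f01", threshold = 1.01), 0)
  Xz <- X
  Xz[, 1] <- 0
  expect_error(correlated_expansion(Xz, "f01"), class = "degenerate_feature_error")
  expect_error(correlated_expansion(X, "nope"), class = "unknown_feature_error")
})
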