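# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the MV oracle is a literal double loop
# over the estimator definition, the quadratic-program oracle goes
# through glmnet on a Cholesky-embedded design, and objectives/KKT are
# computed directly from their formulas.

# brute-force MV statistic: explicit loops, no vectorization
mv_oracle <- function(x, y) {
  n <- length(x)
  classes <- sort(unique(y))
  total <- 0
  for (j in seq_len(n)) {
    Fp <- sum(x <= x[j]) / n
    for (r in classes) {
      xr <- x[y == r]
      Fr <- sum(xr <= x[j]) / length(xr)
      total <- total + (length(xr) / n) * (Fr - Fp)^2
    }
  }
  total / n
}

# objective of the penalised quadratic the discriminant solver minimises
quad_objective <- function(W, d, lambda, v) {
  0.5 * drop(t(v) %*% W %*% v) - sum(d * v) + lambda * sum(abs(v))
}

# largest KKT violation of v for min 1/2 v'Wv - d'v + lambda |v|_1
kkt_violation <- function(W, d, lambda, v) {
  g <- drop(W %*% v) - d
  active <- v != 0
  viol_active <- if (any(active)) max(abs(g[active] + lambda * sign(v[active]))) else 0
  viol_zero <- if (any(!active)) max(pmax(abs(g[!active]) - lambda, 0)) else 0
  max(viol_active, viol_zero)
}

# random symmetric positive-definite matrix with O(1) entries
random_spd <- function(p) {
  M <- matrix(stats::rnorm(p * p), p, p)
  crossprod(M) / p + diag(0.5, p)
}

# glmnet as a generic quadratic-programming oracle: embed
# min 1/2 v'Av - b'v + lambda |v|_1 as a lasso via the Cholesky factor
# of A (X = sqrt(n) L', y s.t. X'y/n = b)
glmnet_quad_oracle <- function(A, b, lambda) {
  p <- length(b)
  L <- chol(A) # A = L'L with upper-triangular L
  X <- sqrt(p) * L
  yy <- sqrt(p) * drop(solve(t(L), b))
  lams <- exp(seq(log(max(abs(b)) + lambda), log(lambda), length.out = 30))
  fit <- glmnet::glmnet(X, yy, family = "gaussian", alpha = 1,
                        lambda = lams, standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14, maxit = 1e7)
  as.numeric(fit$beta[, ncol(fit$beta)])
}

# small labelled Gaussian multi-view problem with planted shared signal;
# separable = TRUE forces a latent margin of 1 between the groups
make_planted_views <- function(seed, n = 18, p = c(30, 25, 20), k = 4,
                               effect = 3, rho = 0.9, noise_sd = 0.2,
                               separable = FALSE) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  z <- stats::rnorm(n, effect * y, 1)
  if (separable)
    z[y == 1] <- z[y == 1] - min(z[y == 1]) + max(z[y == 0]) + 1
  views <- lapply(seq_along(p), function(d) {
    X <- matrix(stats::rnorm(n * p[d]), n,
                dimnames = list(NULL, sprintf("v%d_f%02d", d, seq_len(p[d]))))
    X[, seq_len(k)] <- rho * z +
      matrix(stats::rnorm(n * k, sd = noise_sd), n, k)
    X
  })
  names(views) <- paste0("view", seq_along(p))
  list(views = views, y = y, z = z,
       truth = lapply(seq_along(p), function(d) sprintf("v%d_f%02d", d, seq_len(k))))
}

std_mat <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sd[sd == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sd, "/")
}

# minimal feature_table from a matrix without dimnames
ft <- function(m, kind = "generic", samples = NULL, features = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- if (is.null(samples)) sprintf("s%02d", seq_len(nrow(m))) else samples
  if (is.null(colnames(m)))
    colnames(m) <- if (is.null(features)) sprintf("f%03d", seq_len(ncol(m))) else features
  feature_table(m, kind)
}
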