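# Binary sparse discriminant analysis: the discriminant direction v
# minimises (1/2) v' W v - d' v + lambda ||v||_1, where W is the
# (ridged) within-group covariance and d a scaled mean-difference
# vector. The l1 penalty selects features; when informative features are
# highly correlated only a representative enters, which is why the
# workflow later inspects high-correlation partners of the selection
# (correlated_expansion).

#' Build the quadratic inputs of the sparse discriminant
#'
#' \eqn{W = \frac{1}{n}\sum_g \sum_{i \in g}(x_i-\bar x_g)(x_i-\bar x_g)' + \gamma I}
#' with ridge \eqn{\gamma = 10^{-4}\,\mathrm{mean}(\mathrm{diag}\,W_0)}
#' (falling back to \eqn{10^{-4}} if the within-group scatter is exactly
#' zero, so W stays positive definite), and
#' \eqn{d = \frac{\sqrt{n_1 n_2}}{n}(\bar x_2 - \bar x_1)} with classes
#' in sorted label order.
#'
#' @param X Numeric matrix, samples in rows (standardized columns are
#'   expected by the downstream solver).
#' @param y Binary labels; each class needs at least 2 samples.
#' @return A `discriminant_inputs` list: `W`, `d`, `group_means`, `n1`,
#'   `n2`, `gamma`, `classes`, `feature_ids`.
#' @export
build_inputs <- function(X, y) {
  X <- as.matrix(X)
  lab <- canon_labels(y)
  n1 <- sum(lab$idx == 1L)
  n2 <- sum(lab$idx == 2L)
  if (min(n1, n2) < 2L)
    mvc_error("degenerate_labels_error", "each class needs at least 2 samples")
  n <- n1 + n2
  m1 <- colMeans(X[lab$idx == 1L, , drop = FALSE])
  m2 <- colMeans(X[lab$idx == 2L, , drop = FALSE])
  Xc <- X
  Xc[lab$idx == 1L, ] <- sweep(X[lab$idx == 1L, , drop = FALSE], 2L, m1, "-")
  Xc[lab$idx == 2L, ] <- sweep(X[lab$idx == 2L, , drop = FALSE], 2L, m2, "-")
  W <- crossprod(Xc) / n
  gamma <- 1e-4 * mean(diag(W))
  if (gamma <= 0) gamma <- 1e-4
  diag(W) <- diag(W) + gamma
  d <- sqrt(n1 * n2) / n * (m2 - m1)
  # Xc (group-centered data) is kept so the solver can run in O(np)
  # Gram form when p >> n; W is the explicit p x p quadratic.
  structure(list(W = W, d = d, group_means = rbind(m1, m2),
                 n1 = n1, n2 = n2, gamma = gamma,
                 classes = lab$classes,
                 feature_ids = colnames(X),
                 Xc = Xc),
            class = "discriminant_inputs")
}

#' Fit the l1-penalised discriminant at a fixed penalty
#'
#' Solves \eqn{\min_v \frac12 v'Wv - d'v + \lambda\|v\|_1} by cyclic
#' coordinate descent (soft-thresholding updates; convergence when the
#' largest coordinate change in a sweep falls below 1e-9, at most 1e4
#' sweeps — non-convergence is recorded on the fit, not raised).
#'
#' @param inputs A [build_inputs()] result.
#' @param lambda Positive penalty weight; at
#'   \eqn{\lambda \ge \max_j |d_j|} the solution is exactly zero.
#' @param v_init Optional warm-start coefficient vector.
#' @return A `discriminant_fit`: coefficients `v`, `lambda`, `selected`
#'   ids, decision `threshold` (midpoint of projected group means),
#'   `orientation`, class bookkeeping and the convergence flag.
#' @export
fit_sparse_lda <- function(inputs, lambda, v_init = NULL) {
  mvc_assert(inherits(inputs, "discriminant_inputs"), "config_error",
             "inputs must come from build_inputs()")
  mvc_assert(is.numeric(lambda) && length(lambda) == 1L && lambda > 0,
             "config_error", "lambda must be a positive scalar")
  p <- length(inputs$d)
  if (is.null(v_init)) v_init <- numeric(p)
  # coordinate descent first; if the quadratic is too ill-conditioned to
  # converge within the sweep budget (the saturated small-lambda regime
  # with p >> n), finish with an exact active-set solve so the returned
  # coefficients satisfy the KKT conditions regardless
  budget <- 10000L
  sol <- if (!is.null(inputs$Xc))
    cd_gram_lasso(inputs$Xc, inputs$d, lambda, v_init,
                  scale = 1, ridge = inputs$gamma,
                  tol = 1e-9, max_sweeps = min(200L, budget))
  else
    cd_quad_lasso(inputs$W, inputs$d, lambda, v_init,
                  tol = 1e-9, max_sweeps = min(200L, budget))
  v_num <- as.numeric(sol$v)
  converged <- sol$converged
  if (!converged) {
    polished <- active_set_solve(inputs$W, inputs$d, lambda, v_num,
                                 Xc = inputs$Xc, gamma = inputs$gamma)
    if (!is.null(polished)) {
      v_num <- polished
      converged <- TRUE
    } else {
      sol <- if (!is.null(inputs$Xc))
        cd_gram_lasso(inputs$Xc, inputs$d, lambda, v_num,
                      scale = 1, ridge = inputs$gamma,
                      tol = 1e-9, max_sweeps = budget)
      else
        cd_quad_lasso(inputs$W, inputs$d, lambda, v_num,
                      tol = 1e-9, max_sweeps = budget)
      v_num <- as.numeric(sol$v)
      converged <- sol$converged
    }
  }
  v <- stats::setNames(v_num, inputs$feature_ids)
  s1 <- drop(inputs$group_means[1L, ] %*% v)
  s2 <- drop(inputs$group_means[2L, ] %*% v)
  majority <- if (inputs$n2 > inputs$n1) inputs$classes[2L] else inputs$classes[1L]
  structure(list(v = v, lambda = lambda,
                 selected = inputs$feature_ids[v != 0],
                 threshold = (s1 + s2) / 2,
                 orientation = sign(s2 - s1),
                 classes = inputs$classes, majority = majority,
                 converged = converged, sweeps = sol$sweeps),
            class = "discriminant_fit")
}

#' @export
print.discriminant_fit <- function(x, ...) {
  cat(sprintf("discriminant_fit: lambda = %.4g, %d feature(s) selected",
              x$lambda, length(x$selected)))
  if (!is.null(x$loo_mcr)) cat(sprintf(", LOO MCR = %.3f", x$loo_mcr))
  cat("\n")
  invisible(x)
}

# Exact solver for min 1/2 v'Wv - d'v + lambda ||v||_1 by active-set
# iteration: given a working active set and sign vector, the restricted
# stationary point is W_AA v_A = d_A - lambda * s_A; coordinates whose
# solved sign disagrees are dropped, then inactive KKT violators are
# added (worst first, in small batches) until the full KKT system
# holds, which certifies the global optimum of the convex problem.
# Returns NULL if it fails to settle within the round budget.
active_set_solve <- function(W, d, lambda, v_start, max_rounds = 100L,
                             kkt_tol = 1e-8, Xc = NULL, gamma = 0) {
  p <- length(d)
  n <- if (is.null(Xc)) 0L else nrow(Xc)
  # restricted solve of (W_AA) v = rhs; when the active set is large and
  # W = Xc'Xc/n + gamma I, use the Woodbury identity so only an n x n
  # system is factorized
  solve_restricted <- function(active, rhs) {
    if (is.null(Xc) || gamma <= 0 || length(active) <= 2L * n)
      return(tryCatch(solve(W[active, active, drop = FALSE], rhs),
                      error = function(e) NULL))
    A <- Xc[, active, drop = FALSE]
    M <- diag(n) * gamma + tcrossprod(A) / n
    inner <- tryCatch(solve(M, drop(A %*% rhs)) / n, error = function(e) NULL)
    if (is.null(inner)) return(NULL)
    (rhs - drop(crossprod(A, inner))) / gamma
  }
  gradient <- function(v) {
    if (is.null(Xc)) return(drop(W %*% v) - d)
    drop(crossprod(Xc, drop(Xc %*% v))) / n + gamma * v - d
  }
  active <- which(v_start != 0)
  s <- sign(v_start[active])
  for (round in seq_len(max_rounds)) {
    if (length(active)) {
      vA <- solve_restricted(active, d[active] - lambda * s)
      if (is.null(vA)) return(NULL)
      bad <- sign(vA) != s
      if (any(bad)) {
        # drop at most half the offenders per round to avoid cycling
        drop_idx <- which(bad)
        keep <- setdiff(seq_along(active), drop_idx)
        if (length(keep) == length(active)) return(NULL)
        active <- active[keep]
        s <- s[keep]
        next
      }
    } else {
      vA <- numeric(0)
    }
    v <- numeric(p)
    v[active] <- vA
    g <- gradient(v)
    viol <- setdiff(which(abs(g) > lambda + kkt_tol), active)
    if (!length(viol)) return(v)
    add <- viol[order(-abs(g[viol]))]
    add <- add[seq_len(min(25L, length(add)))]
    active <- c(active, add)
    s <- c(s, -sign(g[add]))
    ord <- order(active)
    active <- active[ord]
    s <- s[ord]
  }
  NULL
}

#' Classify new samples with a discriminant fit
#'
#' Projects rows of `X_new` onto the discriminant direction and assigns
#' the class whose projected group mean lies on the same side of the
#' midpoint threshold. An all-zero fit assigns the training-majority
#' class (ties go to the class with the lower sorted label).
#'
#' @param fit A [fit_sparse_lda()] result.
#' @param X_new Matrix with the same feature columns as the training data.
#' @return Vector of predicted labels (same type as training labels).
#' @export
classify <- function(fit, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new)) && !identical(colnames(X_new), names(fit$v)))
    mvc_error("alignment_error", "X_new features do not match the fit")
  if (ncol(X_new) != length(fit$v))
    mvc_error("alignment_error", "X_new has the wrong number of features")
  if (all(fit$v == 0) || fit$orientation == 0)
    return(rep(fit$majority, nrow(X_new)))
  s <- unname(drop(X_new %*% fit$v))
  ifelse(fit$orientation * (s - fit$threshold) > 0,
         fit$classes[2L], fit$classes[1L])
}

#' Penalty path with leave-one-out cross-validation
#'
#' Lays a log-spaced grid of `grid_size` penalties from
#' \eqn{\lambda_{max} = \max_j |d_j|} (empty selection) down to
#' \eqn{10^{-3}\lambda_{max}}. For every penalty it records the
#' full-data fit and, for every sample, a leave-one-out refit
#' (column standardization and the discriminant inputs are rebuilt
#' inside each fold, so no information leaks from the held-out sample)
#' and the misclassification count of the held-out predictions.
#'
#' @param X Numeric matrix, samples in rows; raw (unstandardized) values.
#' @param y Binary labels; `n >= 6` and at least 3 samples per class.
#' @param grid_size Number of penalties on the path.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @return A `path_fit`: `lambda_grid` (descending), per-penalty
#'   `n_selected`, `selected` sets, `loo_miscl` counts, `loo_mcr` rates,
#'   the full-data `fits`, and `n`.
#' @export
lambda_path_loocv <- function(X, y, grid_size = 50L, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  mvc_assert(n >= 6L, "config_error", "LOO path selection needs n >= 6")
  lab <- canon_labels(y)
  mvc_assert(min(table(lab$idx)) >= 3L, "config_error",
             "each class needs at least 3 samples for leave-one-out refits")
  mvc_assert(grid_size >= 1L, "config_error", "grid_size must be >= 1")

  s_full <- std_fit(X)
  Xs <- std_apply(X, s_full)
  inp <- build_inputs(Xs, y)
  lambda_max <- max(abs(inp$d))
  if (lambda_max <= 0) lambda_max <- 1e-8 # degenerate: identical group means
  grid <- if (grid_size == 1L) lambda_max else
    exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
            length.out = grid_size))

  fits <- vector("list", grid_size)
  v_warm <- numeric(length(inp$d))
  for (l in seq_along(grid)) {
    fits[[l]] <- fit_sparse_lda(inp, grid[l], v_init = v_warm)
    v_warm <- unname(fits[[l]]$v)
  }

  miscl <- integer(grid_size)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    s <- std_fit(Xtr)
    inp_i <- build_inputs(std_apply(Xtr, s), ytr)
    xte <- std_apply(X[i, , drop = FALSE], s)
    v_warm <- numeric(length(inp_i$d))
    for (l in seq_along(grid)) {
      f <- fit_sparse_lda(inp_i, grid[l], v_init = v_warm)
      v_warm <- unname(f$v)
      pred <- classify(f, xte)
      if (as.character(pred) != as.character(y[i])) miscl[l] <- miscl[l] + 1L
    }
  }

  structure(list(lambda_grid = grid,
                 n_selected = vapply(fits, function(f) length(f$selected), integer(1)),
                 selected = lapply(fits, function(f) f$selected),
                 loo_miscl = miscl,
                 loo_mcr = miscl / n,
                 fits = fits,
                 n = n),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path_fit: %d penalties, n = %d, min LOO MCR = %.3f\n",
              length(x$lambda_grid), x$n, min(x$loo_mcr)))
  invisible(x)
}

#' Pick a fit from a penalty path
#'
#' Policies: `"min_mcr_sparsest"` (default) — among penalties attaining
#' the minimal leave-one-out misclassification count, the largest
#' penalty (sparsest model); `"min_mcr"` — among those, the smallest
#' penalty (densest model); `"fixed_size"` — the penalty whose full-data
#' selection size is closest to `size` (ties to the larger penalty),
#' regardless of MCR.
#'
#' The MCR-based policies only consider penalties whose full-data
#' selection has at most `max_size` features (default: the sample size
#' n). Beyond n features the within-group problem is unidentifiable and
#' the ridge term alone determines the extra coefficients, so such fits
#' are discriminant directions but not variable selections; they remain
#' visible in the path but are not eligible winners.
#'
#' @param path A [lambda_path_loocv()] result.
#' @param policy Selection policy.
#' @param size Target selection size for `policy = "fixed_size"`.
#' @param max_size Largest admissible selection for the MCR-based
#'   policies.
#' @return The chosen full-data `discriminant_fit`, annotated with its
#'   `loo_mcr` and `loo_miscl`.
#' @export
select_model <- function(path, policy = c("min_mcr_sparsest", "min_mcr", "fixed_size"),
                         size = NULL, max_size = path$n) {
  policy <- match.arg(policy)
  mvc_assert(inherits(path, "path_fit") && length(path$lambda_grid) >= 1L,
             "config_error", "path must be a non-empty path_fit")
  admissible <- which(path$n_selected <= max_size)
  if (length(admissible) == 0L) admissible <- seq_along(path$lambda_grid)
  # lambda_grid is descending: smaller index = larger penalty
  idx <- switch(policy,
    min_mcr_sparsest = {
      best <- min(path$loo_miscl[admissible])
      min(admissible[path$loo_miscl[admissible] == best])
    },
    min_mcr = {
      best <- min(path$loo_miscl[admissible])
      max(admissible[path$loo_miscl[admissible] == best])
    },
    fixed_size = {
      mvc_assert(is.numeric(size) && length(size) == 1L && size >= 0,
                 "config_error", "fixed_size policy needs a non-negative size")
      gap <- abs(path$n_selected - size)
      min(which(gap == min(gap)))
    })
  fit <- path$fits[[idx]]
  fit$loo_mcr <- path$loo_mcr[idx]
  fit$loo_miscl <- path$loo_miscl[idx]
  fit
}

#' Features highly correlated with a selected anchor
#'
#' The l1 discriminant keeps only one representative of a block of
#' highly correlated informative features; this returns the non-anchor
#' features whose absolute Pearson correlation with any anchor exceeds
#' the threshold, computed on the same matrix the discriminant was fit
#' to.
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param anchor_features Ids of the anchor feature(s); must be present
#'   and non-constant.
#' @param threshold Absolute-correlation cutoff (default 0.95).
#' @return Named numeric vector: for each expanded feature, its largest
#'   absolute correlation with an anchor. Names are the feature ids.
#' @export
correlated_expansion <- function(table, anchor_features, threshold = 0.95) {
  V <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  miss <- setdiff(anchor_features, colnames(V))
  if (length(miss))
    mvc_error("unknown_feature_error",
              paste0("anchor(s) not in table: ", paste(miss, collapse = ", ")))
  A <- V[, anchor_features, drop = FALSE]
  if (any(apply(A, 2L, stats::sd) == 0))
    mvc_error("degenerate_feature_error", "anchor feature has zero variance")
  others <- setdiff(colnames(V), anchor_features)
  if (length(others) == 0L) return(stats::setNames(numeric(0), character(0)))
  suppressWarnings(r <- stats::cor(V[, others, drop = FALSE], A))
  r[is.na(r)] <- 0 # constant non-anchor features cannot correlate
  best <- apply(abs(r), 1L, max)
  keep <- best > threshold
  stats::setNames(as.numeric(best[keep]), others[keep])
}

# ---- serialization --------------------------------------------------------

fit_to_list <- function(f) {
  list(v = as.list(f$v), lambda = f$lambda, selected = as.list(f$selected),
       threshold = f$threshold, orientation = f$orientation,
       classes = as.list(as.character(f$classes)), majority = as.character(f$majority),
       converged = f$converged, sweeps = f$sweeps,
       loo_mcr = f$loo_mcr, loo_miscl = f$loo_miscl)
}

list_to_fit <- function(l) {
  structure(list(v = list_to_named(l$v), lambda = as.numeric(l$lambda),
                 selected = chr(l$selected), threshold = as.numeric(l$threshold),
                 orientation = as.numeric(l$orientation), classes = chr(l$classes),
                 majority = as.character(l$majority),
                 converged = isTRUE(l$converged), sweeps = as.integer(l$sweeps),
                 loo_mcr = if (is.null(l$loo_mcr)) NULL else as.numeric(l$loo_mcr),
                 loo_miscl = if (is.null(l$loo_miscl)) NULL else as.integer(l$loo_miscl)),
            class = "discriminant_fit")
}

report_to_list.path_fit <- function(report) {
  list(lambda_grid = as.list(report$lambda_grid),
       n_selected = as.list(report$n_selected),
       selected = lapply(report$selected, as.list),
       loo_miscl = as.list(report$loo_miscl),
       loo_mcr = as.list(report$loo_mcr),
       fits = lapply(report$fits, fit_to_list),
       n = report$n)
}

list_to_path_fit <- function(l) {
  structure(list(lambda_grid = as.numeric(unlist(l$lambda_grid)),
                 n_selected = as.integer(unlist(l$n_selected)),
                 selected = lapply(l$selected, chr),
                 loo_miscl = as.integer(unlist(l$loo_miscl)),
                 loo_mcr = as.numeric(unlist(l$loo_mcr)),
                 fits = lapply(l$fits, list_to_fit),
                 n = as.integer(l$n)),
            class = "path_fit")
}

report_tsv.path_fit <- function(report) {
  data.frame(lambda = report$lambda_grid,
             n_selected = report$n_selected,
             loo_misclassifications = report$loo_miscl,
             loo_mcr = report$loo_mcr,
             selected = vapply(report$selected, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}
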