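# Joint association and classification across 2-3 views. With optimal
# scores y~ (a zero-mean, unit-norm recoding of the binary labels), the
# convex objective
#
#   F = sum_d (1-alpha)/(2n) ||y~ - X_d w_d||^2
#     + sum_{d<d'} alpha/(2n) ||X_d w_d - X_{d'} w_{d'}||^2
#     + sum_d lambda_d ||w_d||_1
#
# mixes per-view classification loss with cross-view score agreement;
# selected features both discriminate the groups and carry correlated
# signal across views. Minimised by block coordinate descent, each
# block a lasso solved in covariance form by cd_quad_lasso().

#' Optimal-scoring recoding of binary labels
#'
#' Class 1 (lower sorted label) maps to \eqn{\sqrt{n_2/(n\,n_1)}}, class
#' 2 to \eqn{-\sqrt{n_1/(n\,n_2)}}, giving a score vector with exact
#' zero sum and unit sum of squares for any class balance.
#'
#' @param y Binary labels.
#' @return Numeric score vector, one entry per sample.
#' @export
optimal_scores <- function(y) {
  lab <- canon_labels(y)
  n1 <- sum(lab$idx == 1L)
  n2 <- sum(lab$idx == 2L)
  n <- n1 + n2
  ifelse(lab$idx == 1L, sqrt(n2 / (n * n1)), -sqrt(n1 / (n * n2)))
}

# per-view penalty ceiling: smallest lambda_d with w_d = 0 optimal when
# all other blocks are zero
jaca_lambda_max <- function(views, y, alpha) {
  ytil <- optimal_scores(y)
  vapply(views, function(X) {
    n <- nrow(X)
    max(abs(crossprod(X, (1 - alpha) * ytil))) / n
  }, numeric(1))
}

jaca_objective <- function(views, w, ytil, alpha, lambda) {
  n <- length(ytil)
  D <- length(views)
  sc <- mapply(function(X, wd) drop(X %*% wd), views, w, SIMPLIFY = FALSE)
  F <- 0
  for (d in seq_len(D))
    F <- F + (1 - alpha) / (2 * n) * sum((ytil - sc[[d]])^2) +
      lambda[d] * sum(abs(w[[d]]))
  if (D > 1)
    for (d in seq_len(D - 1)) for (e in seq((d + 1), D))
      F <- F + alpha / (2 * n) * sum((sc[[d]] - sc[[e]])^2)
  F
}

#' Fit the joint multi-view sparse model
#'
#' Block coordinate descent on the objective above: the update of block
#' d is the lasso with working response
#' \eqn{r_d = [(1-\alpha)\tilde y + \alpha \sum_{d' \ne d} X_{d'} w_{d'}]/c_d}
#' and weight \eqn{c_d = (1-\alpha) + \alpha(D-1)}, solved by inner
#' coordinate descent. The outer loop stops when the relative objective
#' change falls below 1e-8 (at most 500 outer iterations;
#' non-convergence is recorded, not raised). The recorded objective
#' trace is non-increasing.
#'
#' @param views Named list of 2 or 3 numeric matrices sharing the same
#'   sample ordering; columns are expected standardized.
#' @param y Binary labels.
#' @param alpha Mixing weight in `[0, 1)`: 0 = pure per-view
#'   classification (the problem decouples into independent per-view
#'   lassos), larger values demand cross-view score agreement.
#' @param lambda Per-view l1 penalties (recycled if scalar).
#' @param w_init Optional warm-start list of coefficient vectors.
#' @param max_outer,tol Outer-loop iteration cap and relative-objective
#'   tolerance.
#' @return A `joint_fit`: per-view coefficients `w`, `selected` sets,
#'   sample `scores`, `pairwise_corr` of scores, the `objective` trace,
#'   classification bookkeeping and `loocv_mcr` (NA unless produced by
#'   [jaca_loocv()]).
#' @export
fit_jaca <- function(views, y, alpha = 0.5, lambda, w_init = NULL,
                     max_outer = 500L, tol = 1e-8) {
  mvc_assert(is.list(views) && length(views) %in% 2:3, "config_error",
             "views must be a list of 2 or 3 matrices")
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha >= 0 && alpha < 1))
    mvc_error("config_error", "alpha must lie in [0, 1); at alpha = 1 the objective degenerates (w = 0)")
  views <- lapply(views, as.matrix)
  n <- nrow(views[[1L]])
  mvc_assert(all(vapply(views, nrow, integer(1)) == n), "alignment_error",
             "all views must share the same samples")
  D <- length(views)
  if (length(lambda) == 1L) lambda <- rep(lambda, D)
  mvc_assert(length(lambda) == D && all(lambda > 0), "config_error",
             "one positive lambda per view is required")
  lab <- canon_labels(y)
  ytil <- optimal_scores(y)
  cd <- (1 - alpha) + alpha * (D - 1)

  w <- if (is.null(w_init)) lapply(views, function(X) numeric(ncol(X))) else
    lapply(w_init, as.numeric)
  sc <- mapply(function(X, wd) drop(X %*% wd), views, w, SIMPLIFY = FALSE)

  obj <- jaca_objective(views, w, ytil, alpha, lambda)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    for (d in seq_len(D)) {
      others <- Reduce(`+`, sc[-d])
      resp <- (1 - alpha) * ytil + alpha * others
      b <- drop(crossprod(views[[d]], resp)) / n
      sol <- cd_gram_lasso(views[[d]], b, lambda[d], w[[d]],
                           scale = cd, ridge = 0,
                           tol = 1e-10, max_sweeps = 10000L)
      w[[d]] <- as.numeric(sol$v)
      sc[[d]] <- drop(views[[d]] %*% w[[d]])
    }
    obj_new <- jaca_objective(views, w, ytil, alpha, lambda)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * (abs(obj) + 1e-12)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  vn <- names(views)
  if (is.null(vn)) vn <- paste0("view", seq_len(D))
  w <- mapply(function(wd, X) stats::setNames(wd, colnames(X)), w, views,
              SIMPLIFY = FALSE)
  names(w) <- vn
  names(sc) <- vn
  selected <- lapply(w, function(wd) names(wd)[wd != 0])
  pc <- matrix(NA_real_, D, D, dimnames = list(vn, vn))
  diag(pc) <- 1
  for (d in seq_len(D)) for (e in seq_len(D)) if (d < e) {
    r <- if (stats::sd(sc[[d]]) > 0 && stats::sd(sc[[e]]) > 0)
      stats::cor(sc[[d]], sc[[e]]) else NA_real_
    pc[d, e] <- pc[e, d] <- r
  }
  pooled <- Reduce(`+`, sc) / D
  m1 <- mean(pooled[lab$idx == 1L])
  m2 <- mean(pooled[lab$idx == 2L])
  n1 <- sum(lab$idx == 1L)
  n2 <- sum(lab$idx == 2L)
  structure(list(w = w, alpha = alpha,
                 lambda = stats::setNames(as.numeric(lambda), vn),
                 selected = selected, scores = sc, pairwise_corr = pc,
                 objective = as.numeric(trace), converged = converged,
                 classes = lab$classes,
                 majority = if (n2 > n1) lab$classes[2L] else lab$classes[1L],
                 centroids = c(m1, m2), threshold = (m1 + m2) / 2,
                 orientation = sign(m2 - m1),
                 loocv_mcr = NA_real_),
            class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("joint_fit: alpha = %.2f, selections [%s]",
              x$alpha,
              paste(sprintf("%s: %d", names(x$w),
                            vapply(x$selected, length, integer(1))), collapse = ", ")))
  if (is.finite(x$loocv_mcr)) cat(sprintf(", LOO MCR = %.3f", x$loocv_mcr))
  cat("\n")
  invisible(x)
}

#' Classify new samples with a joint fit
#'
#' Pools the per-view scores \eqn{s = \frac1D \sum_d x_d w_d} and
#' assigns the nearest projected class centroid (midpoint threshold).
#' An all-zero fit assigns the training-majority class.
#'
#' @param fit A [fit_jaca()] result.
#' @param new_views Named list of matrices with the training feature
#'   spaces.
#' @return Predicted labels.
#' @export
jaca_classify <- function(fit, new_views) {
  D <- length(fit$w)
  mvc_assert(length(new_views) == D, "alignment_error",
             "new_views must have one matrix per trained view")
  new_views <- lapply(new_views, function(X) {
    X <- as.matrix(X)
    X
  })
  for (d in seq_len(D)) {
    cn <- colnames(new_views[[d]])
    if (!is.null(cn) && !identical(cn, names(fit$w[[d]])))
      mvc_error("alignment_error", "new view features do not match the fit")
    if (ncol(new_views[[d]]) != length(fit$w[[d]]))
      mvc_error("alignment_error", "new view has the wrong number of features")
  }
  if (all(vapply(fit$w, function(wd) all(wd == 0), logical(1))) ||
      fit$orientation == 0)
    return(rep(fit$majority, nrow(new_views[[1L]])))
  s <- unname(Reduce(`+`, mapply(function(X, wd) drop(X %*% wd), new_views,
                                 fit$w, SIMPLIFY = FALSE))) / D
  ifelse(fit$orientation * (s - fit$threshold) > 0,
         fit$classes[2L], fit$classes[1L])
}

#' Leave-one-out selection of the joint penalty level
#'
#' Searches a shared multiplier t over a log-spaced grid, with
#' \eqn{\lambda_d = t\,\lambda_{max,d}} (per-view ceilings computed on
#' the full standardized data, as in standard regularization-path
#' cross-validation). For each left-out sample the views are
#' re-standardized on the training fold and the whole t-path refit with
#' warm starts; the returned fit is the full-data fit at the t with the
#' fewest held-out misclassifications (ties to the larger t, i.e. the
#' sparser model).
#'
#' @param views Named list of raw (unstandardized) matrices sharing
#'   sample order.
#' @param y Binary labels, `n >= 6`, at least 3 per class.
#' @param alpha Mixing weight in `[0, 1)`.
#' @param grid_size Number of t values between 1 and `t_min_ratio`.
#' @param t_min_ratio Smallest multiplier on the grid.
#' @return A `joint_fit` on the full data at the selected penalties,
#'   with `loocv_mcr` and a `cv` element (`t_grid`, `loo_miscl`,
#'   `loo_mcr`).
#' @export
jaca_loocv <- function(views, y, alpha = 0.5, grid_size = 20L,
                       t_min_ratio = 1e-3) {
  views <- lapply(views, as.matrix)
  n <- nrow(views[[1L]])
  mvc_assert(n >= 6L, "config_error", "LOO selection needs n >= 6")
  lab <- canon_labels(y)
  mvc_assert(min(table(lab$idx)) >= 3L, "config_error",
             "each class needs at least 3 samples for leave-one-out refits")
  mvc_assert(grid_size >= 1L, "config_error", "grid_size must be >= 1")

  s_full <- lapply(views, std_fit)
  Xs <- mapply(std_apply, views, s_full, SIMPLIFY = FALSE)
  lmax <- jaca_lambda_max(Xs, y, alpha)
  lmax[lmax <= 0] <- 1e-8
  tgrid <- if (grid_size == 1L) 1 else
    exp(seq(log(1), log(t_min_ratio), length.out = grid_size))

  miscl <- integer(grid_size)
  for (i in seq_len(n)) {
    tr <- lapply(views, function(X) X[-i, , drop = FALSE])
    ytr <- y[-i]
    s_tr <- lapply(tr, std_fit)
    Xtr <- mapply(std_apply, tr, s_tr, SIMPLIFY = FALSE)
    xte <- mapply(function(X, s) std_apply(X[i, , drop = FALSE], s),
                  views, s_tr, SIMPLIFY = FALSE)
    w_warm <- NULL
    for (l in seq_along(tgrid)) {
      f <- fit_jaca(Xtr, ytr, alpha = alpha, lambda = tgrid[l] * lmax,
                    w_init = w_warm)
      w_warm <- lapply(f$w, unname)
      pred <- jaca_classify(f, xte)
      if (as.character(pred) != as.character(y[i])) miscl[l] <- miscl[l] + 1L
    }
  }
  best <- min(which(miscl == min(miscl))) # descending t: first = largest
  fit <- fit_jaca(Xs, y, alpha = alpha, lambda = tgrid[best] * lmax)
  fit$loocv_mcr <- miscl[best] / n
  fit$cv <- list(t_grid = tgrid, loo_miscl = miscl, loo_mcr = miscl / n,
                 t_selected = tgrid[best], lambda_max = lmax)
  fit
}

#' Cross-view correlations of the fitted scores
#'
#' Pearson correlation of \eqn{X_d w_d} versus \eqn{X_{d'} w_{d'}} for
#' every view pair, plus the per-pair sample projections for plotting.
#'
#' @param fit A `joint_fit`.
#' @param views Optional named list of matrices on which to evaluate the
#'   scores; defaults to the training scores stored in the fit.
#' @return List with `correlations` (data frame: view_1, view_2, r) and
#'   `projections` (one data frame of paired sample scores per pair).
#' @export
score_correlations <- function(fit, views = NULL) {
  sc <- if (is.null(views)) fit$scores else
    mapply(function(X, wd) drop(as.matrix(X) %*% wd), views, fit$w,
           SIMPLIFY = FALSE)
  vn <- names(fit$w)
  D <- length(sc)
  bad <- vapply(sc, function(s) stats::sd(s) == 0, logical(1))
  if (any(bad))
    mvc_error("degenerate_score_error",
              paste0("zero-variance score in view(s): ",
                     paste(vn[bad], collapse = ", ")))
  pairs <- utils::combn(D, 2)
  cors <- data.frame(view_1 = vn[pairs[1L, ]], view_2 = vn[pairs[2L, ]],
                     r = apply(pairs, 2L, function(pr) stats::cor(sc[[pr[1L]]], sc[[pr[2L]]])),
                     stringsAsFactors = FALSE)
  proj <- lapply(seq_len(ncol(pairs)), function(k) {
    d <- pairs[1L, k]; e <- pairs[2L, k]
    data.frame(sample = seq_along(sc[[d]]), score_1 = sc[[d]], score_2 = sc[[e]],
               stringsAsFactors = FALSE)
  })
  names(proj) <- paste(vn[pairs[1L, ]], vn[pairs[2L, ]], sep = "_vs_")
  list(correlations = cors, projections = proj)
}

# ---- serialization --------------------------------------------------------

report_to_list.joint_fit <- function(report) {
  list(w = lapply(report$w, as.list),
       alpha = report$alpha,
       lambda = as.list(report$lambda),
       selected = lapply(report$selected, as.list),
       scores = lapply(report$scores, as.list),
       pairwise_corr = as.list(as.data.frame(report$pairwise_corr)),
       objective = as.list(report$objective),
       converged = report$converged,
       classes = as.list(as.character(report$classes)),
       majority = as.character(report$majority),
       centroids = as.list(report$centroids),
       threshold = report$threshold,
       orientation = report$orientation,
       loocv_mcr = report$loocv_mcr,
       cv = if (is.null(report$cv)) NULL else
         list(t_grid = as.list(report$cv$t_grid),
              loo_miscl = as.list(report$cv$loo_miscl),
              loo_mcr = as.list(report$cv$loo_mcr),
              t_selected = report$cv$t_selected,
              lambda_max = as.list(report$cv$lambda_max)))
}

list_to_joint_fit <- function(l) {
  vn <- names(l$w)
  pc <- sapply(l$pairwise_corr, function(col)
    vapply(col, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1)))
  pc <- matrix(as.numeric(pc), length(vn), length(vn), dimnames = list(vn, vn))
  out <- structure(list(w = lapply(l$w, list_to_named),
                 alpha = as.numeric(l$alpha),
                 lambda = list_to_named(l$lambda),
                 selected = lapply(l$selected, chr),
                 scores = lapply(l$scores, function(s) as.numeric(unlist(s))),
                 pairwise_corr = pc,
                 objective = as.numeric(unlist(l$objective)),
                 converged = isTRUE(l$converged),
                 classes = chr(l$classes),
                 majority = as.character(l$majority),
                 centroids = as.numeric(unlist(l$centroids)),
                 threshold = as.numeric(l$threshold),
                 orientation = as.numeric(l$orientation),
                 loocv_mcr = if (is.null(l$loocv_mcr)) NA_real_ else as.numeric(l$loocv_mcr)),
            class = "joint_fit")
  if (!is.null(l$cv))
    out$cv <- list(t_grid = as.numeric(unlist(l$cv$t_grid)),
                   loo_miscl = as.integer(unlist(l$cv$loo_miscl)),
                   loo_mcr = as.numeric(unlist(l$cv$loo_mcr)),
                   t_selected = as.numeric(l$cv$t_selected),
                   lambda_max = list_to_named(l$cv$lambda_max))
  out
}

report_tsv.joint_fit <- function(report) {
  do.call(rbind, lapply(names(report$w), function(vn) {
    wd <- report$w[[vn]]
    sel <- wd != 0
    if (!any(sel)) return(NULL)
    data.frame(view = vn, feature = names(wd)[sel], loading = unname(wd[sel]),
               stringsAsFactors = FALSE)
  }))
}
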