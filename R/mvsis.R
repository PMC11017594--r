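# Model-free sure-independence screening with the mean-variance (MV)
# index: for a feature x and binary labels y, the class-probability
# weighted integrated squared gap between the conditional and pooled
# empirical CDFs, integrated over the pooled empirical distribution.
# Rank-based, so invariant to strictly increasing transforms of x.

canon_labels <- function(y) {
  y <- as.vector(y)
  if (is.factor(y)) y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) < 2L)
    mvc_error("degenerate_labels_error", "both classes must be present")
  mvc_assert(length(cls) == 2L, "config_error",
             "binary labels required (exactly two distinct values)")
  list(idx = match(y, cls), classes = cls)
}

#' Mean-variance (MV) screening statistic
#'
#' \deqn{\widehat{MV} = \frac{1}{n}\sum_{j=1}^{n}\sum_{r=1}^{2}
#'   \hat p_r\,(\hat F_r(x_j) - \hat F(x_j))^2}
#' where \eqn{\hat F_r} is the empirical CDF within class r, \eqn{\hat F}
#' the pooled empirical CDF and \eqn{\hat p_r} the class proportion. For
#' binary labels the statistic lies in \eqn{[0, \hat p_1 \hat p_2]}; a
#' constant feature scores exactly 0.
#'
#' @param x Numeric vector (one feature across samples).
#' @param y Binary labels, same length as `x`.
#' @return The MV statistic, a non-negative scalar.
#' @examples
#' mv_statistic(c(1, 2, 3, 4), c("A", "A", "B", "B")) # 0.09375
#' @export
mv_statistic <- function(x, y) {
  mvc_assert(is.numeric(x) && all(is.finite(x)), "value_domain_error",
             "x must be finite numeric")
  lab <- canon_labels(y)
  n <- length(x)
  mvc_assert(length(lab$idx) == n, "config_error", "x and y lengths differ")
  mvc_assert(n >= 4L, "config_error", "MV screening needs n >= 4")
  # F(x_j) via max-ranks; F_r(x_j) by counting class members <= x_j
  Fpool <- rank(x, ties.method = "max") / n
  acc <- numeric(n)
  for (r in 1:2) {
    xr <- x[lab$idx == r]
    nr <- length(xr)
    Fr <- vapply(x, function(t) sum(xr <= t), numeric(1)) / nr
    acc <- acc + (nr / n) * (Fr - Fpool)^2
  }
  mean(acc)
}

#' Screen all features of a table by MV statistic
#'
#' Computes the MV statistic per feature, a dense ranking (1 = most
#' discriminatory; tied values share a rank) and the top-k carry-forward
#' set. Ties in the top-k cut are broken by feature id (lexicographic),
#' so the result is deterministic.
#'
#' @param table A [feature_table()].
#' @param y Binary labels, one per sample.
#' @param top_k Size of the carry-forward set; defaults to
#'   `min(300, n_features(table))`.
#' @return A `screening_result`: list with `feature_ids`, `mv`, `rank`,
#'   `top_k`, `top_set`.
#' @export
mvsis_screen <- function(table, y, top_k = min(300L, n_features(table))) {
  p <- n_features(table)
  mvc_assert(top_k >= 1L && top_k <= p, "config_error",
             sprintf("top_k must be in [1, %d]", p))
  mv <- apply(table$values, 2L, mv_statistic, y = y)
  dense_rank <- match(-mv, sort(unique(-mv)))
  ord <- order(-mv, feature_ids(table))
  top_set <- feature_ids(table)[ord[seq_len(top_k)]]
  structure(list(feature_ids = feature_ids(table),
                 mv = stats::setNames(as.numeric(mv), feature_ids(table)),
                 rank = stats::setNames(as.integer(dense_rank), feature_ids(table)),
                 top_k = as.integer(top_k),
                 top_set = top_set),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result: %d features, top-%d carried forward\n",
              length(x$feature_ids), x$top_k))
  best <- utils::head(x$top_set, 5L)
  cat("  leading features:", paste(best, collapse = ", "), "\n")
  invisible(x)
}
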