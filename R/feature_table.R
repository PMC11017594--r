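#' Sample-by-feature table
#'
#' The universal exchange object of the package: a numeric matrix with
#' samples in rows and features in columns, plus a declared kind of
#' measurement. Identifiers are case-sensitive; leading/trailing
#' whitespace is stripped.
#'
#' @param values Numeric matrix (or coercible) with unique row names
#'   (sample identifiers) and unique column names (feature identifiers).
#' @param view_kind One of `"counts"`, `"intensities"`,
#'   `"relative_abundance"`, `"differences"`, `"generic"`. Counts must be
#'   non-negative; relative-abundance rows must sum to 1 (tolerance 1e-9).
#' @return An object of class `feature_table` with elements `values` and
#'   `view_kind`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' ft <- feature_table(m, "counts")
#' n_samples(ft)
#' @export
feature_table <- function(values, view_kind = c("generic", "counts", "intensities",
                                                "relative_abundance", "differences")) {
  view_kind <- match.arg(view_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sid <- rownames(values)
  fid <- colnames(values)
  mvc_assert(!is.null(sid) && !is.null(fid), "parse_error",
             "feature_table requires sample (row) and feature (column) identifiers")
  sid <- trimws(sid)
  fid <- trimws(fid)
  mvc_assert(all(nzchar(sid)) && all(nzchar(fid)), "parse_error",
             "empty sample or feature identifier")
  if (anyDuplicated(sid))
    mvc_error("duplicate_id_error", paste0("duplicate sample identifier(s): ",
                                           paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  if (anyDuplicated(fid))
    mvc_error("duplicate_id_error", paste0("duplicate feature identifier(s): ",
                                           paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  mvc_assert(all(is.finite(values)), "value_domain_error",
             "all values in a feature_table must be finite")
  if (view_kind == "counts")
    mvc_assert(all(values >= 0), "value_domain_error", "counts view must be non-negative")
  if (view_kind == "relative_abundance")
    mvc_assert(all(abs(rowSums(values) - 1) <= 1e-9), "value_domain_error",
               "relative_abundance rows must sum to 1 (tolerance 1e-9)")
  dimnames(values) <- list(sid, fid)
  structure(list(values = values, view_kind = view_kind), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$view_kind))
  invisible(x)
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname feature_table
#' @export
feature_ids <- function(x) colnames(x$values)

#' @rdname feature_table
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname feature_table
#' @export
n_features <- function(x) ncol(x$values)

# replace values, keeping class and (by default) kind
ft_replace <- function(x, values, view_kind = x$view_kind) {
  feature_table(values, view_kind)
}
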