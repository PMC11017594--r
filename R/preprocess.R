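# View-specific preprocessing for the three omic views:
# metabolite intensities (median normalisation, drug-feature removal,
# paired differencing), amplicon counts (genus aggregation, prevalence
# filter, relative abundance, paired differencing) and host gene counts
# (log-CPM on the single post-treatment day).

#' Median-normalize an intensity table
#'
#' Rescales every feature so its across-sample median equals 1. Features
#' whose median is 0 cannot be rescaled; they are left unchanged and
#' listed in the `"unscaled_features"` attribute (and a message).
#'
#' @param table A [feature_table()] of non-negative intensities.
#' @return Normalized `feature_table`.
#' @export
median_normalize <- function(table) {
  v <- table$values
  mvc_assert(all(v >= 0), "value_domain_error",
             "median normalisation expects non-negative intensities")
  med <- apply(v, 2L, stats::median)
  zero <- med == 0
  scale <- ifelse(zero, 1, med)
  out <- sweep(v, 2L, scale, "/")
  res <- ft_replace(table, out)
  if (any(zero)) {
    flagged <- feature_ids(table)[zero]
    message("median_normalize: ", length(flagged),
            " feature(s) with zero median left unscaled: ",
            paste(utils::head(flagged, 5L), collapse = ", "),
            if (length(flagged) > 5L) ", ..." else "")
    attr(res, "unscaled_features") <- flagged
  }
  res
}

#' Drop a single feature from a table
#'
#' @param table A [feature_table()].
#' @param feature_id Identifier of the feature to remove (e.g. the
#'   administered drug itself, which trivially separates the groups).
#' @return The table without that column.
#' @export
remove_feature <- function(table, feature_id) {
  keep <- feature_ids(table) != feature_id
  if (all(keep))
    mvc_error("unknown_feature_error",
              paste0("feature not present in table: ", feature_id))
  ft_replace(table, table$values[, keep, drop = FALSE])
}

#' Aggregate ASV-level counts to genus level
#'
#' Sums counts of all amplicon sequence variants mapping to the same
#' genus label; per-sample totals are conserved exactly.
#'
#' @param table A counts [feature_table()] with ASV columns.
#' @param taxonomy Named character vector (names = ASV ids, values =
#'   genus labels; `"unassigned"` is a valid label) or a two-column data
#'   frame `(asv_id, genus)`.
#' @return Counts table with one column per genus, columns sorted by
#'   genus label.
#' @export
aggregate_to_genus <- function(table, taxonomy) {
  if (is.data.frame(taxonomy)) {
    mvc_assert(ncol(taxonomy) >= 2L, "parse_error",
               "taxonomy data frame needs columns (asv_id, genus)")
    taxonomy <- stats::setNames(as.character(taxonomy[[2L]]),
                                trimws(as.character(taxonomy[[1L]])))
  }
  asv <- feature_ids(table)
  miss <- setdiff(asv, names(taxonomy))
  if (length(miss))
    mvc_error("missing_taxonomy_error",
              paste0("ASV(s) missing from taxonomy: ",
                     paste(utils::head(miss, 5L), collapse = ", "),
                     if (length(miss) > 5L) ", ..." else ""))
  genus <- factor(taxonomy[asv], levels = sort(unique(taxonomy[asv])))
  agg <- t(rowsum(t(table$values), group = genus))
  colnames(agg) <- levels(genus)
  ft_replace(table, agg, view_kind = table$view_kind)
}

#' Remove rarely observed features
#'
#' Keeps features with a strictly positive value in at least
#' `min_samples` samples. The default of 6 removes features present in 5
#' or fewer samples.
#'
#' @param table Counts or relative-abundance [feature_table()].
#' @param min_samples Minimum number of samples a feature must be
#'   observed in.
#' @return Filtered table.
#' @export
prevalence_filter <- function(table, min_samples = 6L) {
  mvc_assert(min_samples >= 1L, "config_error", "min_samples must be >= 1")
  if (min_samples > n_samples(table))
    mvc_error("config_error",
              sprintf("min_samples (%d) exceeds the number of samples (%d)",
                      min_samples, n_samples(table)))
  prev <- colSums(table$values > 0)
  ft_replace(table, table$values[, prev >= min_samples, drop = FALSE])
}

#' Convert counts to within-sample relative abundance
#'
#' @param table Counts [feature_table()] with positive sample totals.
#' @return Table whose rows sum to 1, `view_kind = "relative_abundance"`.
#' @export
relative_abundance <- function(table) {
  tot <- rowSums(table$values)
  if (any(tot <= 0))
    mvc_error("zero_sample_error",
              paste0("sample(s) with zero total: ",
                     paste(sample_ids(table)[tot <= 0], collapse = ", ")))
  ft_replace(table, sweep(table$values, 1L, tot, "/"),
             view_kind = "relative_abundance")
}

#' Per-subject day-10 minus day-0 differences
#'
#' Collapses paired samples to one row per subject holding the
#' post-treatment minus baseline change, removing subject-level baseline
#' variation. Subjects lacking either day are dropped with a message.
#'
#' @param table A [feature_table()] whose sample ids appear in `design`.
#' @param design A [study_design()].
#' @return `feature_table` with rows named by subject id,
#'   `view_kind = "differences"`.
#' @export
paired_difference <- function(table, design) {
  sid <- sample_ids(table)
  d <- design[design$sample_id %in% sid, , drop = FALSE]
  subjects <- unique(d$subject_id)
  have0 <- subjects %in% d$subject_id[d$day == 0L]
  have10 <- subjects %in% d$subject_id[d$day == 10L]
  complete <- subjects[have0 & have10]
  dropped <- setdiff(subjects, complete)
  if (length(dropped))
    message("paired_difference: dropping subject(s) without both days: ",
            paste(dropped, collapse = ", "))
  if (length(complete) == 0L)
    mvc_error("pairing_error", "no subject has both a day-0 and a day-10 sample")
  s0 <- d$sample_id[match(paste(complete, 0L), paste(d$subject_id, d$day))]
  s10 <- d$sample_id[match(paste(complete, 10L), paste(d$subject_id, d$day))]
  diff <- table$values[s10, , drop = FALSE] - table$values[s0, , drop = FALSE]
  rownames(diff) <- complete
  ft_replace(table, diff, view_kind = "differences")
}

#' Log2 counts-per-million transform
#'
#' `log2(1e6 * count / sample_total + 1)` per entry; a zero count maps to
#' 0 exactly and rescaling a sample's library size leaves its values
#' unchanged.
#'
#' @param table Counts [feature_table()] with positive sample totals.
#' @return Transformed table, `view_kind = "generic"`.
#' @export
log_cpm <- function(table) {
  tot <- rowSums(table$values)
  if (any(tot <= 0))
    mvc_error("zero_sample_error",
              paste0("sample(s) with zero total: ",
                     paste(sample_ids(table)[tot <= 0], collapse = ", ")))
  ft_replace(table, log2(sweep(table$values, 1L, tot, "/") * 1e6 + 1),
             view_kind = "generic")
}

# population-sd standardization of a bare matrix; zero-variance columns
# become all-zero. Returns list(values, center, scale, constant).
std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2))
  constant <- sd == 0
  list(center = mu, scale = ifelse(constant, 1, sd), constant = constant)
}

std_apply <- function(X, s) {
  out <- sweep(sweep(X, 2L, s$center, "-"), 2L, s$scale, "/")
  if (any(s$constant)) out[, s$constant] <- 0
  out
}

#' Standardize features to mean 0, standard deviation 1
#'
#' Uses the population standard deviation (denominator n). Constant
#' features are set to all-zero and listed in the
#' `"constant_features"` attribute.
#'
#' @param table A [feature_table()] with at least 2 samples.
#' @return Standardized table, `view_kind = "generic"`.
#' @export
standardize_columns <- function(table) {
  mvc_assert(n_samples(table) >= 2L, "config_error",
             "standardization needs at least 2 samples")
  s <- std_fit(table$values)
  res <- ft_replace(table, std_apply(table$values, s), view_kind = "generic")
  if (any(s$constant))
    attr(res, "constant_features") <- feature_ids(table)[s$constant]
  res
}
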