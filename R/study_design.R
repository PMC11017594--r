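#' Study design: subjects, groups, sampling days
#'
#' Per-sample metadata defining the two study arms and the paired
#' baseline (day 0) / end-of-treatment (day 10) sampling. Group may be
#' given as 0/1 or as "control"/"treated" (mapped to 0/1).
#'
#' @param df Data frame with columns `sample_id`, `subject_id`, `group`,
#'   `day`.
#' @return A `study_design` data frame with `group` as integer 0/1 and
#'   `day` as integer.
#' @examples
#' study_design(data.frame(
#'   sample_id = c("a0", "a1", "b0", "b1"),
#'   subject_id = c("a", "a", "b", "b"),
#'   group = c(0, 0, 1, 1), day = c(0, 10, 0, 10)))
#' @export
study_design <- function(df) {
  need <- c("sample_id", "subject_id", "group", "day")
  mvc_assert(all(need %in% names(df)), "parse_error",
             paste("study design requires columns:", paste(need, collapse = ", ")))
  df <- as.data.frame(df)[need]
  df$sample_id <- trimws(as.character(df$sample_id))
  df$subject_id <- trimws(as.character(df$subject_id))
  g <- df$group
  if (is.character(g) || is.factor(g)) {
    g <- trimws(tolower(as.character(g)))
    mvc_assert(all(g %in% c("control", "treated", "0", "1")), "parse_error",
               "group must be 0/1 or control/treated")
    g <- ifelse(g %in% c("control", "0"), 0L, 1L)
  }
  df$group <- as.integer(g)
  df$day <- as.integer(df$day)
  mvc_assert(all(df$group %in% c(0L, 1L)), "parse_error", "group must be 0 or 1")
  mvc_assert(all(df$day %in% c(0L, 10L)), "parse_error", "day must be 0 or 10")
  if (anyDuplicated(df$sample_id))
    mvc_error("duplicate_id_error", "duplicate sample_id in study design")
  key <- paste(df$subject_id, df$day)
  if (anyDuplicated(key))
    mvc_error("duplicate_id_error", "a (subject, day) pair appears more than once")
  mvc_assert(length(unique(df$group)) == 2L, "degenerate_labels_error",
             "both groups must be present in the study design")
  grp_by_subj <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  mvc_assert(all(grp_by_subj == 1L), "parse_error",
             "a subject must belong to exactly one group")
  class(df) <- c("study_design", "data.frame")
  df
}

#' Read a study design table
#'
#' @param path Delimited text file (`.tsv` tab, `.csv` comma) with a
#'   header row naming `sample_id`, `subject_id`, `group`, `day`.
#' @return A [study_design()] object.
#' @export
read_study_design <- function(path) {
  df <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  study_design(df)
}

# group label (0/1) for an identifier that may be a sample_id or a subject_id
design_labels <- function(design, ids) {
  lab <- design$group[match(ids, design$sample_id)]
  miss <- is.na(lab)
  if (any(miss)) {
    subj <- match(ids[miss], design$subject_id)
    lab[miss] <- design$group[subj]
  }
  if (anyNA(lab))
    mvc_error("alignment_error",
              paste0("identifiers absent from study design: ",
                     paste(ids[is.na(lab)], collapse = ", ")))
  as.integer(lab)
}

#' Align views on their common samples
#'
#' Restricts every view to the samples present in all views, in a single
#' shared order, and derives binary labels from the study design.
#' Identifiers may be sample ids (raw tables) or subject ids
#' (subject-level tables such as paired differences).
#'
#' @param views Named list of [feature_table()] objects.
#' @param design A [study_design()].
#' @return An `aligned_dataset`: list with `views` (all sharing one
#'   sample ordering), `labels` (integer 0/1) and `design`.
#' @export
align_views <- function(views, design) {
  mvc_assert(is.list(views) && length(views) >= 1L, "config_error",
             "views must be a non-empty named list of feature tables")
  if (is.null(names(views)) || any(!nzchar(names(views))))
    mvc_error("config_error", "every view must be named")
  common <- Reduce(intersect, lapply(views, sample_ids))
  if (length(common) == 0L)
    mvc_error("alignment_error", "no samples are shared by all views")
  # keep the first view's ordering, restricted to the intersection
  common <- sample_ids(views[[1L]])[sample_ids(views[[1L]]) %in% common]
  labels <- design_labels(design, common)
  if (length(unique(labels)) < 2L)
    mvc_error("degenerate_labels_error",
              "only one group remains after aligning samples across views")
  views <- lapply(views, function(v) ft_replace(v, v$values[common, , drop = FALSE]))
  structure(list(views = views, labels = labels, design = design),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("aligned_dataset: %d samples, %d view(s) [%s], groups %d/%d\n",
              length(x$labels), length(x$views),
              paste(names(x$views), collapse = ", "),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}
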