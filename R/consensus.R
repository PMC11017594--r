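# Final consensus rule: features selected by screening, the sparse
# discriminant and the joint model form the core set; the report is
# augmented with (1) features whose absolute correlation with the
# top-loading discriminant feature exceeds a threshold and (2) the top
# fraction of joint-model selections by loading magnitude. Every entry
# carries a provenance tag, with priority
# selected_by_all > correlate_of_top > jaca_top_fraction.

#' Three-way intersection of method selections
#'
#' @param mvsis_top,discriminant_set,joint_set Character vectors of
#'   feature ids from one view's feature universe.
#' @return Sorted character vector of features chosen by all methods.
#' @export
intersect_selections <- function(mvsis_top, discriminant_set, joint_set) {
  sort(Reduce(intersect, list(as.character(mvsis_top),
                              as.character(discriminant_set),
                              as.character(joint_set))))
}

#' Build the consensus report for one view
#'
#' Starting from the core set, adds (1) non-anchor features whose
#' absolute Pearson correlation with the top-|loading| discriminant
#' feature exceeds `corr_threshold`, computed on the same matrix the
#' discriminant was fit to, and (2) the `ceiling(m * top_fraction)`
#' joint-model selections of largest absolute loading (m = joint
#' selection size; ties broken by loading magnitude then feature id).
#' Duplicate candidates keep the highest-priority provenance.
#'
#' @param core Character vector from [intersect_selections()].
#' @param discriminant_fit A `discriminant_fit` for this view.
#' @param joint_fit A `joint_fit`; the view is identified by `view`.
#' @param table The [feature_table()] (or matrix) the discriminant was
#'   fit on, used for the correlation criterion.
#' @param view Name of this view inside `joint_fit`.
#' @param corr_threshold Absolute-correlation cutoff for criterion (1).
#' @param top_fraction Fraction of joint selections kept by criterion (2).
#' @param screen_set Optional screening carry-forward set, echoed in the
#'   report.
#' @return A `consensus_report`: `view`, `entries` (feature, provenance,
#'   anchor, r, jaca_rank), `core`, echoed `method_sets`, `params`.
#' @export
augment <- function(core, discriminant_fit, joint_fit, table, view,
                    corr_threshold = 0.95, top_fraction = 1 / 3,
                    screen_set = NULL) {
  mvc_assert(is.numeric(corr_threshold) && length(corr_threshold) == 1L,
             "config_error", "corr_threshold must be a scalar")
  mvc_assert(is.numeric(top_fraction) && top_fraction >= 0 && top_fraction <= 1,
             "config_error", "top_fraction must lie in [0, 1]")
  mvc_assert(view %in% names(joint_fit$w), "config_error",
             paste0("view '", view, "' not present in joint fit"))
  core <- sort(as.character(core))

  entries <- data.frame(feature = core,
                        provenance = rep("selected_by_all", length(core)),
                        anchor = rep(NA_character_, length(core)),
                        r = rep(NA_real_, length(core)),
                        jaca_rank = rep(NA_integer_, length(core)),
                        stringsAsFactors = FALSE)

  # (1) correlates of the top discriminant feature
  v <- discriminant_fit$v
  if (length(discriminant_fit$selected)) {
    sel <- discriminant_fit$selected
    ord <- order(-abs(v[sel]), sel)
    anchor <- sel[ord[1L]]
    cors <- correlated_expansion(table, anchor, threshold = corr_threshold)
    if (length(cors)) {
      add <- !(names(cors) %in% entries$feature)
      if (any(add))
        entries <- rbind(entries, data.frame(
          feature = names(cors)[add], provenance = "correlate_of_top",
          anchor = anchor, r = as.numeric(cors[add]),
          jaca_rank = NA_integer_, stringsAsFactors = FALSE))
    }
  } else {
    message("augment: empty discriminant selection; correlation criterion skipped")
  }

  # (2) top fraction of joint selections by |loading|
  wd <- joint_fit$w[[view]]
  jsel <- names(wd)[wd != 0]
  m <- length(jsel)
  if (m == 0L && top_fraction > 0) {
    message("augment: empty joint selection; loading criterion contributes nothing")
  } else if (m > 0L) {
    ord <- order(-abs(wd[jsel]), jsel)
    ranked <- jsel[ord]
    k <- ceiling(m * top_fraction)
    topj <- ranked[seq_len(k)]
    add <- !(topj %in% entries$feature)
    if (any(add))
      entries <- rbind(entries, data.frame(
        feature = topj[add], provenance = "jaca_top_fraction",
        anchor = NA_character_, r = NA_real_,
        jaca_rank = match(topj[add], ranked), stringsAsFactors = FALSE))
  }

  entries <- entries[order(match(entries$provenance,
                                 c("selected_by_all", "correlate_of_top",
                                   "jaca_top_fraction")),
                           entries$feature), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(view = view, entries = entries, core = core,
                 method_sets = list(
                   screen = if (is.null(screen_set)) character(0) else
                     as.character(screen_set),
                   discriminant = as.character(discriminant_fit$selected),
                   joint = as.character(jsel)),
                 params = list(corr_threshold = corr_threshold,
                               top_fraction = top_fraction)),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("consensus_report (%s): %d feature(s), core %d\n",
              x$view, nrow(x$entries), length(x$core)))
  print(x$entries)
  invisible(x)
}

#' Recovery metrics against a known truth set
#'
#' Sensitivity = |selected & truth| / |truth|;
#' FDR = |selected \ truth| / max(|selected|, 1) (an empty selection has
#' FDR 0 by convention).
#'
#' @param report_or_set A `consensus_report` (its entry features are
#'   used) or a character vector of feature ids.
#' @param truth Non-empty character vector of true feature ids.
#' @return List with `sensitivity` and `fdr`.
#' @export
truth_metrics <- function(report_or_set, truth) {
  sel <- if (inherits(report_or_set, "consensus_report"))
    report_or_set$entries$feature else as.character(report_or_set)
  truth <- as.character(truth)
  mvc_assert(length(truth) > 0L, "config_error",
             "truth set must be non-empty for sensitivity")
  sel <- unique(sel)
  list(sensitivity = length(intersect(sel, truth)) / length(truth),
       fdr = length(setdiff(sel, truth)) / max(length(sel), 1L))
}

# ---- serialization --------------------------------------------------------

report_to_list.consensus_report <- function(report) {
  e <- report$entries
  list(view = report$view,
       entries = lapply(seq_len(nrow(e)), function(i)
         list(feature = e$feature[i], provenance = e$provenance[i],
              anchor = e$anchor[i], r = e$r[i], jaca_rank = e$jaca_rank[i])),
       core = as.list(report$core),
       method_sets = lapply(report$method_sets, as.list),
       params = report$params)
}

list_to_consensus <- function(l) {
  ent <- l$entries
  entries <- data.frame(
    feature = vapply(ent, function(x) as.character(x$feature), character(1)),
    provenance = vapply(ent, function(x) as.character(x$provenance), character(1)),
    anchor = vapply(ent, function(x)
      if (is.null(x$anchor)) NA_character_ else as.character(x$anchor), character(1)),
    r = vapply(ent, function(x)
      if (is.null(x$r)) NA_real_ else as.numeric(x$r), numeric(1)),
    jaca_rank = vapply(ent, function(x)
      if (is.null(x$jaca_rank)) NA_integer_ else as.integer(x$jaca_rank), integer(1)),
    stringsAsFactors = FALSE)
  if (length(ent) == 0L)
    entries <- data.frame(feature = character(0), provenance = character(0),
                          anchor = character(0), r = numeric(0),
                          jaca_rank = integer(0), stringsAsFactors = FALSE)
  structure(list(view = as.character(l$view), entries = entries,
                 core = chr(l$core),
                 method_sets = lapply(l$method_sets, chr),
                 params = list(corr_threshold = as.numeric(l$params$corr_threshold),
                               top_fraction = as.numeric(l$params$top_fraction))),
            class = "consensus_report")
}

report_tsv.consensus_report <- function(report) {
  report$entries
}
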