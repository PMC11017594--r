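# End-to-end workflow: view-specific preprocessing -> alignment ->
# MV screening -> per-view sparse discriminant with LOO-selected
# penalty -> joint multi-view fit with LOO-selected penalties ->
# per-view consensus reports. Deterministic given inputs and config;
# optionally writes per-stage artifacts plus a manifest.

#' Pipeline configuration
#'
#' @param top_k Screening carry-forward size per view (capped at the
#'   view's feature count).
#' @param alpha Joint-model mixing weight in `[0, 1)`.
#' @param corr_threshold Consensus correlation-augmentation cutoff.
#' @param top_fraction Consensus fraction of joint selections kept.
#' @param min_prevalence Prevalence filter for compositional views.
#' @param mgsda_grid,jaca_grid Penalty-grid sizes of the two solvers.
#' @param policy Discriminant model-selection policy, see
#'   [select_model()].
#' @param recipes Named list mapping each view to the ordered
#'   preprocessing steps to apply, from: `"median_normalize"`,
#'   `"prevalence_filter"`, `"relative_abundance"`,
#'   `"paired_difference"`, `"log_cpm"`. Defaults reproduce the study
#'   workflow for views named metabolome / microbiome / exfoliome.
#' @param drop_features Named list: features to remove from a view
#'   before anything else (e.g. the administered drug itself).
#' @param out_dir Optional directory for per-stage artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(top_k = 300L, alpha = 0.5, corr_threshold = 0.95,
                            top_fraction = 1 / 3, min_prevalence = 6L,
                            mgsda_grid = 50L, jaca_grid = 20L,
                            policy = "min_mcr_sparsest",
                            recipes = list(
                              metabolome = c("median_normalize", "paired_difference"),
                              microbiome = c("prevalence_filter", "relative_abundance",
                                             "paired_difference"),
                              exfoliome = "log_cpm"),
                            drop_features = list(),
                            out_dir = NULL) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha >= 0 && alpha < 1))
    mvc_error("config_error", "alpha must lie in [0, 1)")
  mvc_assert(top_k >= 1L, "config_error", "top_k must be >= 1")
  mvc_assert(corr_threshold > 0, "config_error", "corr_threshold must be positive")
  mvc_assert(top_fraction >= 0 && top_fraction <= 1, "config_error",
             "top_fraction must lie in [0, 1]")
  mvc_assert(mgsda_grid >= 1L && jaca_grid >= 1L, "config_error",
             "grid sizes must be >= 1")
  structure(list(top_k = as.integer(top_k), alpha = alpha,
                 corr_threshold = corr_threshold, top_fraction = top_fraction,
                 min_prevalence = as.integer(min_prevalence),
                 mgsda_grid = as.integer(mgsda_grid),
                 jaca_grid = as.integer(jaca_grid),
                 policy = policy, recipes = recipes,
                 drop_features = drop_features, out_dir = out_dir),
            class = "pipeline_config")
}

apply_recipe <- function(table, steps, design, config) {
  for (s in steps) {
    table <- switch(s,
      median_normalize = median_normalize(table),
      prevalence_filter = prevalence_filter(table, config$min_prevalence),
      relative_abundance = relative_abundance(table),
      paired_difference = paired_difference(table, design),
      log_cpm = log_cpm(table),
      mvc_error("config_error", paste0("unknown preprocessing step: ", s)))
  }
  table
}

# subject-level ids for a table that kept raw sample ids (e.g. the
# day-10-only count view): collapse "<subject>_d10"-style ids to subjects
to_subject_rows <- function(table, design) {
  idx <- match(sample_ids(table), design$sample_id)
  if (anyNA(idx)) return(table) # already subject-level
  v <- table$values
  rownames(v) <- design$subject_id[idx]
  ft_replace(table, v, view_kind = table$view_kind)
}

#' Run the full consensus feature-selection pipeline
#'
#' Executes preprocessing, screening, the sparse discriminant, the
#' joint multi-view model and the consensus rule in order, on a
#' [simulate_multiomic()] study or an equivalent list with `views`
#' (named feature tables) and `design`. Identical inputs and config
#' give identical outputs; when `config$out_dir` is set, every stage's
#' report is written (JSON + TSV) together with a `manifest.json`
#' echoing the config.
#'
#' @param study A `multiomic_study`, or a list with elements `views`
#'   and `design`.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: `consensus` (per-view reports),
#'   `features` (combined entry table with a view column), `screening`,
#'   `mgsda` (per-view annotated fits and paths), `jaca` fit,
#'   `score_correlations`, `labels`, `aligned` tables and the config.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  mvc_assert(inherits(config, "pipeline_config"), "config_error",
             "config must come from pipeline_config()")
  mvc_assert(is.list(study) && !is.null(study$views) && !is.null(study$design),
             "config_error", "study must carry views and a design")
  design <- if (inherits(study$design, "study_design")) study$design else
    study_design(study$design)
  views <- study$views
  mvc_assert(all(names(views) %in% names(config$recipes)), "config_error",
             "every view needs a preprocessing recipe")

  # stage 1: preprocessing
  for (vn in names(config$drop_features))
    for (f in config$drop_features[[vn]])
      views[[vn]] <- remove_feature(views[[vn]], f)
  processed <- lapply(names(views), function(vn)
    to_subject_rows(apply_recipe(views[[vn]], config$recipes[[vn]], design, config),
                    design))
  names(processed) <- names(views)

  # stage 2: alignment on common subjects
  aligned <- align_views(processed, design)
  labels <- aligned$labels

  # stage 3: MV screening, carry forward top-k per view
  screening <- lapply(aligned$views, function(v)
    mvsis_screen(v, labels, top_k = min(config$top_k, n_features(v))))
  screened <- mapply(function(v, s)
    ft_replace(v, v$values[, s$top_set, drop = FALSE], view_kind = v$view_kind),
    aligned$views, screening, SIMPLIFY = FALSE)

  # stage 4: per-view sparse discriminant with LOO-selected penalty
  mgsda <- lapply(screened, function(v) {
    path <- lambda_path_loocv(v$values, labels, grid_size = config$mgsda_grid)
    list(path = path, fit = select_model(path, policy = config$policy))
  })

  # stage 5: joint multi-view model with LOO-selected penalties
  jaca <- jaca_loocv(lapply(screened, function(v) v$values), labels,
                     alpha = config$alpha, grid_size = config$jaca_grid)
  score_cor <- if (all(vapply(jaca$scores, stats::sd, numeric(1)) > 0)) {
    score_correlations(jaca)
  } else {
    message("run_pipeline: degenerate joint scores; score correlations are NA")
    vn <- names(jaca$w)
    prs <- utils::combn(length(vn), 2)
    list(correlations = data.frame(view_1 = vn[prs[1L, ]], view_2 = vn[prs[2L, ]],
                                   r = NA_real_, stringsAsFactors = FALSE),
         projections = list())
  }

  # stage 6: consensus per view
  consensus <- lapply(names(screened), function(vn) {
    core <- intersect_selections(screening[[vn]]$top_set,
                                 mgsda[[vn]]$fit$selected,
                                 jaca$selected[[vn]])
    augment(core, mgsda[[vn]]$fit, jaca, screened[[vn]], view = vn,
            corr_threshold = config$corr_threshold,
            top_fraction = config$top_fraction,
            screen_set = screening[[vn]]$top_set)
  })
  names(consensus) <- names(screened)

  features <- do.call(rbind, lapply(consensus, function(r) {
    if (nrow(r$entries) == 0L) return(NULL)
    cbind(view = r$view, r$entries, stringsAsFactors = FALSE)
  }))
  if (is.null(features))
    features <- data.frame(view = character(0), feature = character(0),
                           provenance = character(0), anchor = character(0),
                           r = numeric(0), jaca_rank = integer(0),
                           stringsAsFactors = FALSE)
  rownames(features) <- NULL

  result <- structure(list(consensus = consensus, features = features,
                           screening = screening, mgsda = mgsda, jaca = jaca,
                           score_correlations = score_cor, labels = labels,
                           aligned = screened, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  for (vn in names(result$mgsda)) {
    write_report(result$mgsda[[vn]]$path, file.path(out_dir, paste0("mgsda_", vn, ".json")))
    stages <- c(stages, paste0("mgsda_", vn))
  }
  write_report(result$jaca, file.path(out_dir, "jaca.json"))
  stages <- c(stages, "jaca")
  for (vn in names(result$consensus)) {
    write_report(result$consensus[[vn]], file.path(out_dir, paste0("consensus_", vn, ".json")))
    stages <- c(stages, paste0("consensus_", vn))
  }
  utils::write.table(result$features, file.path(out_dir, "consensus_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$score_correlations$correlations,
                     file.path(out_dir, "score_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- result$config
  cfg$out_dir <- NULL
  manifest <- list(stages = as.list(c("preprocess", "align", "screen", stages)),
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (vn in names(x$consensus))
    cat(sprintf("  %s: %d consensus feature(s) (core %d), MGSDA LOO MCR %.3f\n",
                vn, nrow(x$consensus[[vn]]$entries),
                length(x$consensus[[vn]]$core), x$mgsda[[vn]]$fit$loo_mcr))
  cat(sprintf("  joint model LOO MCR %.3f\n", x$jaca$loocv_mcr))
  print(x$score_correlations$correlations)
  invisible(x)
}
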