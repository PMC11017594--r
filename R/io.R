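# Delimited-table and report input/output.
#
# Tables are plain text: header row = feature ids, first column = sample
# ids (samples_in_rows orientation). Delimiter follows the extension:
# .csv is comma, everything else tab. Missing or non-numeric cells are
# errors, never silent zeros.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a sample-by-feature table from delimited text
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file with
#'   one header row and identifiers in the first column.
#' @param orientation `"samples_in_rows"` (default) if rows are samples,
#'   `"features_in_rows"` if the file stores the transpose; the returned
#'   table is always samples-in-rows.
#' @param view_kind Declared measurement kind, see [feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows", "features_in_rows"),
                               view_kind = "generic") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) mvc_error("io_error", paste0("file not found: ", path))
  raw <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", na.strings = character(0))
  mvc_assert(ncol(raw) >= 2L && nrow(raw) >= 1L, "parse_error",
             "table must have an identifier column and at least one data column")
  row_ids <- trimws(raw[[1L]])
  col_ids <- trimws(colnames(raw)[-1L])
  vals <- matrix(NA_real_, nrow(raw), length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad))
      mvc_error("parse_error",
                sprintf("non-numeric value '%s' at row '%s', column '%s'",
                        cell[bad[1L]], row_ids[bad[1L]], col_ids[j]))
    vals[, j] <- num
  }
  if (orientation == "features_in_rows") vals <- t(vals)
  feature_table(vals, view_kind)
}

#' Write a feature table as delimited text
#'
#' @param table A [feature_table()].
#' @param path Output path; delimiter chosen from the extension.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = sample_ids(table), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mvc_error("io_error", paste0("cannot write: ", path))
  invisible(path)
}

# ---- report serialization -------------------------------------------------
# Each report class round-trips through a plain list (JSON) and also
# emits a flat per-feature/per-lambda TSV next to the JSON file.

report_to_list <- function(report) UseMethod("report_to_list")
report_tsv <- function(report) UseMethod("report_tsv")

report_type <- function(report) {
  if (inherits(report, "consensus_report")) return("consensus_report")
  if (inherits(report, "path_fit")) return("path_fit")
  if (inherits(report, "joint_fit")) return("joint_fit")
  mvc_error("config_error", "write_report supports consensus_report, path_fit, joint_fit")
}

#' Write an analysis report as JSON plus a per-row TSV
#'
#' Serializes a [build_consensus()] report, a [lambda_path_loocv()] path
#' or a [fit_jaca()]/[jaca_loocv()] fit. The JSON form is lossless
#' ([read_report()] reproduces the object); the TSV is a flat view for
#' spreadsheets and plotting (one row per feature, per lambda, or per
#' loading, respectively).
#'
#' @param report Report object.
#' @param path Output path for the JSON file; the TSV is written next to
#'   it with extension `.tsv`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  type <- report_type(report)
  lst <- c(list(type = type), report_to_list(report))
  ok <- tryCatch({
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mvc_error("io_error", paste0("cannot write: ", path))
  tsv <- sub("\\.[A-Za-z0-9]+$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(report_tsv(report), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The reconstructed report object.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) mvc_error("io_error", paste0("file not found: ", path))
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  type <- lst$type
  lst$type <- NULL
  switch(type,
         consensus_report = list_to_consensus(lst),
         path_fit = list_to_path_fit(lst),
         joint_fit = list_to_joint_fit(lst),
         mvc_error("parse_error", paste0("unknown report type: ", type)))
}

named_to_list <- function(x) as.list(x)

list_to_named <- function(x) {
  out <- unlist(lapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v)))
  if (is.null(out)) out <- numeric(0)
  nms <- names(x)
  stats::setNames(as.numeric(out), nms)
}

chr <- function(x) if (is.null(x)) character(0) else as.character(unlist(x))
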