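# CSV/JSON file interfaces. Score tables are UTF-8 comma-separated files
# with header `sample_id,<class labels...>`; class identity is by column
# label, not position, so a column swap in one model file cannot silently
# corrupt a run.

read_score_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop(path, ": first column must be 'sample_id'", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(path, ": duplicate sample_id ",
         df$sample_id[anyDuplicated(df$sample_id)], call. = FALSE)
  num <- df[-1]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop(path, ": non-numeric confidence column(s): ",
         paste(names(num)[bad], collapse = ", "), call. = FALSE)
  m <- as.matrix(num)
  rownames(m) <- as.character(df$sample_id)
  m
}

#' Read an ensemble score bank from CSV files
#'
#' Reads M per-classifier score tables plus a ground-truth label table and
#' aligns them by `sample_id`. Sample order follows the labels file; class
#' order follows the first score file's header, and every file must carry
#' exactly the same class header. A sample missing from any score file is
#' an error naming the id.
#'
#' @param paths Character vector of M score-table CSV paths (header
#'   `sample_id,<class...>`).
#' @param labels_path CSV with columns `sample_id,label`.
#' @param classifier_names Optional model names (default: file base names).
#' @return List with `scores` (a [score_set()]) and `truth` (character
#'   vector aligned to `scores$sample_ids`).
#' @export
read_score_bank <- function(paths, labels_path, classifier_names = NULL) {
  stopifnot(length(paths) >= 1)
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(labels)))
    stop(labels_path, ": needs columns sample_id and label", call. = FALSE)
  labels$sample_id <- as.character(labels$sample_id)
  if (anyDuplicated(labels$sample_id))
    stop(labels_path, ": duplicate sample_id", call. = FALSE)

  tables <- lapply(paths, read_score_table)
  class_labels <- colnames(tables[[1]])
  for (i in seq_along(tables)) {
    if (!identical(colnames(tables[[i]]), class_labels))
      stop(paths[i], ": class header differs from ", paths[1], call. = FALSE)
    missing <- setdiff(labels$sample_id, rownames(tables[[i]]))
    if (length(missing) > 0)
      stop(paths[i], ": missing sample id(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    tables[[i]] <- tables[[i]][labels$sample_id, , drop = FALSE]
  }
  classifier_names <- classifier_names %||%
    tools::file_path_sans_ext(basename(paths))
  names(tables) <- classifier_names
  list(scores = score_set(tables, sample_ids = labels$sample_id,
                          class_labels = class_labels,
                          classifier_names = classifier_names),
       truth = labels$label)
}

#' Write a score bank to CSV files
#'
#' Inverse of [read_score_bank()]: writes `model_<i>.csv` per classifier
#' (or names derived from `classifier_names`) plus `labels.csv` into
#' `dir`. Used by the `simulate` subcommand.
#'
#' @param scores A [score_set()].
#' @param truth Optional true labels (writes `labels.csv` when given).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_score_bank <- function(scores, truth = NULL, dir = ".") {
  stopifnot(inherits(scores, "score_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(scores$matrices)) {
    df <- data.frame(sample_id = scores$sample_ids,
                     scores$matrices[[i]], check.names = FALSE)
    p <- file.path(dir, paste0(scores$classifier_names[i], ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(truth)) {
    p <- file.path(dir, "labels.csv")
    utils::write.csv(data.frame(sample_id = scores$sample_ids, label = truth),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write fusion predictions to CSV
#'
#' Columns: `sample_id`, `fused_label`, then one `fds_<class>` column per
#' class. Deterministic: no timestamps inside the file.
#'
#' @param result A `fusion_result` from [fuse()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(result, path) {
  stopifnot(inherits(result, "fusion_result"))
  fds <- result$fds
  colnames(fds) <- paste0("fds_", colnames(fds))
  df <- data.frame(sample_id = result$sample_ids,
                   fused_label = result$fused_label,
                   fds, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_to_list <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  list(
    accuracy = report$accuracy,
    macro = list(precision = report$macro_precision,
                 recall = report$macro_recall, f1 = report$macro_f1),
    weighted = list(precision = report$weighted_precision,
                    recall = report$weighted_recall, f1 = report$weighted_f1),
    per_class = report$per_class,
    confusion = list(labels = rownames(report$confusion),
                     counts = lapply(seq_len(nrow(report$confusion)),
                                     function(i) unname(report$confusion[i, ]))),
    rounding = report$rounding)
}

#' Write a JSON evaluation report
#'
#' Serializes an [classification_report()] result together with the
#' effective run configuration and the package version. Deterministic for
#' identical inputs and configuration.
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @param config Optional named list echoed under `"config"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, config = NULL) {
  out <- report_to_list(report)
  out$config <- config
  out$tool_version <- as.character(utils::packageVersion("fuzzfuse"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
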