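#' Construct a clinical data table
#'
#' The canonical in-memory dataset representation used by every stage of the
#' pipeline: a feature data frame (numeric and/or categorical columns), a
#' binary class label per row, and per-column type tags.
#'
#' @param features A data frame. Numeric columns are tagged `"numeric"`;
#'   character or factor columns are tagged `"categorical"` and stored as
#'   character. Missing cells are `NA`.
#' @param labels A vector of class tokens, one per row of `features`. Exactly
#'   two distinct tokens must occur and no label may be missing.
#' @param class_names Optional character vector of length 2 giving the two
#'   label tokens in order; the second token is the one mapped to class 1.
#'   Defaults to the sorted distinct labels, so e.g. `"0" < "1"` and
#'   `"die" < "live"`.
#' @param positive_class Token treated as the positive class by the metric
#'   suite. Defaults to the token mapped to class 1.
#' @return An object of class `data_table` with elements `features`,
#'   `labels`, `column_kinds`, `class_names` and `positive_class`.
#' @seealso [read_table()] to build one from a delimited file.
#' @export
data_table <- function(features, labels, class_names = NULL,
                       positive_class = NULL) {
  if (!is.data.frame(features)) stop("`features` must be a data frame")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (anyDuplicated(names(features)))
    stop("feature column names must be unique")
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stop("`labels` must have one entry per row")
  if (anyNA(labels)) stop("every row must carry a class label")
  tokens <- sort(unique(labels))
  if (length(tokens) != 2L)
    stop("exactly two distinct label tokens required, found ",
         length(tokens))
  if (is.null(class_names)) class_names <- tokens
  class_names <- as.character(class_names)
  if (length(class_names) != 2L || !setequal(class_names, tokens))
    stop("`class_names` must name the two label tokens")
  kinds <- vapply(features, function(col) {
    if (is.numeric(col)) "numeric" else "categorical"
  }, character(1))
  for (j in which(kinds == "categorical"))
    features[[j]] <- as.character(features[[j]])
  if (is.null(positive_class)) positive_class <- class_names[2L]
  if (!positive_class %in% class_names)
    stop("`positive_class` must be one of the class tokens")
  structure(
    list(features = features, labels = labels, column_kinds = kinds,
         class_names = class_names, positive_class = positive_class),
    class = "data_table")
}

#' @export
print.data_table <- function(x, ...) {
  cat(sprintf("<data_table> %d rows x %d features (%d numeric, %d categorical)\n",
              nrow(x$features), ncol(x$features),
              sum(x$column_kinds == "numeric"),
              sum(x$column_kinds == "categorical")))
  tab <- table(factor(x$labels, levels = x$class_names))
  cat(sprintf("  classes: %s=%d, %s=%d (positive: %s)\n",
              x$class_names[1], tab[1], x$class_names[2], tab[2],
              x$positive_class))
  invisible(x)
}

#' @export
dim.data_table <- function(x) dim(x$features)

n_rows <- function(table) nrow(table$features)
n_features <- function(table) ncol(table$features)

#' Subset a data table
#'
#' @param table A [data_table()].
#' @param rows,cols Row / feature-column indices (any standard subscript).
#'   `NULL` keeps everything.
#' @return A `data_table` with the selected rows and feature columns.
#' @export
subset_table <- function(table, rows = NULL, cols = NULL) {
  stopifnot(inherits(table, "data_table"))
  feats <- table$features
  labs <- table$labels
  if (!is.null(rows)) {
    feats <- feats[rows, , drop = FALSE]
    labs <- labs[rows]
    rownames(feats) <- NULL
  }
  if (!is.null(cols)) feats <- feats[, cols, drop = FALSE]
  data_table(feats, labs, class_names = table$class_names,
             positive_class = table$positive_class)
}

#' Describe the layout of a delimited dataset file
#'
#' @param label_column Name or index of the class column; `NULL` means the
#'   last column (the usual layout of UCI-style clinical files).
#' @param missing_tokens Strings read as missing cells. The default covers the
#'   empty string, the `"?"` marker used by the UCI hepatitis file, and `"NA"`.
#' @param delimiter Field separator; `","` for CSV, `"\t"` for TSV.
#' @return An object of class `column_schema`.
#' @export
column_schema <- function(label_column = NULL,
                          missing_tokens = c("", "?", "NA"),
                          delimiter = ",") {
  stopifnot(is.null(label_column) || length(label_column) == 1L,
            is.character(missing_tokens),
            is.character(delimiter), nchar(delimiter) == 1L)
  structure(list(label_column = label_column,
                 missing_tokens = missing_tokens,
                 delimiter = delimiter),
            class = "column_schema")
}

#' Read a delimited clinical dataset
#'
#' Parses a header-ed CSV/TSV file into a [data_table()]. A column is typed
#' numeric iff every non-missing cell parses as a number; anything else is
#' categorical. The label column is removed from the features and stored as
#' the per-row class token.
#'
#' @param path Path to the file.
#' @param schema A [column_schema()].
#' @return A [data_table()].
#' @export
read_table <- function(path, schema = column_schema()) {
  stopifnot(inherits(schema, "column_schema"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = schema$delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (nrow(raw) < 1L) stop("file has no data rows")
  for (j in seq_along(raw)) {
    col <- trimws(raw[[j]])
    col[col %in% schema$missing_tokens] <- NA_character_
    raw[[j]] <- col
  }
  lab <- schema$label_column
  if (is.null(lab)) {
    lab_idx <- ncol(raw)
  } else if (is.numeric(lab)) {
    lab_idx <- as.integer(lab)
    if (lab_idx < 1L || lab_idx > ncol(raw)) stop("label column out of range")
  } else {
    lab_idx <- match(lab, names(raw))
    if (is.na(lab_idx)) stop("label column not found: ", lab)
  }
  labels <- raw[[lab_idx]]
  if (anyNA(labels)) stop("missing values in the label column")
  if (length(unique(labels)) != 2L)
    stop("label column must contain exactly two distinct tokens, found ",
         length(unique(labels)))
  feats <- raw[, -lab_idx, drop = FALSE]
  if (ncol(feats) == 0L) stop("no feature columns besides the label")
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    num <- suppressWarnings(as.numeric(col))
    if (!any(is.na(num) & !is.na(col))) feats[[j]] <- num
  }
  data_table(feats, labels)
}

#' Write a data table to a delimited file
#'
#' Inverse of [read_table()]: features plus a final label column, with
#' missing cells written as empty fields.
#'
#' @param table A [data_table()].
#' @param path Output path.
#' @param label_name Header for the label column.
#' @param delimiter Field separator.
#' @export
write_table <- function(table, path, label_name = "class", delimiter = ",") {
  stopifnot(inherits(table, "data_table"))
  out <- table$features
  if (label_name %in% names(out))
    stop("label column name collides with a feature name")
  out[[label_name]] <- table$labels
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Write a structured JSON analysis report
#'
#' Serializes a pipeline or selection report. Refuses non-finite metric
#' values and empty feature selections so a written report is always a
#' complete, reproducible record.
#'
#' @param result A named list; if it has `metrics`, all must be finite
#'   numbers, and if it has `selected_features`, it must be non-empty.
#' @param path Output path for the JSON file.
#' @export
write_report <- function(result, path) {
  stopifnot(is.list(result))
  if (!is.null(result$metrics)) {
    vals <- unlist(result$metrics)
    if (!all(is.finite(vals)))
      stop("report metrics must be finite numbers")
  }
  if (!is.null(result$selected_features) &&
      length(result$selected_features) == 0L)
    stop("report has an empty selected-feature list")
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The report as a named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a method-comparison metrics table as TSV
#'
#' One row per method: instance and attribute counts plus the full metric
#' suite, the shape used to compare selection heuristics side by side.
#'
#' @param comparison A data frame as returned by [run_compare()].
#' @param path Output path.
#' @export
write_metrics_tsv <- function(comparison, path) {
  stopifnot(is.data.frame(comparison))
  utils::write.table(comparison, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
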