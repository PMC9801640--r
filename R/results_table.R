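#' Construct a metric-by-algorithm results table
#'
#' A plain numeric matrix with metric names on the rows and algorithm names
#' on the columns, the layout consumed by [average_ranks()],
#' [friedman_test()] and the pairwise Wilcoxon machinery.
#'
#' @param values Numeric matrix (N metrics x k algorithms).
#' @param metrics Row names.
#' @param algorithms Column names.
#' @return A matrix of class `results_table`.
#' @export
results_table <- function(values, metrics = rownames(values),
                          algorithms = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (anyNA(values)) stop("missing cells", call. = FALSE)
  if (is.null(metrics) || is.null(algorithms))
    stop("metric and algorithm names are required", call. = FALSE)
  dimnames(values) <- list(metrics, algorithms)
  class(values) <- c("results_table", class(values))
  values
}

#' Write a results table as CSV
#'
#' One `metric` name column followed by one column per algorithm. Values are
#' written as-is (no re-rounding), so fixture tables round-trip unchanged.
#'
#' @param tbl A [results_table()] or named numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(tbl, path) {
  df <- data.frame(metric = rownames(tbl), as.data.frame(unclass(tbl)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path CSV path; first column holds metric names.
#' @return A [results_table()].
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  results_table(m, metrics = df[[1L]], algorithms = colnames(df)[-1L])
}

#' Published benchmark tables shipped as fixtures
#'
#' Returns the verbatim printed ten-fold cross-validation results (percent
#' scale, one decimal) of the study this package follows: six metric rows
#' (Precision, Sensitivity, Specificity, F-measure, MCC, AUC) by thirteen
#' columns (the unsampled Original data plus twelve sampling algorithms), for
#' each of six classifiers on two clinical datasets. These are read-only
#' reference values used by the statistical-comparison examples and tests;
#' they are not recomputed.
#'
#' @param classifier One of `"c45"`, `"randomtree"`, `"reptree"`,
#'   `"random_forest"`, `"adaboost"`, `"bagging"`.
#' @param dataset One of `"missed_abortion"`, `"diabetes"`.
#' @return A 6 x 13 [results_table()].
#' @export
printed_results <- function(classifier = c("c45", "randomtree", "reptree",
                                           "random_forest", "adaboost",
                                           "bagging"),
                            dataset = c("missed_abortion", "diabetes")) {
  classifier <- match.arg(classifier)
  dataset <- match.arg(dataset)
  path <- system.file("extdata", "printed_tables",
                      paste0(classifier, "_", dataset, ".csv"),
                      package = "hybridsample", mustWork = TRUE)
  read_results_table(path)
}
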