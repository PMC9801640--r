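#' Construct a labeled binary dataset
#'
#' The core container used by every resampler and learner: a numeric feature
#' matrix with one binary label per row. The class with the strictly larger
#' count is the majority class; on an exact tie the lexicographically smaller
#' label is assigned the majority role and the dataset is flagged as balanced.
#'
#' @param features Numeric matrix or data frame (n rows, p columns). All
#'   values must be finite; no missing values are allowed.
#' @param labels Vector of length n with at most two distinct values.
#'   One-class tables are constructible but flagged degenerate.
#' @param positive_class Label treated as the "case" (disease) class when
#'   computing metrics. Defaults to the minority class.
#' @param label_name Name of the label column, used when writing CSV.
#' @return An object of class `labeled_dataset`: a list with elements
#'   `features`, `labels` (character), `feature_names`, `label_name`,
#'   `positive_class`, `n`, `p`.
#' @seealso [load_csv()], [class_counts()], [nearest_neighbors()]
#' @export
labeled_dataset <- function(features, labels, positive_class = NULL,
                            label_name = "class") {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features))
    stop("`features` must be a numeric matrix", call. = FALSE)
  if (anyNA(features) || any(!is.finite(features)))
    stop("`features` must be finite with no missing values", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stop("length(labels) must equal nrow(features)", call. = FALSE)
  lv <- sort(unique(labels))
  if (length(lv) > 2L)
    stop("more than two distinct labels: ", paste(lv, collapse = ", "),
         call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  if (is.null(positive_class)) {
    ## default positive class: the minority (on a tie the lexicographically
    ## smaller label takes the majority role, so the larger one is minority)
    if (length(lv) == 1L) positive_class <- lv
    else {
      cnt <- as.integer(table(factor(labels, levels = lv)))
      positive_class <- if (cnt[1L] < cnt[2L]) lv[1L] else lv[2L]
    }
  }
  positive_class <- as.character(positive_class)
  if (!positive_class %in% lv)
    stop("positive_class '", positive_class, "' is not a label value",
         call. = FALSE)
  structure(list(
    features = features,
    labels = labels,
    feature_names = colnames(features),
    label_name = label_name,
    positive_class = positive_class,
    n = nrow(features),
    p = ncol(features)
  ), class = "labeled_dataset")
}

#' Class counts and majority/minority roles
#'
#' @param ds A [labeled_dataset()].
#' @return A list with `majority`, `n_majority`, `minority`, `n_minority`,
#'   `balanced` (TRUE on an exact count tie) and `degenerate` (TRUE when only
#'   one class is present). On a tie the lexicographically smaller label takes
#'   the majority role, a deterministic convention.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  lv <- sort(unique(ds$labels))
  if (length(lv) == 1L) {
    return(list(majority = lv, n_majority = ds$n,
                minority = lv, n_minority = 0L,
                balanced = FALSE, degenerate = TRUE))
  }
  cnt <- as.integer(table(factor(ds$labels, levels = lv)))
  if (cnt[1L] == cnt[2L]) {
    maj <- 1L; balanced <- TRUE            # tie: smaller label is "majority"
  } else {
    maj <- which.max(cnt); balanced <- FALSE
  }
  min_ <- 3L - maj
  list(majority = lv[maj], n_majority = cnt[maj],
       minority = lv[min_], n_minority = cnt[min_],
       balanced = balanced, degenerate = FALSE)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat("<labeled_dataset> ", x$n, " rows x ", x$p, " features\n", sep = "")
  cat("  labels (", x$label_name, "): ", cc$majority, "=", cc$n_majority,
      " (majority) / ", cc$minority, "=", cc$n_minority, " (minority)",
      if (cc$balanced) " [balanced tie]", "\n", sep = "")
  cat("  positive class:", x$positive_class, "\n")
  invisible(x)
}

#' Read a labeled dataset from CSV
#'
#' Fixed dialect: comma-separated, UTF-8, one header row, decimal point.
#' Every non-label cell must parse as a number; the first offending cell is
#' reported by row and column.
#'
#' @param path CSV file path.
#' @param label_column Name of the label column in the header.
#' @param positive_class Optional label value treated as the case class.
#' @return A [labeled_dataset()].
#' @export
load_csv <- function(path, label_column, positive_class = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in header", call. = FALSE)
  feat_cols <- setdiff(names(df), label_column)
  if (length(feat_cols) == 0L) stop("no feature columns", call. = FALSE)
  X <- matrix(NA_real_, nrow(df), length(feat_cols),
              dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    raw <- df[[feat_cols[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0L)
      stop("non-numeric cell '", raw[bad[1L]], "' at row ", bad[1L],
           ", column '", feat_cols[j], "'", call. = FALSE)
    X[, j] <- val
  }
  labeled_dataset(X, df[[label_column]], positive_class = positive_class,
                  label_name = label_column)
}

#' Write a labeled dataset to CSV
#'
#' Values are printed with 17 significant digits so that write -> read
#' round-trips are lossless for doubles.
#'
#' @param ds A [labeled_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  cols <- c(lapply(seq_len(ds$p), function(j) sprintf("%.17g", ds$features[, j])),
            list(ds$labels))
  header <- paste(c(ds$feature_names, ds$label_name), collapse = ",")
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Euclidean k-nearest neighbours of a dataset row
#'
#' Distances are computed on the raw feature values (no standardisation) by
#' default, with an optional min-max scaling switch. Ties in distance are
#' broken by ascending row index, a deterministic seed-free rule.
#'
#' @param ds A [labeled_dataset()].
#' @param index Query row index.
#' @param k Number of neighbours to return.
#' @param restrict_class Optional label; only rows of that class are eligible.
#' @param exclude_self Drop the query row itself from the candidates.
#' @param scale_minmax Min-max scale each feature to \[0, 1\] before computing
#'   distances (off by default).
#' @return Integer vector of `k` row indices ordered by ascending distance.
#' @export
nearest_neighbors <- function(ds, index, k, restrict_class = NULL,
                              exclude_self = TRUE, scale_minmax = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (index < 1L || index > ds$n) stop("invalid row index", call. = FALSE)
  X <- ds$features
  if (scale_minmax) X <- minmax_scale(X)
  eligible <- seq_len(ds$n)
  if (!is.null(restrict_class))
    eligible <- eligible[ds$labels[eligible] == restrict_class]
  if (exclude_self) eligible <- eligible[eligible != index]
  if (k > length(eligible))
    stop("k = ", k, " exceeds the ", length(eligible), " eligible points",
         call. = FALSE)
  d2 <- colSums((t(X[eligible, , drop = FALSE]) - X[index, ])^2)
  eligible[order(d2, eligible)[seq_len(k)]]
}

minmax_scale <- function(X) {
  rng <- apply(X, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  sweep(sweep(X, 2L, rng[1L, ]), 2L, span, "/")
}

## All-rows k-NN (self excluded), shared by the editing resamplers.
## Returns an n x k matrix of neighbour row indices, distance ties broken by
## ascending row index.
knn_index_matrix <- function(X, k) {
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of rows", call. = FALSE)
  d2 <- as.matrix(stats::dist(X, method = "euclidean"))^2
  diag(d2) <- Inf
  out <- matrix(0L, n, k)
  idx <- seq_len(n)
  for (i in idx) out[i, ] <- idx[order(d2[i, ], idx)[seq_len(k)]]
  out
}
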