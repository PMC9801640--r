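#' Stratified fold assignment
#'
#' Shuffles each class (seeded) and deals its rows cyclically across folds,
#' starting each class where the previous one left off, so overall fold sizes
#' differ by at most one and per-fold class ratios stay within one row of the
#' global ratio. Folds partition the rows exactly.
#'
#' @param labels Class labels, one per row.
#' @param folds Number of folds.
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(labels, folds, seed = NULL) {
  labels <- as.character(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  cnt <- table(labels)
  if (any(cnt < folds))
    stop("class '", names(cnt)[which.min(cnt)], "' has fewer rows (",
         min(cnt), ") than folds (", folds, ")", call. = FALSE)
  assign_ <- integer(length(labels))
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "folds"), {
    start <- 0L
    for (lab in sort(unique(labels))) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      assign_[idx] <- ((start + seq_along(idx) - 1L) %% folds) + 1L
      start <- (start + length(idx)) %% folds
    }
  })
  assign_
}

subset_dataset <- function(ds, rows) {
  labeled_dataset(ds$features[rows, , drop = FALSE], ds$labels[rows],
                  positive_class = if (ds$positive_class %in% ds$labels[rows])
                    ds$positive_class else NULL,
                  label_name = ds$label_name)
}

resolve_dataset <- function(x) {
  if (inherits(x, "resampled_dataset")) x$dataset else x
}

#' Stratified k-fold cross-validation with optional resampling
#'
#' Two protocols are implemented. `mode = "paper_faithful"` resamples the
#' whole dataset once and then runs stratified k-fold CV on the resampled
#' data — the headline protocol of the study this package follows, which
#' leaks synthetic neighbours across folds. `mode = "leakage_safe"` builds
#' folds on the original data and resamples only the training portion of each
#' fold, leaving the test folds untouched. The two coincide exactly when
#' `resampler` is `NULL`.
#'
#' @param ds A [labeled_dataset()].
#' @param resampler `NULL`, or a function `function(ds, seed)` returning a
#'   `resampled_dataset` or `labeled_dataset`.
#' @param learner A function `function(ds, seed)` returning a model with a
#'   [predict()] method supporting `type = "both"`.
#' @param folds Number of folds (default 10).
#' @param mode `"paper_faithful"` or `"leakage_safe"`.
#' @param seed Integer seed driving fold assignment, the resampler and the
#'   per-fold learners through derived streams.
#' @param positive_class Label treated as positive; defaults to the
#'   dataset's.
#' @return An object of class `cv_report`: per-fold metrics
#'   (`$per_fold`, a data frame), their means (`$mean`), class counts before
#'   and after resampling, and the protocol echo.
#' @export
cross_validate <- function(ds, resampler = NULL, learner, folds = 10L,
                           mode = c("paper_faithful", "leakage_safe"),
                           seed = NULL, positive_class = ds$positive_class) {
  stopifnot(inherits(ds, "labeled_dataset"))
  mode <- match.arg(mode)
  counts_before <- class_counts(ds)
  counts_after <- counts_before

  eval_fold <- function(train_ds, test_ds, fold_seed) {
    model <- learner(train_ds, fold_seed)
    pr <- predict(model, test_ds$features, type = "both")
    cm <- confusion(test_ds$labels, pr$class, positive_class,
                    classes = sort(unique(c(ds$labels, pr$class))))
    mr <- classification_metrics(cm)
    auc <- if (length(unique(test_ds$labels)) == 2L)
      auc_score(pr$score, test_ds$labels, positive_class) else NA_real_
    c(precision = mr$precision, sensitivity = mr$sensitivity,
      specificity = mr$specificity, f_measure = mr$f_measure, mcc = mr$mcc,
      auc = auc)
  }

  if (mode == "paper_faithful") {
    data <- ds
    if (!is.null(resampler)) {
      rs <- resampler(ds, if (is.null(seed)) NULL else derive_seed(seed, "resample"))
      data <- resolve_dataset(rs)
      counts_after <- class_counts(data)
    }
    fold_id <- stratified_folds(data$labels, folds, seed)
    rows <- lapply(seq_len(folds), function(f) which(fold_id == f))
    per <- t(vapply(seq_len(folds), function(f) {
      eval_fold(subset_dataset(data, setdiff(seq_len(data$n), rows[[f]])),
                subset_dataset(data, rows[[f]]),
                if (is.null(seed)) NULL else derive_seed(seed, paste0("fold", f)))
    }, numeric(6L)))
  } else {
    fold_id <- stratified_folds(ds$labels, folds, seed)
    rows <- lapply(seq_len(folds), function(f) which(fold_id == f))
    after <- NULL
    per <- t(vapply(seq_len(folds), function(f) {
      train <- subset_dataset(ds, setdiff(seq_len(ds$n), rows[[f]]))
      if (!is.null(resampler)) {
        rs <- resampler(train, if (is.null(seed)) NULL else
          derive_seed(seed, paste0("resample", f)))
        train <- resolve_dataset(rs)
      }
      eval_fold(train, subset_dataset(ds, rows[[f]]),
                if (is.null(seed)) NULL else derive_seed(seed, paste0("fold", f)))
    }, numeric(6L)))
    counts_after <- counts_before      # test data is never resampled
  }

  per <- as.data.frame(per)
  per$fold <- seq_len(folds)
  structure(list(per_fold = per,
                 mean = colMeans(per[, c("precision", "sensitivity",
                                         "specificity", "f_measure", "mcc",
                                         "auc")], na.rm = TRUE),
                 counts_before = counts_before, counts_after = counts_after,
                 folds = folds, mode = mode, seed = seed,
                 positive_class = positive_class),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$folds, "-fold, mode = ", x$mode, "\n", sep = "")
  cat("  Maj/Min: ", x$counts_before$n_majority, "/",
      x$counts_before$n_minority, " -> ", x$counts_after$n_majority, "/",
      x$counts_after$n_minority, "\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}
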