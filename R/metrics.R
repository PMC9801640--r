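#' Confusion counts for binary predictions
#'
#' `TP` counts positive-class rows predicted positive, `TN` negative rows
#' predicted negative, `FP` negatives predicted positive, `FN` positives
#' predicted negative. Counts are invariant to row order.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param positive_class The label treated as positive (the case class).
#' @param classes Optional length-2 vector of the known labels; defaults to
#'   the values seen in `y_true` and `y_pred`.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive_class, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (length(classes) > 2L)
    stop("more than two classes: ", paste(classes, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) stop("unknown label: ", bad[1L], call. = FALSE)
  if (!positive_class %in% classes)
    stop("positive_class not among the known classes", call. = FALSE)
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  structure(list(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
                 FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p),
                 positive_class = positive_class),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> positive =", x$positive_class, "\n")
  cat(sprintf("  TP=%d FN=%d FP=%d TN=%d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Imbalance-aware metrics from confusion counts
#'
#' Sensitivity (recall of the positive class) `TP/(TP+FN)`, specificity
#' `TN/(FP+TN)`, precision `TP/(TP+FP)`, F-measure (the harmonic mean of
#' recall and precision) and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))`. Any 0/0 cell
#' returns 0 by convention and is listed in the `degenerate` field, so result
#' tables stay total.
#'
#' @param cm A [confusion()] object.
#' @return A list of class `metric_report` with fields `sensitivity`,
#'   `specificity`, `precision`, `f_measure`, `mcc`, `degenerate` and a
#'   `counts` echo.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0L) stop("no evaluated rows", call. = FALSE)
  degenerate <- character(0)
  sens <- safe_ratio(cm$TP, cm$TP + cm$FN)
  if (cm$TP + cm$FN == 0L) degenerate <- c(degenerate, "sensitivity")
  spec <- safe_ratio(cm$TN, cm$FP + cm$TN)
  if (cm$FP + cm$TN == 0L) degenerate <- c(degenerate, "specificity")
  prec <- safe_ratio(cm$TP, cm$TP + cm$FP)
  if (cm$TP + cm$FP == 0L) degenerate <- c(degenerate, "precision")
  f <- safe_ratio(2 * sens * prec, sens + prec)
  if (sens + prec == 0) degenerate <- c(degenerate, "f_measure")
  denom <- as.numeric(cm$TN + cm$FN) * (cm$TN + cm$FP) *
    (cm$TP + cm$FN) * (cm$TP + cm$FP)
  mcc <- if (denom == 0) { degenerate <- c(degenerate, "mcc"); 0 } else
    (as.numeric(cm$TP) * cm$TN - as.numeric(cm$FP) * cm$FN) / sqrt(denom)
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 f_measure = f, mcc = mcc, degenerate = degenerate,
                 counts = cm),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  v <- unlist(x[c("precision", "sensitivity", "specificity", "f_measure",
                  "mcc")])
  if (!is.null(x$auc)) v <- c(v, auc = x$auc)
  print(round(v, 4))
  if (length(x$degenerate))
    cat("  degenerate cells:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random positive outscores a random negative, with half
#' credit for score ties; equivalently the normalised Mann-Whitney U computed
#' from average ranks. Invariant to strictly increasing score transforms.
#'
#' @param scores Positive-class scores.
#' @param y_true True labels.
#' @param positive_class The label treated as positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, y_true, positive_class) {
  pos <- as.character(y_true) == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
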