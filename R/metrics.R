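#' Regression evaluation report
#'
#' MAE, RMSE and the coefficient of determination computed on the test set.
#' With zero variance in the true ages, R-squared is undefined and reported
#' as NA with a reason code rather than silently as 0.
#'
#' @param y true ages (years).
#' @param y_pred predicted ages.
#' @return object of class \code{regression_report}: list(n, mae, rmse, r2,
#'   r2_reason).
#' @export
regression_metrics <- function(y, y_pred) {
  if (!length(y) || length(y) != length(y_pred))
    stop("y and y_pred must have equal positive length")
  n <- length(y)
  mae <- mean(abs(y - y_pred))
  rmse <- sqrt(mean((y - y_pred)^2))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) {
    r2 <- NA_real_
    reason <- "zero variance in true values"
  } else {
    r2 <- 1 - sum((y - y_pred)^2) / ss_tot
    reason <- NULL
  }
  structure(list(n = n, mae = mae, rmse = rmse, r2 = r2,
                 r2_reason = reason),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Age estimation on %d subjects: MAE %.4f y, RMSE %.4f y, R2 %s\n",
              x$n, x$mae, x$rmse,
              if (is.na(x$r2)) paste0("NA (", x$r2_reason, ")")
              else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' Classification evaluation report
#'
#' Confusion counts and accuracy/precision/recall/F1 with female as the
#' positive class: scores are female probabilities, thresholded at 0.5.
#' Precision is reported as NA with a reason when there are no positive
#' predictions.
#'
#' @param labels true classes: "male"/"female", or 0/1 with 1 = female.
#' @param scores female-probability scores in [0, 1].
#' @param threshold decision threshold (score >= threshold -> female).
#' @return object of class \code{classification_report}.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  if (!length(labels) || length(labels) != length(scores))
    stop("labels and scores must have equal positive length")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  pos <- if (is.numeric(labels)) labels == 1 else labels == "female"
  pred_pos <- scores >= threshold
  tp <- sum(pos & pred_pos); tn <- sum(!pos & !pred_pos)
  fp <- sum(!pos & pred_pos); fn <- sum(pos & !pred_pos)
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  structure(list(n = length(labels), tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 threshold = threshold,
                 precision_reason = if (tp + fp == 0)
                   "no positive predictions" else NULL),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Sex classification on %d subjects (female positive, threshold %.2f)\n",
              x$n, x$threshold))
  cat(sprintf("  TP %d TN %d FP %d FN %d\n", x$tp, x$tn, x$fp, x$fn))
  fmt <- function(v, reason = NULL)
    if (is.na(v)) paste0("NA", if (!is.null(reason)) paste0(" (", reason, ")"))
    else sprintf("%.4f", v)
  cat(sprintf("  accuracy %s precision %s recall %s F1 %s\n",
              fmt(x$accuracy), fmt(x$precision, x$precision_reason),
              fmt(x$recall), fmt(x$f1)))
  invisible(x)
}
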