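#' Confusion matrix with row percentages
#'
#' Counts of true class (rows) by predicted class (columns), with row
#' percentages whose diagonal is the per-class correct classification
#' rate. Row percentages always sum to 100 (up to rounding on export).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param labels Class order; defaults to the union of observed labels in
#'   order of first appearance in `truth` then `predicted`. Labels outside
#'   this list are an error.
#' @return Object of class `confusion_matrix`: list with integer `counts`,
#'   numeric `row_pct` and `labels`.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted differ in length")
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(labels)) labels <- unique(c(truth, predicted))
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad) > 0) stop("labels outside class list: ",
                            paste(bad, collapse = ", "))
  counts <- table(factor(truth, levels = labels),
                  factor(predicted, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(truth = labels, predicted = labels))
  rs <- rowSums(counts)
  row_pct <- 100 * counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, row_pct = row_pct, labels = labels),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Confusion matrix (", sum(x$counts), " cases)\n", sep = "")
  shown <- matrix(sprintf("%d (%.*f%%)", x$counts, digits, x$row_pct),
                  nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Percent correct classification
#'
#' @param truth,predicted Equal-length, non-empty label vectors.
#' @return `100 * matches / cases`.
#' @export
correct_classification <- function(truth, predicted) {
  if (length(truth) == 0) stop("no cases")
  if (length(truth) != length(predicted)) {
    stop("truth and predicted differ in length")
  }
  100 * mean(as.character(truth) == as.character(predicted))
}

#' Calibration/prediction diagnostics for a regression model
#'
#' Root-mean-square error, coefficient of determination
#' `R2 = 1 - SSE/SST` (set `r2 = "correlation"` for the squared-correlation
#' variant), residual predictive deviation `RPD = sd(measured) / RMSE`
#' (sample SD, n-1 denominator), and the slope/intercept of the ordinary
#' least-squares line of predicted (y) on measured (x).
#'
#' @param measured,predicted Equal-length numeric vectors, n >= 2; the
#'   measured values must have positive variance.
#' @param r2 `"sse"` (default) or `"correlation"`.
#' @return Object of class `regression_metrics`: list with `r2`, `rmse`,
#'   `rpd` (`Inf` when `rmse` is 0), `slope`, `intercept`, `n`.
#' @examples
#' m <- regression_metrics(1:5, c(1.1, 2.1, 2.9, 4.2, 4.8))
#' round(m$rmse, 4); round(m$rpd, 2)
#' @export
regression_metrics <- function(measured, predicted, r2 = c("sse", "correlation")) {
  r2 <- match.arg(r2)
  if (length(measured) != length(predicted)) {
    stop("measured and predicted differ in length")
  }
  n <- length(measured)
  if (n < 2) stop("at least 2 cases are required")
  sdm <- stats::sd(measured)
  if (sdm == 0) stop("measured values have zero variance; R2 and RPD undefined")
  err <- predicted - measured
  rmse <- sqrt(mean(err^2))
  r2v <- if (r2 == "sse") {
    1 - sum(err^2) / sum((measured - mean(measured))^2)
  } else {
    stats::cor(measured, predicted)^2
  }
  rpd <- if (rmse == 0) Inf else sdm / rmse
  slope <- stats::cov(measured, predicted) / stats::var(measured)
  intercept <- mean(predicted) - slope * mean(measured)
  structure(list(r2 = r2v, rmse = rmse, rpd = rpd, slope = slope,
                 intercept = intercept, n = n),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("n = %d  R2 = %.3f  RMSE = %.3f  RPD = %.2f  y = %.2fx %+.2f\n",
              x$n, x$r2, x$rmse, x$rpd, x$slope, x$intercept))
  invisible(x)
}

#' Interpret a residual predictive deviation value
#'
#' Standard chemometric bands: below 2.0 insufficient for prediction,
#' 2.0-2.5 approximate quantitative prediction, 2.5-3.0 good, 3.0 and
#' above excellent.
#'
#' @param rpd Positive RPD value(s).
#' @return Character vector of category labels.
#' @export
rpd_category <- function(rpd) {
  if (any(rpd <= 0)) stop("RPD must be positive")
  cut(rpd, breaks = c(0, 2, 2.5, 3, Inf), right = FALSE,
      labels = c("insufficient", "approximate", "good", "excellent")) |>
    as.character()
}
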