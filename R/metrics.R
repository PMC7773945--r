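# Robust feature scaling and the evaluation metric set.

#' Fit a median/IQR robust scaler
#'
#' Per-column median and interquartile range computed on training rows
#' only. Columns with zero IQR are centred but not divided (with a
#' warning), so constant features stay constant instead of becoming NaN.
#'
#' @param X Numeric training matrix or data.frame.
#' @return An object of class \code{robust_scaler}.
#' @export
robust_scale_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training rows to fit a scaler")
  med <- apply(X, 2, stats::median)
  iqr <- apply(X, 2, stats::IQR)
  if (any(iqr == 0)) {
    warning("zero IQR in column(s) ",
            paste(colnames(X)[iqr == 0], collapse = ", "),
            ": centering only")
    iqr[iqr == 0] <- 1
  }
  structure(list(center = med, scale = iqr, columns = colnames(X)),
            class = "robust_scaler")
}

#' Apply a fitted robust scaler
#'
#' Transforms rows with the stored training medians and IQRs; unseen rows
#' never contribute their own statistics.
#'
#' @param scaler A \code{robust_scaler}.
#' @param X Matrix or data.frame with the same columns as the training
#'   data.
#' @return Scaled numeric matrix.
#' @export
robust_scale_apply <- function(scaler, X) {
  X <- as.matrix(X)
  if (!is.null(scaler$columns) && !is.null(colnames(X)))
    X <- X[, scaler$columns, drop = FALSE]
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Regression metric set
#'
#' RMSE, Pearson r, Spearman rho, the coefficient of determination R2
#' (around the test mean) and the external-validation coefficient QF3^2.
#' The default QF3^2 uses the Consonni definition with the training-set
#' variance in the denominator and per-set n-normalisation:
#' 1 - [sum_test (yhat - y)^2 / n_test] / [sum_train (y - mean_train)^2 /
#' n_train]. \code{qf3_variant = "test_denominator"} instead divides by the
#' test-set sum of (yhat - mean_train)^2, an alternative reading of the
#' formula that appears in print.
#'
#' Correlations are NA (with no error) when y_true is constant.
#'
#' @param y_true Observed test targets.
#' @param y_pred Predicted test targets.
#' @param y_train Training targets (needed for QF3^2); may be NULL, in
#'   which case QF32 is NA.
#' @param qf3_variant "consonni" (default) or "test_denominator".
#' @return Named numeric vector: RMSE, r, rho, R2, QF32.
#' @export
metric_set <- function(y_true, y_pred, y_train = NULL,
                       qf3_variant = c("consonni", "test_denominator")) {
  qf3_variant <- match.arg(qf3_variant)
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 3L) stop("need at least 3 observation pairs")
  res <- y_pred - y_true
  rmse <- sqrt(mean(res^2))
  const <- stats::sd(y_true) == 0
  r <- if (const || stats::sd(y_pred) == 0) NA_real_ else
    stats::cor(y_true, y_pred)
  rho <- if (const || stats::sd(y_pred) == 0) NA_real_ else
    stats::cor(y_true, y_pred, method = "spearman")
  r2 <- if (const) NA_real_ else
    1 - sum(res^2) / sum((y_true - mean(y_true))^2)
  qf32 <- NA_real_
  if (!is.null(y_train)) {
    if (qf3_variant == "consonni") {
      denom <- sum((y_train - mean(y_train))^2) / length(y_train)
      qf32 <- 1 - (sum(res^2) / length(y_true)) / denom
    } else {
      qf32 <- 1 - sum(res^2) / sum((y_pred - mean(y_train))^2)
    }
  }
  c(RMSE = rmse, r = r, rho = rho, R2 = r2, QF32 = qf32)
}
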