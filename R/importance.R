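# Permutation feature importance and feature-ablation retraining.

#' Permutation feature importance
#'
#' After prediction on a held-out test set, each feature column in turn is
#' shuffled (within the test set; the model is never retrained) in
#' \code{n_shuffles} seeded replicates, and the drop in Pearson correlation
#' is recorded. Positive values mean the model relied on the feature.
#'
#' @param model A \code{raspd_model} handle (or a list with elements
#'   \code{model} and \code{scaler} as stored inside a \code{raspd} fit).
#' @param X_test Unscaled test feature matrix/data.frame (scaled internally
#'   when a scaler accompanies the model, otherwise used as-is).
#' @param y_test Observed test targets (must not be constant).
#' @param n_shuffles Number of shuffle replicates per feature (default 5).
#' @param seed Integer seed.
#' @return data.frame of class \code{raspd_importance}: feature,
#'   delta_r_mean, delta_r_sd, n_shuffles, plus the baseline r as an
#'   attribute.
#' @export
permutation_importance <- function(model, X_test, y_test, n_shuffles = 5L,
                                   seed = 1L) {
  scaler <- NULL
  if (!inherits(model, "raspd_model") && is.list(model) &&
      !is.null(model$model)) {
    scaler <- model$scaler
    model <- model$model
  }
  if (stats::sd(y_test) == 0) stop("constant y_test: Pearson r undefined")
  X <- as.matrix(X_test)
  if (nrow(X) != length(y_test)) stop("row/target length mismatch")
  pred_fun <- function(M) {
    if (!is.null(scaler)) M <- robust_scale_apply(scaler, M)
    predict_model(model, M)
  }
  base_r <- stats::cor(y_test, pred_fun(X))
  set.seed(seed)
  res <- lapply(colnames(X) %||% as.character(seq_len(ncol(X))),
                function(j) NULL)
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(X)))
  dr <- matrix(NA_real_, n_shuffles, ncol(X))
  for (s in seq_len(n_shuffles)) {
    for (j in seq_len(ncol(X))) {
      Xs <- X
      Xs[, j] <- X[sample.int(nrow(X)), j]
      r_s <- suppressWarnings(stats::cor(y_test, pred_fun(Xs)))
      dr[s, j] <- base_r - r_s
    }
  }
  out <- data.frame(feature = feats,
                    delta_r_mean = colMeans(dr),
                    delta_r_sd = apply(dr, 2, stats::sd),
                    n_shuffles = n_shuffles,
                    stringsAsFactors = FALSE)
  attr(out, "baseline_r") <- base_r
  class(out) <- c("raspd_importance", class(out))
  out
}

#' @export
print.raspd_importance <- function(x, ...) {
  cat(sprintf("Permutation importance (baseline r = %.3f, %d shuffles)\n",
              attr(x, "baseline_r"), x$n_shuffles[1]))
  y <- x[order(-x$delta_r_mean), c("feature", "delta_r_mean", "delta_r_sd")]
  print.data.frame(y, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Named feature subsets for ablation analysis
#'
#' The standard ablation panel: single-feature models (MR only, MASS
#' only), ligand-only (6 features), protein-only (14 features) and the
#' full set.
#'
#' @return Named list of character vectors.
#' @export
ablation_subsets <- function() {
  list("MR only" = "MR", "MASS only" = "MASS",
       "ligand only" = .LIGAND_FEATURES,
       "protein only" = .POCKET_FEATURES,
       "all" = .ALL_FEATURES)
}

#' Feature-ablation retraining
#'
#' Re-runs the identical nested cross-validation protocol on named feature
#' subsets and collects the per-subset metric summaries.
#'
#' @param data Feature data.frame including the target column.
#' @param subsets Named list of feature-name vectors (default
#'   \code{\link{ablation_subsets}} intersected with the available
#'   columns).
#' @param target Target column name (default "dG").
#' @param ... Passed to \code{\link{raspd}} (method, replicates, seed...).
#' @return Named list of \code{raspd} fits, with a combined summary in
#'   attribute "summary".
#' @export
ablation_models <- function(data, subsets = NULL, target = "dG", ...) {
  if (is.null(subsets)) subsets <- ablation_subsets()
  feat_cols <- setdiff(names(data), c(target, "id"))
  fits <- lapply(names(subsets), function(nm) {
    cols <- subsets[[nm]]
    missing <- setdiff(cols, feat_cols)
    if (length(missing))
      stop("unknown feature(s) in subset '", nm, "': ",
           paste(missing, collapse = ", "))
    d <- data[, c(cols, target), drop = FALSE]
    raspd(stats::as.formula(paste(target, "~ .")), d, ...)
  })
  names(fits) <- names(subsets)
  summ <- do.call(rbind, lapply(names(fits), function(nm) {
    m <- fits[[nm]]$metrics
    cbind(subset = nm, m)
  }))
  attr(fits, "summary") <- summ
  fits
}
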