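# The central estimator: nested cross-validation over the learner zoo.
# Outer loop: seeded random test splits for unbiased evaluation. Inner
# loop: k-fold cross-validation grid search selecting hyperparameters by
# mean validation Pearson r. Every winning fold model is evaluated on the
# replicate's test set, so `replicates x inner_folds` models per method
# enter the reported mean and standard deviation.

#' Fit binding free energy models by nested cross-validation
#'
#' For each of \code{replicates} outer draws, a seeded random
#' \code{test_frac} share of rows is held out; the remaining rows are split
#' into \code{inner_folds} near-equal folds. For every hyperparameter
#' combination, one model per fold is trained on the other folds and
#' scored on the held-out fold; the combination with the highest mean
#' validation Pearson r wins (ties to the simplest model, then first in
#' grid order). The winning fold models are evaluated on the replicate's
#' test set. Feature scaling (median/IQR) is fitted on each model's own
#' training rows only, so no test information leaks into training.
#'
#' @param formula Model formula, typically \code{dG ~ .}; the right-hand
#'   side selects the feature columns.
#' @param data data.frame with features and target; non-numeric columns on
#'   the right-hand side are an error.
#' @param methods Character vector of learners: subset of "null", "lr",
#'   "knn", "lsvr", "svr", "rf", "erf", "dnn".
#' @param replicates Number of outer random draws (default 10).
#' @param test_frac Held-out fraction per draw (default 0.125).
#' @param inner_folds Inner cross-validation folds (default 6).
#' @param grids Hyperparameter grids, as \code{\link{default_grids}}.
#' @param seed Integer seed; the entire report is reproducible from it.
#' @param store_models "first" keeps the trained fold models of the first
#'   replicate (enough to predict/screen), "all" keeps everything, "none"
#'   keeps only metrics.
#' @param qf3_variant Passed to \code{\link{metric_set}}.
#' @return An object of class \code{raspd}.
#' @examples
#' \donttest{
#' tab <- make_feature_table(n = 96, seed = 7)
#' fit <- raspd(dG ~ . - id, tab$table, methods = c("null", "lr"),
#'              replicates = 2, seed = 7)
#' print(fit)
#' }
#' @export
raspd <- function(formula, data, methods = c("lr", "knn", "lsvr", "svr",
                                             "rf", "erf"),
                  replicates = 10L, test_frac = 0.125, inner_folds = 6L,
                  grids = default_grids(), seed = 1L,
                  store_models = c("first", "all", "none"),
                  qf3_variant = c("consonni", "test_denominator")) {
  store_models <- match.arg(store_models)
  qf3_variant <- match.arg(qf3_variant)
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)

  tt <- stats::terms(formula, data = data)
  labs <- attr(tt, "term.labels")
  yname <- all.vars(formula)[1]
  if (!yname %in% names(data)) stop("target '", yname, "' not in data")
  y <- data[[yname]]
  if (!all(labs %in% names(data)))
    stop("feature column(s) not in data: ",
         paste(setdiff(labs, names(data)), collapse = ", "))
  X <- as.matrix(data[, labs, drop = FALSE])
  if (!is.numeric(X)) stop("all features must be numeric")
  n <- nrow(X)
  if (n < 48L) stop("need at least 48 rows for the nested protocol")

  splits <- make_cv_splits(n, replicates, test_frac, inner_folds, seed)

  reps <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    sp <- splits[[rep_i]]
    keep_models <- store_models == "all" ||
      (store_models == "first" && rep_i == 1L)
    per_method <- lapply(methods, function(m)
      fit_one_method(m, X, y, sp, grids[[m]], seed, rep_i, keep_models,
                     qf3_variant))
    names(per_method) <- methods
    reps[[rep_i]] <- list(test_idx = sp$test, fold_of = sp$fold_of,
                          methods = per_method)
  }

  metrics <- summarize_cv(reps, methods)
  structure(list(call = match.call(), formula = formula, methods = methods,
                 replicates = replicates, test_frac = test_frac,
                 inner_folds = inner_folds, seed = seed,
                 features = colnames(X), n = n,
                 qf3_variant = qf3_variant,
                 reps = reps, metrics = metrics),
            class = "raspd")
}

# seeded outer/inner split plan: list per replicate of test indices and a
# fold assignment for the remaining (cross-validation pool) rows
make_cv_splits <- function(n, replicates, test_frac, inner_folds, seed) {
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    n_test <- max(1L, round(n * test_frac))
    test <- sort(sample.int(n, n_test))
    pool <- setdiff(seq_len(n), test)
    fold_sizes <- rep(length(pool) %/% inner_folds, inner_folds)
    extra <- length(pool) %% inner_folds
    if (extra > 0) fold_sizes[seq_len(extra)] <- fold_sizes[seq_len(extra)] + 1L
    fold_of <- stats::setNames(rep(seq_len(inner_folds), fold_sizes),
                               sample(pool))
    list(test = test, pool = pool,
         fold_of = fold_of[order(as.integer(names(fold_of)))])
  })
}

fit_one_method <- function(method, X, y, sp, grid, seed, rep_i,
                           keep_models, qf3_variant) {
  combos <- expand_grid_list(grid %||% list())
  pool <- as.integer(names(sp$fold_of))
  folds <- sort(unique(sp$fold_of))

  # train every combo on every fold once; reuse the winners for the test
  all_fits <- vector("list", length(combos))
  val_r <- matrix(NA_real_, length(combos), length(folds))
  for (gi in seq_along(combos)) {
    fits <- vector("list", length(folds))
    for (f in folds) {
      tr <- pool[sp$fold_of != f]
      va <- pool[sp$fold_of == f]
      fit <- tryCatch({
        sc <- suppressWarnings(robust_scale_fit(X[tr, , drop = FALSE]))
        m <- train_model(method, robust_scale_apply(sc, X[tr, , drop = FALSE]),
                         y[tr], combos[[gi]],
                         seed = seed + 131L * rep_i + 7L * f + gi)
        pred <- predict_model(m, robust_scale_apply(sc, X[va, , drop = FALSE]))
        list(model = m, scaler = sc, train_idx = tr,
             val_r = suppressWarnings(stats::cor(y[va], pred)))
      }, error = function(e) {
        warning(sprintf("%s grid candidate %d failed on fold %d: %s",
                        method, gi, f, conditionMessage(e)))
        NULL
      })
      fits[[f]] <- fit
      if (!is.null(fit) && is.finite(fit$val_r)) val_r[gi, f] <- fit$val_r
    }
    all_fits[[gi]] <- fits
  }

  mean_r <- rowMeans(val_r)
  mean_r[!is.finite(mean_r)] <- -Inf
  if (length(combos) > 1L) {
    cx <- vapply(combos, function(p) grid_complexity(method, p), numeric(1))
    best <- order(-mean_r, cx, seq_along(combos))[1]
  } else best <- 1L

  winners <- all_fits[[best]]
  test_metrics <- lapply(winners, function(w) {
    if (is.null(w)) return(NULL)
    pred <- predict_model(w$model,
                          robust_scale_apply(w$scaler,
                                             X[sp$test, , drop = FALSE]))
    metric_set(y[sp$test], pred, y[w$train_idx], qf3_variant)
  })

  list(best_pars = combos[[best]],
       mean_val_r = if (is.finite(mean_r[best])) mean_r[best] else NA_real_,
       test_metrics = test_metrics,
       models = if (keep_models) winners else NULL)
}

summarize_cv <- function(reps, methods) {
  do.call(rbind, lapply(methods, function(m) {
    ms <- do.call(rbind, unlist(lapply(reps, function(r)
      r$methods[[m]]$test_metrics), recursive = FALSE))
    data.frame(method = m, n_models = nrow(ms),
               RMSE = mean(ms[, "RMSE"]), RMSE_sd = stats::sd(ms[, "RMSE"]),
               r = mean(ms[, "r"]), r_sd = stats::sd(ms[, "r"]),
               rho = mean(ms[, "rho"]), rho_sd = stats::sd(ms[, "rho"]),
               R2 = mean(ms[, "R2"]), R2_sd = stats::sd(ms[, "R2"]),
               QF32 = mean(ms[, "QF32"]), QF32_sd = stats::sd(ms[, "QF32"]),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.raspd <- function(x, digits = 3, ...) {
  cat(sprintf("Nested cross-validation fit: %d rows, %d replicates x %d folds (seed %d)\n",
              x$n, x$replicates, x$inner_folds, x$seed))
  cat(sprintf("Features (%d): %s\n\n", length(x$features),
              paste(utils::head(x$features, 6), collapse = ", ")))
  m <- x$metrics
  tab <- data.frame(method = m$method, models = m$n_models,
                    RMSE = sprintf("%.*f +/- %.*f", digits, m$RMSE, digits,
                                   m$RMSE_sd),
                    r = sprintf("%.*f +/- %.*f", digits, m$r, digits, m$r_sd),
                    rho = sprintf("%.*f +/- %.*f", digits, m$rho, digits,
                                  m$rho_sd))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.raspd <- function(object, ...) {
  structure(list(metrics = object$metrics,
                 best_pars = lapply(object$reps[[1]]$methods,
                                    `[[`, "best_pars"),
                 replicates = object$replicates,
                 inner_folds = object$inner_folds, n = object$n,
                 seed = object$seed),
            class = "summary.raspd")
}

#' @export
print.summary.raspd <- function(x, ...) {
  cat(sprintf("Nested CV: %d replicates x %d folds = %d models/method on %d rows\n\n",
              x$replicates, x$inner_folds, x$replicates * x$inner_folds,
              x$n))
  print(x$metrics, row.names = FALSE)
  cat("\nSelected hyperparameters (first replicate):\n")
  for (m in names(x$best_pars)) {
    p <- x$best_pars[[m]]
    cat(sprintf("  %-5s %s\n", m,
                if (length(p)) paste(names(p), unlist(p), sep = "=",
                                     collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Predict binding free energies from a nested-CV fit
#'
#' Per method, predictions of the stored fold models of one replicate are
#' averaged (each model applies its own training scaler). With
#' \code{method = "ensemble"} the per-method averages are averaged again
#' over all fitted methods.
#'
#' @param object A \code{raspd} fit (with stored models).
#' @param newdata data.frame or matrix with the training feature columns.
#' @param method One fitted method name or "ensemble" (default: the method
#'   with the best mean test RMSE).
#' @param replicate Which replicate's models to use (default 1; only 1 is
#'   stored unless \code{store_models = "all"}).
#' @param ... Unused.
#' @return Numeric vector of predicted dG (kcal/mol).
#' @export
predict.raspd <- function(object, newdata, method = NULL, replicate = 1L,
                          ...) {
  if (is.null(method))
    method <- object$metrics$method[which.min(object$metrics$RMSE)]
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (method == "ensemble") {
    preds <- vapply(object$methods, function(m)
      predict.raspd(object, newdata, method = m, replicate = replicate),
      numeric(nrow(X)))
    return(rowMeans(preds))
  }
  method <- match.arg(method, object$methods)
  rep_models <- object$reps[[replicate]]$methods[[method]]$models
  if (is.null(rep_models))
    stop("no stored models for replicate ", replicate,
         "; refit with store_models = \"all\"")
  preds <- vapply(rep_models[!vapply(rep_models, is.null, logical(1))],
                  function(w)
                    predict_model(w$model, robust_scale_apply(w$scaler, X)),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' @export
residuals.raspd <- function(object, method = NULL, ...) {
  if (is.null(method))
    method <- object$metrics$method[which.min(object$metrics$RMSE)]
  ti <- object$reps[[1]]$test_idx
  data <- eval(object$call$data, envir = parent.frame())
  y <- data[[all.vars(object$formula)[1]]]
  pred <- predict.raspd(object, data[ti, object$features, drop = FALSE],
                        method = method)
  y[ti] - pred
}

#' Mean linear-regression coefficients
#'
#' Average OLS coefficients (on the robust-scaled feature scale) over the
#' stored fold models; defined only when "lr" was among the fitted methods.
#'
#' @param object A \code{raspd} fit.
#' @param ... Unused.
#' @return Named numeric vector of coefficients.
#' @export
coef.raspd <- function(object, ...) {
  if (!"lr" %in% object$methods) stop("no linear model in this fit")
  mods <- object$reps[[1]]$methods[["lr"]]$models
  if (is.null(mods)) stop("no stored models; refit with store_models")
  cf <- vapply(mods[!vapply(mods, is.null, logical(1))],
               function(w) w$model$fit$coefficients,
               numeric(length(object$features) + 1L))
  rowMeans(cf)
}

#' Predicted-versus-observed plot for a nested-CV fit
#'
#' Scatter of test-set predictions of the chosen method (first replicate)
#' against observed values, with the identity line.
#'
#' @param x A \code{raspd} fit.
#' @param data The data used to fit (defaults to re-evaluating the call).
#' @param method Method name (default: best by mean RMSE).
#' @param ... Passed to \code{plot}.
#' @method plot raspd
#' @export
plot.raspd <- function(x, data = NULL, method = NULL, ...) {
  if (is.null(method))
    method <- x$metrics$method[which.min(x$metrics$RMSE)]
  if (is.null(data)) data <- eval(x$call$data, envir = parent.frame())
  y <- data[[all.vars(x$formula)[1]]]
  ti <- x$reps[[1]]$test_idx
  pred <- predict.raspd(x, data[ti, x$features, drop = FALSE],
                        method = method)
  graphics::plot(y[ti], pred,
                 xlab = expression(paste("observed ", Delta, "G (kcal/mol)")),
                 ylab = expression(paste("predicted ", Delta, "G (kcal/mol)")),
                 main = sprintf("%s, held-out test set", method), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
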