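# The learner zoo: null model, ordinary least squares, k-nearest
# neighbours, linear and RBF-kernel support vector regression, random and
# extremely randomised forests, and a small two-hidden-layer feed-forward
# network. A uniform train/predict surface lets the nested cross-validation
# treat them interchangeably.

.METHODS <- c("null", "lr", "knn", "lsvr", "svr", "rf", "erf", "dnn")

#' Default hyperparameter grids
#'
#' A typical search space per method; each element is a named list of value
#' vectors expanded to a full grid. The eRF default follows the convention
#' of 200 trees with unrestricted leaves. Grids can be overridden per call.
#'
#' @return Named list of grids.
#' @export
default_grids <- function() {
  list(
    null = list(),
    lr = list(),
    knn = list(k = c(1, 3, 5, 7, 11, 15, 21)),
    lsvr = list(C = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1, 0.5)),
    svr = list(C = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1, 0.5),
               gamma = c(NA, 0.01, 0.1)),    # NA = "scale" heuristic
    rf = list(ntree = c(100, 200), mtry_frac = c(1, NA)),   # NA = sqrt
    erf = list(ntree = c(100, 200), mtry_frac = c(1, NA)),
    dnn = list(units = c(32, 64), dropout = c(0, 0.2))
  )
}

expand_grid_list <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# complexity score used for deterministic tie-breaking: smaller = simpler
grid_complexity <- function(method, pars) {
  switch(method,
    knn = -pars$k,                         # larger k = smoother = simpler
    lsvr = pars$C - pars$epsilon,          # small C, large eps = regularised
    svr = pars$C - pars$epsilon +
      ifelse(is.na(pars$gamma), 0, pars$gamma),
    rf = , erf = pars$ntree +
      ifelse(is.na(pars$mtry_frac), 0, pars$mtry_frac),
    dnn = pars$units - pars$dropout,
    0)
}

#' Train one learner
#'
#' @param method One of "null", "lr", "knn", "lsvr", "svr", "rf", "erf",
#'   "dnn".
#' @param X Scaled numeric feature matrix.
#' @param y Numeric targets (kcal/mol).
#' @param pars Named list of hyperparameters for the method (see
#'   \code{\link{default_grids}}).
#' @param seed Integer seed for stochastic learners.
#' @return A model handle of class \code{raspd_model} with a
#'   \code{\link{predict_model}} method behind it.
#' @export
train_model <- function(method, X, y, pars = list(), seed = 1L) {
  method <- match.arg(method, .METHODS)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(y)))
  fit <- switch(method,
    null = list(mean = mean(y)),
    lr = fit_ols(X, y),
    knn = {
      k <- if (is.null(pars$k)) 5L else as.integer(pars$k)
      caret::knnreg(as.data.frame(X), y, k = k)
    },
    lsvr = {
      e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                 cost = pars$C %||% 1, epsilon = pars$epsilon %||% 0.1,
                 scale = FALSE)
    },
    svr = {
      g <- pars$gamma
      if (is.null(g) || is.na(g)) {
        v <- mean(apply(X, 2, stats::var))
        g <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
      }
      e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                 cost = pars$C %||% 1, epsilon = pars$epsilon %||% 0.1,
                 gamma = g, scale = FALSE)
    },
    rf = {
      mtry <- mtry_from_frac(pars$mtry_frac, ncol(X))
      set.seed(seed)
      randomForest::randomForest(X, y, ntree = pars$ntree %||% 200,
                                 mtry = mtry, nodesize = 1)
    },
    erf = {
      mtry <- mtry_from_frac(pars$mtry_frac, ncol(X))
      ranger::ranger(y = y, x = as.data.frame(X),
                     num.trees = pars$ntree %||% 200,
                     mtry = mtry, splitrule = "extratrees",
                     num.random.splits = 1, replace = FALSE,
                     sample.fraction = 1, min.node.size = 1,
                     seed = seed, num.threads = 1)
    },
    dnn = fit_mlp(X, y, units = pars$units %||% 64,
                  dropout = pars$dropout %||% 0, seed = seed))
  structure(list(method = method, fit = fit, pars = pars,
                 features = colnames(X)),
            class = "raspd_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mtry_from_frac <- function(frac, p) {
  if (is.null(frac) || is.na(frac)) max(1L, floor(sqrt(p)))
  else max(1L, floor(frac * p))
}

# OLS with an intercept; rank-deficient designs fall back to the
# minimum-norm SVD solution with a warning
fit_ols <- function(X, y) {
  Xa <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xa)
  if (qrx$rank < ncol(Xa)) {
    warning("singular design: using minimum-norm least squares")
    sv <- svd(Xa)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrx, y)
  }
  names(beta) <- colnames(Xa)
  list(coefficients = beta)
}

#' Predict from a trained learner
#'
#' @param model A \code{raspd_model} from \code{\link{train_model}}.
#' @param X Scaled feature matrix (same columns as at training).
#' @return Numeric predictions.
#' @export
predict_model <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X)))
    X <- X[, model$features, drop = FALSE]
  switch(model$method,
    null = rep(model$fit$mean, nrow(X)),
    lr = drop(cbind(1, X) %*% model$fit$coefficients),
    knn = as.numeric(stats::predict(model$fit, as.data.frame(X))),
    lsvr = , svr = as.numeric(stats::predict(model$fit, X)),
    rf = as.numeric(stats::predict(model$fit, X)),
    erf = as.numeric(stats::predict(model$fit, data = as.data.frame(X),
                                    num.threads = 1)$predictions),
    dnn = predict_mlp(model$fit, X))
}

#' @export
print.raspd_model <- function(x, ...) {
  p <- if (length(x$pars))
    paste0(" (", paste(names(x$pars), unlist(x$pars), sep = "=",
                       collapse = ", "), ")") else ""
  cat(sprintf("<raspd_model> %s%s, %d features\n", x$method, p,
              length(x$features)))
  invisible(x)
}

# ---- small feed-forward network -------------------------------------------
# Two hidden layers with tanh activations trained by full-batch Adam on the
# squared error; dropout is applied as multiplicative Bernoulli noise on
# hidden activations during training. Deliberately small and deterministic
# for a given seed.

fit_mlp <- function(X, y, units = 64, dropout = 0, epochs = 400,
                    lr = 0.01, patience = 30, seed = 1L) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  h1 <- units; h2 <- max(8L, units %/% 2L)
  init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                  sqrt(2 / (nin + nout))),
                                     nin, nout)
  W <- list(init(p, h1), init(h1, h2), init(h2, 1))
  b <- list(rep(0, h1), rep(0, h2), 0)
  mu_y <- mean(y); sd_y <- stats::sd(y); if (sd_y == 0) sd_y <- 1
  yt <- (y - mu_y) / sd_y
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(b, function(x) x * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- Inf; best_W <- W; best_b <- b; wait <- 0
  for (t in seq_len(epochs)) {
    a1 <- tanh(sweep(X %*% W[[1]], 2, b[[1]], "+"))
    a2 <- tanh(sweep(a1 %*% W[[2]], 2, b[[2]], "+"))
    if (dropout > 0) {
      m1 <- matrix(stats::rbinom(n * h1, 1, 1 - dropout), n) / (1 - dropout)
      m2 <- matrix(stats::rbinom(n * h2, 1, 1 - dropout), n) / (1 - dropout)
      a1 <- a1 * m1; a2 <- a2 * m2
    }
    out <- drop(a2 %*% W[[3]]) + b[[3]]
    err <- out - yt
    loss <- mean(err^2)
    if (loss < best - 1e-6) { best <- loss; best_W <- W; best_b <- b
                              wait <- 0 } else wait <- wait + 1
    if (wait >= patience) break
    d3 <- matrix(2 * err / n, ncol = 1)
    gW3 <- t(a2) %*% d3; gb3 <- sum(d3)
    d2 <- (d3 %*% t(W[[3]])) * (1 - a2^2)
    gW2 <- t(a1) %*% d2; gb2 <- colSums(d2)
    d1 <- (d2 %*% t(W[[2]])) * (1 - a1^2)
    gW1 <- t(X) %*% d1; gb1 <- colSums(d1)
    gW <- list(gW1, gW2, gW3); gB <- list(gb1, gb2, gb3)
    for (l in 1:3) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
      vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
      mh <- mW[[l]] / (1 - beta1^t); vh <- vW[[l]] / (1 - beta2^t)
      W[[l]] <- W[[l]] - lr * mh / (sqrt(vh) + eps)
      mhb <- mB[[l]] / (1 - beta1^t); vhb <- vB[[l]] / (1 - beta2^t)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(W = best_W, b = best_b, mu_y = mu_y, sd_y = sd_y)
}

predict_mlp <- function(fit, X) {
  a1 <- tanh(sweep(X %*% fit$W[[1]], 2, fit$b[[1]], "+"))
  a2 <- tanh(sweep(a1 %*% fit$W[[2]], 2, fit$b[[2]], "+"))
  out <- drop(a2 %*% fit$W[[3]]) + fit$b[[3]]
  out * fit$sd_y + fit$mu_y
}
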