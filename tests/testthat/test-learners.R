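test_that("robust scaling gives training median 0 and IQR 1, applied with stored params", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(10, 30, 20, 50, 40))
  sc <- robust_scale_fit(X)
  Z <- robust_scale_apply(sc, X)
  expect_equal(apply(Z, 2, median), c(a = 0, b = 0))
  expect_equal(apply(Z, 2, IQR), c(a = 1, b = 1))
  # held-out row transformed with the stored training statistics
  held <- cbind(a = 11, b = 100)
  expect_equal(robust_scale_apply(sc, held)[1, ],
               c(a = (11 - 3) / 2, b = (100 - 30) / 20))
})

test_that("constant columns are centred, not divided, with a warning", {
  X <- cbind(a = 1:6, b = rep(7, 6))
  expect_warning(sc <- robust_scale_fit(X), "IQR")
  Z <- robust_scale_apply(sc, X)
  expect_true(all(Z[, "b"] == 0))
  expect_equal(IQR(Z[, "a"]), 1)
})

test_that("metrics match a hand-worked four-point example", {
  y <- c(-8, -6, -7, -5)
  p <- c(-7.5, -6.5, -6, -5.5)
  tr <- c(-9, -7, -6, -8, -5)
  m <- metric_set(y, p, tr)
  expect_equal(m[["RMSE"]], 0.661437827766, tolerance = 1e-9)
  expect_equal(m[["r"]], 0.831521840620, tolerance = 1e-9)
  expect_equal(m[["rho"]], 0.8, tolerance = 1e-9)
  expect_equal(m[["R2"]], 0.65, tolerance = 1e-9)
  expect_equal(m[["QF32"]], 0.78125, tolerance = 1e-9)
})

test_that("metrics agree with brute-force formulas on random vectors", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- rnorm(n, -7, 2)
    p <- y + rnorm(n, 0, runif(1, 0.1, 3))
    tr <- rnorm(n + 10, -7, 2)
    expect_equal(unname(metric_set(y, p, tr)),
                 unname(oracle_metrics(y, p, tr)), tolerance = 1e-9)
  }
})

test_that("perfect predictions and the null model behave as expected", {
  y <- c(-9, -6, -8, -4, -7)
  expect_equal(unname(metric_set(y, y, y)), c(0, 1, 1, 1, 1))
  # predicting the training mean: RMSE = test spread around training mean
  tr <- rnorm(30, -7, 2.5)
  m <- train_model("null", matrix(0, 30, 2), tr)
  yt <- rnorm(12, -6, 2)
  pred <- predict_model(m, matrix(0, 12, 2))
  expect_equal(pred, rep(mean(tr), 12))
  ms <- metric_set(yt, pred, tr)
  expect_equal(ms[["RMSE"]], sqrt(mean((yt - mean(tr))^2)))
  expect_lte(ms[["R2"]], 0)
})

test_that("constant targets yield NA correlations rather than errors", {
  m <- metric_set(rep(-5, 4), c(-5, -4, -6, -5), rnorm(10))
  expect_true(is.na(m[["r"]]) && is.na(m[["rho"]]))
  expect_false(is.na(m[["RMSE"]]))
})

test_that("both QF3^2 variants are available and differ as documented", {
  set.seed(1)
  y <- rnorm(20, -7); p <- y + rnorm(20, 0, 1); tr <- rnorm(50, -6, 2)
  cons <- metric_set(y, p, tr)[["QF32"]]
  alt <- metric_set(y, p, tr, qf3_variant = "test_denominator")[["QF32"]]
  expect_equal(cons,
               1 - mean((p - y)^2) / (sum((tr - mean(tr))^2) / length(tr)))
  expect_equal(alt, 1 - sum((p - y)^2) / sum((p - mean(tr))^2))
  expect_false(isTRUE(all.equal(cons, alt)))
})

test_that("ordinary least squares recovers a noiseless linear model exactly", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * X[, 1] + 1
  m <- train_model("lr", X, y)
  expect_equal(unname(m$fit$coefficients),
               c(1, 2, 0, 0, 0), tolerance = 1e-8)
  Xnew <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(predict_model(m, Xnew), 2 * Xnew[, 1] + 1, tolerance = 1e-8)
  # singular design falls back to minimum-norm with a warning
  Xs <- cbind(X, f5 = X[, 1])
  expect_warning(ms <- train_model("lr", Xs, y), "minimum-norm")
  expect_equal(predict_model(ms, cbind(Xnew, f5 = Xnew[, 1])),
               2 * Xnew[, 1] + 1, tolerance = 1e-6)
})

test_that("every learner beats the null model on its own training set", {
  set.seed(11)
  X <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(100, 0, 0.3)
  null_rmse <- sqrt(mean((y - mean(y))^2))
  for (method in c("lr", "knn", "lsvr", "svr", "rf", "erf", "dnn")) {
    m <- train_model(method, X, y, seed = 5)
    rmse <- sqrt(mean((predict_model(m, X) - y)^2))
    expect_lte(rmse, null_rmse + 1e-8)
  }
})

test_that("the extra-randomised forest captures interactions linear models cannot", {
  set.seed(23)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] * X[, 2] + rnorm(n, 0, 0.2)   # pure sign interaction
  tr <- 1:300; te <- 301:400
  m_lr <- train_model("lr", X[tr, ], y[tr])
  m_erf <- train_model("erf", X[tr, ], y[tr], list(ntree = 200), seed = 2)
  r_lr <- cor(y[te], predict_model(m_lr, X[te, ]))
  r_erf <- cor(y[te], predict_model(m_erf, X[te, ]))
  expect_gt(r_erf, r_lr)
  expect_gt(r_erf, 0.5)
})

test_that("nested cross-validation produces the full model count and exact split sizes", {
  syn <- make_feature_table(n = 96, seed = 5)
  fit <- raspd(dG ~ . - id, syn$table, methods = c("null", "lr"),
               replicates = 3, seed = 5)
  expect_equal(fit$metrics$n_models, c(18, 18))  # replicates x folds
  for (r in fit$reps) {
    expect_length(r$test_idx, 12)                # round(96 * 0.125)
    expect_length(r$fold_of, 84)
    expect_equal(as.integer(table(r$fold_of)), rep(14L, 6))
    expect_length(intersect(r$test_idx, as.integer(names(r$fold_of))), 0)
  }
})

test_that("refitting with the same seed reproduces the report exactly", {
  syn <- make_feature_table(n = 96, seed = 9)
  f1 <- raspd(dG ~ . - id, syn$table, methods = c("lr", "erf"),
              replicates = 2, seed = 4)
  f2 <- raspd(dG ~ . - id, syn$table, methods = c("lr", "erf"),
              replicates = 2, seed = 4)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$reps[[1]]$test_idx, f2$reps[[1]]$test_idx)
})

test_that("scalers stored in the fit depend only on their training rows", {
  syn <- make_feature_table(n = 96, seed = 2)
  fit <- raspd(dG ~ . - id, syn$table, methods = "lr", replicates = 2,
               seed = 3)
  X <- as.matrix(syn$table[, fit$features])
  for (w in fit$reps[[1]]$methods$lr$models) {
    ref <- robust_scale_fit(X[w$train_idx, , drop = FALSE])
    expect_equal(w$scaler$center, ref$center)
    expect_equal(w$scaler$scale, ref$scale)
    # no test row participates in any training fold
    expect_length(intersect(w$train_idx, fit$reps[[1]]$test_idx), 0)
  }
})
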