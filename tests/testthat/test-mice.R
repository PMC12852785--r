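# Chained-equations imputation, the multiple-imputation driver and
# Rubin's-rules pooling.

test_that("a complete mask returns the data unchanged", {
  set.seed(131)
  X <- matrix(rnorm(40), 20, 2)
  task <- imputationTask(X, matrix(1, 20, 2), rnorm(20))
  out <- chainedImpute(task)
  expect_equal(unclass(out)[, ], X, ignore_attr = TRUE)
})

test_that("task validity enforces the mask/zero-fill/binary contract", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(imputationTask(X, matrix(1, 4, 2), rnorm(5)), "shape")
  expect_error(imputationTask(X, matrix(2, 5, 2), rnorm(5)), "zero-one")
  # zero-filling happens automatically
  m <- matrix(1, 5, 2); m[1, 1] <- 0
  tk <- imputationTask(X, m, rnorm(5))
  expect_identical(tk@data[1, 1], 0)
  # binary detection
  Xb <- cbind(rbinom(5, 1, 0.5), rnorm(5))
  expect_identical(imputationTask(Xb, matrix(1, 5, 2), rnorm(5))@columnKinds,
                   c("binary", "continuous"))
})

test_that("an exactly linear column is recovered and the mask closes", {
  set.seed(132)
  X2 <- rnorm(300)
  X <- cbind(2 * X2, X2)
  mask <- matrix(1, 300, 2)
  mask[sample(300, 90), 1] <- 0
  task <- imputationTask(X * mask, mask, rnorm(300), noiseVar = 0)
  out <- chainedImpute(task)
  expect_lt(max(abs(out[mask[, 1] == 0, 1] - X[mask[, 1] == 0, 1])), 1e-3)
  expect_true(all(attr(out, "mask") == 1))
  # observed entries are never modified
  expect_identical(out[mask[, 1] == 1, 1], X[mask[, 1] == 1, 1])
  expect_identical(out[, 2], X[, 2])
})

test_that("degenerate tasks error out cleanly", {
  X <- matrix(rnorm(20), 10, 2)
  m1 <- matrix(1, 10, 2); m1[, 1] <- 0
  expect_error(chainedImpute(imputationTask(X * m1, m1, rnorm(10))),
               "entirely missing")
  m2 <- matrix(1, 10, 2); m2[1:5, 1] <- 0; m2[6:10, 2] <- 0
  expect_error(chainedImpute(imputationTask(X * m2, m2, rnorm(10))),
               "fully observed")
})

test_that("secure chained imputation matches plaintext with shared noise", {
  set.seed(133)
  X <- cbind(rnorm(120), rnorm(120), rnorm(120))
  X[, 1] <- 0.5 * X[, 2] - 0.3 * X[, 3] + rnorm(120, 0, 0.2)
  mask <- matrix(1, 120, 3)
  mask[sample(120, 40), 1] <- 0
  task <- imputationTask(X * mask, mask, rnorm(120))
  set.seed(99)
  plain <- chainedImpute(task)
  ctx <- newCtx(1)
  set.seed(99)  # identical injected noise draws
  sec <- reconstructSecret(chainedImpute(task, mode = "smc", ctx = ctx))
  expect_lt(max(abs(sec - plain)), 1e-3)
})

test_that("multiple imputation degenerates and pools correctly", {
  set.seed(134)
  X <- cbind(rnorm(100), rnorm(100))
  y <- 1 + rowSums(X) + rnorm(100, 0, 0.1)
  mask <- matrix(1, 100, 2); mask[sample(100, 30), 1] <- 0
  task0 <- imputationTask(X * mask, mask, y, noiseVar = 0)
  # noise variance 0 and deterministic fits: identical coefficient rows
  r0 <- multipleImputeAnalyze(task0, k = 3L)
  expect_equal(r0@coefficients[1, ], r0@coefficients[3, ], tolerance = 1e-12)
  # k = 1 reduces to a single impute-then-fit
  r1 <- multipleImputeAnalyze(task0, k = 1L)
  expect_identical(nrow(r1@coefficients), 1L)
  expect_true(all(is.na(r1@totalVar)))
  # complete data: pooled coefficients equal the direct regression
  taskC <- imputationTask(X, matrix(1, 100, 2), y)
  rC <- multipleImputeAnalyze(taskC, k = 5L)
  direct <- coef(fitPlain(regressionModel("linear"), X, y))
  expect_lt(max(abs(pooledCoef(rC) - direct)), 1e-6)
})

test_that("Rubin pooling is the arithmetic mean, also on shares", {
  C <- rbind(c(1, 2), c(3, 4))
  expect_identical(rubinPool(C), c(2, 3))
  expect_identical(rubinPool(rbind(c(5, 6), c(5, 6))), c(5, 6))
  expect_error(rubinPool(matrix(numeric(0), 0, 0)), "empty")
  ctx <- newCtx(2)
  set.seed(135)
  rows <- replicate(4, matrix(runif(3, -5, 5)), simplify = FALSE)
  pooledS <- reconstructSecret(
    rubinPoolSecure(lapply(rows, shareSecret, ctx = ctx)))
  expect_lt(max(abs(pooledS - Reduce(`+`, rows) / 4)), 1e-4)
})

test_that("Rubin total variance follows the two-level decomposition", {
  # identical rows: between-variance 0, total = within
  C <- rbind(c(1, 1), c(1, 1))
  W <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(rubinVariance(C, W), c(0.3, 0.7))
  # k = 2, coefficients 0 and 2, within 0: B = 2, T = 3
  expect_equal(rubinVariance(matrix(c(0, 2)), matrix(c(0, 0))), 3)
  expect_error(rubinVariance(matrix(1, 1, 2), matrix(1, 1, 2)), "k >= 2")
  # brute force on random inputs
  set.seed(136)
  C <- matrix(rnorm(15), 5, 3)
  W <- matrix(runif(15), 5, 3)
  brute <- vapply(1:3, function(j)
    mean(W[, j]) + (1 + 1 / 5) * sum((C[, j] - mean(C[, j]))^2) / 4,
    numeric(1))
  expect_equal(rubinVariance(C, W), brute, tolerance = 1e-12)
})

test_that("pooled result is consistent and p-values behave", {
  set.seed(137)
  X <- cbind(rnorm(150), rnorm(150))
  y <- 1 + 2 * X[, 1] + rnorm(150, 0, 0.2)  # X2 is pure noise
  mask <- matrix(1, 150, 2); mask[sample(150, 40), 1] <- 0
  task <- imputationTask(X * mask, mask, y)
  res <- multipleImputeAnalyze(task, k = 5L)
  expect_equal(pooledCoef(res), colMeans(res@coefficients),
               tolerance = 1e-12)
  pv <- pooledPValues(res)
  expect_lt(pv[1], 0.05)   # strong real effect
  expect_gt(pv[2], 0.05)   # pure-noise covariate
})
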