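# Regression contract: closed form vs gradient descent, plaintext vs
# secure, secure small-matrix inversion, prediction noise.

test_that("bias column is appended (and appending is not idempotent)", {
  X <- matrix(1:6, 3, 2)
  Xt <- appendBias(X)
  expect_identical(dim(Xt), c(3L, 3L))
  expect_identical(Xt[, 3], rep(1, 3))
  expect_identical(ncol(appendBias(Xt)), 4L)
  expect_identical(appendBias(matrix(numeric(0), 3, 0)),
                   matrix(1, 3, 1))
})

test_that("closed form recovers an exact line and flags singular input", {
  fit <- fitPlain(regressionModel("linear"), matrix(0:2), c(1, 3, 5))
  expect_equal(coef(fit), c(2, 1), tolerance = 1e-10)
  Xs <- cbind(1:5, 2 * (1:5))  # collinear
  expect_error(fitPlain(regressionModel("linear"), Xs, rnorm(5)),
               "singular")
})

test_that("full-batch GD converges to the closed form and the update is
           exactly w + (R - C w) * step", {
  set.seed(71)
  pb <- linearProblem(200, 5)
  X5 <- scale(pb$X)
  gd <- fitPlain(regressionModel("linear", epochs = 2000L, step = 0.01),
                 X5, pb$y)
  Xt <- appendBias(X5)
  wCF <- solve(crossprod(Xt), crossprod(Xt, pb$y))
  expect_lt(max(abs(coef(gd) - wCF)), 1e-3)
  # hand-rolled epoch loop
  C <- crossprod(Xt) / nrow(Xt); R <- crossprod(Xt, pb$y) / nrow(Xt)
  w <- numeric(6)
  for (e in 1:50) w <- w + (R - C %*% w) * 0.05
  ours <- fitPlain(regressionModel("linear", epochs = 50L, step = 0.05),
                   X5, pb$y)
  expect_equal(coef(ours), as.numeric(w), tolerance = 1e-12)
  # divergence detector
  expect_error(fitPlain(regressionModel("linear", epochs = 500L, step = 3),
                        X5, pb$y), "diverged")
})

test_that("mini-batch linear GD runs and approaches the closed form", {
  set.seed(72)
  pb <- linearProblem(120, 4)
  mb <- fitPlain(regressionModel("linear", epochs = 800L, step = 0.05,
                                 batchSize = 40L), pb$X, pb$y)
  Xt <- appendBias(pb$X)
  wCF <- as.numeric(solve(crossprod(Xt), crossprod(Xt, pb$y)))
  expect_lt(max(abs(coef(mb) - wCF)), 0.05)
})

test_that("secure closed-form linear fits match plaintext within 1e-3", {
  ctx <- newCtx(81)
  set.seed(81)
  worst <- 0
  for (i in 1:20) {
    pb <- linearProblem(50, 2)
    fitP <- fitPlain(regressionModel("linear"), pb$X, pb$y)
    ws <- fitSecure(regressionModel("linear"), shareSecret(pb$X, ctx),
                    shareSecret(pb$y, ctx), ctx)
    worst <- max(worst, max(abs(reconstructSecret(ws) - coef(fitP))))
  }
  expect_lt(worst, 1e-3)
})

test_that("secure GD linear fit matches plaintext GD within 1e-3", {
  ctx <- newCtx(82)
  set.seed(82)
  pb <- linearProblem(150, 5)
  model <- regressionModel("linear", epochs = 2000L, step = 0.05)
  fitP <- fitPlain(model, pb$X, pb$y)
  ws <- fitSecure(model, shareSecret(pb$X, ctx), shareSecret(pb$y, ctx),
                  ctx)
  expect_lt(max(abs(reconstructSecret(ws) - coef(fitP))), 1e-3)
})

test_that("logistic: stationary start, sign recovery, secure parity", {
  # balanced labels per covariate pattern leave w = 0 stationary
  X <- matrix(rep(c(-1, 1), each = 10))
  y <- rep(c(0, 1), 10)  # mean 0.5 within each pattern
  fit <- fitPlain(regressionModel("logistic", epochs = 50L,
                                  sigmoid = "exact", standardize = FALSE),
                  X, y)
  expect_equal(coef(fit), c(0, 0), tolerance = 1e-12)
  # separable 1-D data gives a positive slope
  set.seed(91)
  x1 <- matrix(c(rnorm(40, -2), rnorm(40, 2)))
  y1 <- rep(c(0, 1), each = 40)
  fitSep <- fitPlain(regressionModel("logistic"), x1, y1)
  expect_gt(coef(fitSep)[1], 0)
  expect_error(fitPlain(regressionModel("logistic"), x1, rnorm(80)), "0/1")
  # secure vs plaintext on a random 200 x 2 problem
  ctx <- newCtx(91)
  X2 <- matrix(rnorm(400), 200, 2)
  p <- plogis(0.8 * X2[, 1] - 0.5 * X2[, 2])
  y2 <- rbinom(200, 1, p)
  model <- regressionModel("logistic")
  fitP <- fitPlain(model, X2, y2)
  ws <- fitSecure(model, shareSecret(X2, ctx), shareSecret(y2, ctx), ctx)
  expect_lt(max(abs(reconstructSecret(ws) - coef(fitP))), 1e-2)
})

test_that("prediction adds calibrated noise and logistic w = 0 gives 0.5", {
  m <- regressionModel("linear")
  m@weights <- c(2, 1)
  expect_identical(predictModel(m, matrix(3)), 7)
  lg <- regressionModel("logistic", sigmoid = "exact")
  lg@weights <- c(0, 0)
  expect_identical(predictModel(lg, matrix(rnorm(5))), rep(0.5, 5))
  set.seed(101)
  base <- predictModel(m, matrix(rep(3, 1e5)))
  noisy <- predictModel(m, matrix(rep(3, 1e5)), noiseVar = 0.01)
  expect_lt(abs(sd(noisy - base) - 0.1), 0.005)
})

test_that("secure small-matrix inversion matches plaintext", {
  ctx <- newCtx(111)
  ident <- reconstructSecret(secureInverseSmall(shareSecret(diag(3), ctx),
                                                ctx))
  expect_lt(max(abs(ident - diag(3))), 1e-4)
  d <- reconstructSecret(secureInverseSmall(shareSecret(diag(c(2, 4)), ctx),
                                            ctx))
  expect_lt(max(abs(d - diag(c(0.5, 0.25)))), 1e-3)
  set.seed(111)
  worst <- 0
  for (i in 1:50) {
    Cm <- randomSPD(3)
    ci <- reconstructSecret(secureInverseSmall(shareSecret(Cm, ctx), ctx))
    worst <- max(worst, max(abs(ci - solve(Cm))))
  }
  expect_lt(worst, 1e-3)
  expect_error(secureInverseSmall(shareSecret(diag(4), ctx), ctx), "<= 3")
  expect_error(secureInverseSmall(shareSecret(-diag(2), ctx), ctx),
               "not positive")
})

test_that("secure prediction matches plaintext prediction", {
  ctx <- newCtx(121)
  set.seed(121)
  X <- matrix(rnorm(60), 20, 3)
  w <- c(1.5, -2, 0.5, 0.25)
  eta <- as.numeric(appendBias(X) %*% w)
  ws <- shareSecret(matrix(w), ctx)
  out <- reconstructSecret(predictSecure("linear", shareSecret(X, ctx), ws,
                                         ctx))
  expect_equal(as.numeric(out), eta, tolerance = 1e-6)
  noise <- rnorm(20)
  outN <- reconstructSecret(predictSecure("linear", shareSecret(X, ctx), ws,
                                          ctx, noise = noise))
  expect_equal(as.numeric(outN), eta + noise, tolerance = 1e-6)
})
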