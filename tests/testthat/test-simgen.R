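# Simulation scenario generators: shapes, rates, mechanisms, outcome model.

test_that("scenario shapes, kinds and determinism", {
  ds <- genScenario(scenarioSpec(1, 500, seed = 7))
  expect_identical(dim(ds@X), c(500L, 10L))
  expect_identical(dim(ds@mask), c(500L, 10L))
  expect_true(all(ds@mask[, -1] == 1))
  ds2 <- genScenario(scenarioSpec(1, 500, seed = 7))
  expect_identical(ds@X, ds2@X)
  expect_identical(ds@mask, ds2@mask)
  expect_identical(ds@y, ds2@y)
  dsb <- genScenario(scenarioSpec(2, 300, seed = 3))
  expect_true(all(dsb@X[, 1] %in% c(0, 1)))
  ds3 <- genScenario(scenarioSpec(3, 400, seed = 3))
  expect_identical(ncol(ds3@X), 2L)
  expect_error(scenarioSpec(7), "1-6")
})

test_that("masked-entry counts hit the target rates", {
  # scenario 1 at n=500: expected count 150 (30%)
  counts <- vapply(1:30, function(s)
    sum(genScenario(scenarioSpec(1, 500, seed = s))@mask[, 1] == 0),
    numeric(1))
  expect_lt(abs(mean(counts) - 150), 2 * sqrt(500 * 0.3 * 0.7 / 30))
  # calibrated mechanisms: achieved rate within 2 binomial sd of target
  for (sc in 3:6) {
    spec <- scenarioSpec(sc, 2000, seed = 5)
    rate <- mean(genScenario(spec)@mask[, 1] == 0)
    tol <- 2 * sqrt(spec@missingRate * (1 - spec@missingRate) / 2000)
    expect_lt(abs(rate - spec@missingRate), tol + 0.01)
  }
})

test_that("predictor distributions match their analytic moments", {
  ds <- genScenario(scenarioSpec(3, 1e5, seed = 9))
  expect_equal(var(ds@X[, 2]), 3.0, tolerance = 0.05)        # U(-3,3)
  # X1 | X2 ~ N(0.2 - 0.5 X2, 1)
  resid <- ds@X[, 1] - (0.2 - 0.5 * ds@X[, 2])
  expect_equal(mean(resid), 0, tolerance = 0.02)
  expect_equal(sd(resid), 1, tolerance = 0.02)
  ds4 <- genScenario(scenarioSpec(4, 1e5, seed = 9))
  expect_equal(mean(ds4@X[, 1]), mean(plogis(0.2 - 0.5 * ds4@X[, 2])),
               tolerance = 0.01)
})

test_that("outcome noise follows the per-row |linear predictor|/100 law", {
  ds <- genScenario(scenarioSpec(1, 1e5, seed = 13))
  lin <- 1 + rowSums(ds@X)
  z <- (ds@y - lin) / sqrt(abs(lin) / 100)
  expect_equal(sd(z), 1, tolerance = 0.02)
  expect_equal(mean(z), 0, tolerance = 0.02)
})

test_that("MAR missingness is ignorable given X2; MNAR is not", {
  ds <- genScenario(scenarioSpec(3, 2e4, seed = 17))
  miss <- as.integer(ds@mask[, 1] == 0)
  # glm as the independent oracle for the selection model
  fitMAR <- glm(miss ~ ds@X[, 1] + ds@X[, 2], family = binomial)
  zX1 <- summary(fitMAR)$coefficients[2, 3]
  expect_lt(abs(zX1), 3)  # X1 carries no signal beyond X2
  zX2 <- summary(fitMAR)$coefficients[3, 3]
  expect_gt(abs(zX2), 5)  # the selection driver is strongly present
  ds5 <- genScenario(scenarioSpec(5, 2e4, seed = 17))
  miss5 <- as.integer(ds5@mask[, 1] == 0)
  fitMNAR <- glm(miss5 ~ ds5@X[, 1], family = binomial)
  expect_gt(abs(summary(fitMNAR)$coefficients[2, 3]), 5)
})

test_that("binary-outcome variant is balanced and sign-recoverable", {
  ds <- genBinaryOutcome(scenarioSpec(1, 5000, seed = 19))
  expect_true(all(ds@y %in% c(0, 1)))
  expect_equal(mean(ds@y), 0.5, tolerance = 0.05)
  ds2 <- genBinaryOutcome(scenarioSpec(1, 5000, seed = 19))
  expect_identical(ds@y, ds2@y)
  fit <- fitPlain(regressionModel("logistic"), ds@X, ds@y)
  expect_true(all(coef(fit)[1:10] > 0))
})

test_that("datasets convert to tasks with the right kinds", {
  ds <- genScenario(scenarioSpec(2, 200, seed = 21))
  task <- asImputationTask(ds)
  expect_identical(task@columnKinds[1], "binary")
  expect_true(all(task@data[task@mask == 0] == 0))
})
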