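# Evaluation statistics: coefficient moments, imputation/prediction error,
# rank AUC and the discrepancy count.

test_that("theta bias/sd/rmse satisfy their defining identity", {
  theta <- rep(1, 4)
  runs <- rbind(theta, theta, theta)
  expect_equal(unname(thetaStats(runs, theta)), c(0, 0, 0))
  # two symmetric runs around the truth
  delta <- 0.3
  runs2 <- rbind(theta + c(delta, 0, 0, 0), theta - c(delta, 0, 0, 0))
  st <- thetaStats(runs2, theta)
  expect_equal(unname(st), c(0, delta, delta), tolerance = 1e-12)
  set.seed(151)
  runsR <- matrix(rnorm(60), 12, 5)
  stR <- thetaStats(runsR, rnorm(5))
  expect_lt(abs(stR["rmse"]^2 - stR["bias"]^2 - stR["sd"]^2), 1e-12)
})

test_that("imputation error matches half-normal moments on pure noise", {
  n <- 400L
  truth <- matrix(rnorm(n^0 * n * 2), n, 2)
  mask <- matrix(1, n, 2)
  expect_error(imputationError(truth, truth, mask), "no missing")
  mask[, 1] <- 0
  expect_equal(unname(imputationError(truth, truth, mask)), c(0, 0))
  set.seed(152)
  big <- matrix(rnorm(1e5), ncol = 1)
  bigMask <- matrix(0, 1e5, 1)
  noisy <- big + rnorm(1e5)
  err <- imputationError(noisy, big, bigMask)
  expect_equal(unname(err["mean"]), sqrt(2 / pi), tolerance = 0.01)
  expect_equal(unname(err["sd"]), sqrt(1 - 2 / pi), tolerance = 0.01)
  # binary: perfect imputation
  bt <- matrix(rbinom(50, 1, 0.5), 50, 1)
  bm <- matrix(0, 50, 1)
  bi <- imputationError(bt, bt, bm, kind = "binary", probs = bt)
  expect_identical(unname(bi), c(1, 1))
})

test_that("prediction error agrees with a brute-force row loop", {
  set.seed(153)
  X <- matrix(rnorm(60), 20, 3)
  w <- c(1, -1, 0.5, 2)
  y <- as.numeric(appendBias(X) %*% w)
  expect_equal(unname(predictionError(w, X, y)), c(0, 0))
  y2 <- y + rnorm(20)
  pe <- predictionError(w, X, y2)
  d <- vapply(1:20, function(i)
    abs(sum(c(X[i, ], 1) * w) - y2[i]), numeric(1))
  expect_equal(unname(pe), c(mean(d), sd(d)), tolerance = 1e-12)
  # constant predictor on balanced binary outcome
  yb <- rep(c(0, 1), 10)
  pb <- predictionError(c(0, 0, 0, 0), X, yb, kind = "logistic")
  expect_equal(unname(pb), c(0.5, 0.5))
})

test_that("rank AUC handles order, ties and the null", {
  expect_identical(aucRank(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_identical(aucRank(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(aucRank(1:5, rep(1, 5)), "both classes")
  set.seed(154)
  sc <- runif(1e4); lb <- rbinom(1e4, 1, 0.5)
  expect_equal(aucRank(sc, lb), 0.5, tolerance = 0.02)
  if (requireNamespace("pROC", quietly = TRUE)) {
    sc2 <- rnorm(500); lb2 <- rbinom(500, 1, plogis(sc2))
    ref <- as.numeric(pROC::auc(pROC::roc(lb2, sc2, quiet = TRUE)))
    expect_equal(aucRank(sc2, lb2), ref, tolerance = 1e-12)
  }
})

test_that("discrepancy counting follows the directional definition", {
  base <- list(pooled = c(2, -1, 0.5, 1), pvalues = c(0.01, 0.2, 0.03, 0.5))
  expect_identical(discrepancyCount(base, base), 0L)
  # sign flip on a base-significant variable
  flip <- list(pooled = c(-2, -1, 0.5, 1), pvalues = c(0.01, 0.2, 0.03, 0.5))
  expect_identical(discrepancyCount(base, flip), 1L)
  # lost significance
  lost <- list(pooled = c(2, -1, 0.5, 1), pvalues = c(0.2, 0.2, 0.03, 0.5))
  expect_identical(discrepancyCount(base, lost), 1L)
  # nothing significant in the base gates everything off
  weak <- list(pooled = c(2, -1, 0.5, 1), pvalues = rep(0.2, 4))
  expect_identical(discrepancyCount(weak, flip), 0L)
  # directional: the reverse comparison can differ
  expect_identical(discrepancyCount(lost, base), 0L)
  expect_error(discrepancyCount(base, list(pooled = 1:2, pvalues = 1:2)),
               "variable sets")
})
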