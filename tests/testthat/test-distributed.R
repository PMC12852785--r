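# Partitioned dataflow: aggregation, the two multiplication pairings,
# distributed fits vs their centralised counterparts, and the operation
# log contract.

test_that("aggregation decodes to sum / concatenation", {
  be <- shareBackend(newCtx(141))
  one <- partitionedMatrix(list(matrix(1:6 / 2, 3, 2)), "additive")
  agg1 <- aggregateParts(one, be)
  expect_equal(decodeAggregated(agg1, be), matrix(1:6 / 2, 3, 2),
               tolerance = 1e-8)
  threes <- aggregateParts(
    partitionedMatrix(replicate(3, matrix(1, 3, 3), simplify = FALSE),
                      "additive"), be)
  expect_equal(decodeAggregated(threes, be), matrix(3, 3, 3),
               tolerance = 1e-8)
  set.seed(141)
  M <- matrix(runif(12, -5, 5), 3, 4)
  p1 <- matrix(runif(12, -5, 5), 3, 4)
  p2 <- matrix(runif(12, -5, 5), 3, 4)
  split3 <- list(p1, p2, M - p1 - p2)
  agg <- aggregateParts(partitionedMatrix(split3, "additive"), be)
  expect_equal(decodeAggregated(agg, be), M, tolerance = 1e-8)
  # horizontal concatenation
  hb <- partitionRows(M, 2L)
  aggH <- aggregateParts(partitionedMatrix(hb, "horizontal"), be)
  expect_equal(decodeAggregated(aggH, be), M, tolerance = 1e-8)
  expect_error(partitionedMatrix(list(matrix(1, 2, 2), matrix(1, 3, 3)),
                                 "additive"), "shape")
})

test_that("vertical x horizontal block products sum to the pooled Gramian", {
  set.seed(142)
  be <- shareBackend(newCtx(142))
  X <- matrix(rnorm(60), 20, 3)
  blocks <- partitionRows(X, 3L)
  vert <- partitionedMatrix(lapply(blocks, t), "vertical")
  horiz <- partitionedMatrix(blocks, "horizontal")
  prod_ <- partitionedMatmul(vert, horiz, be)
  expect_identical(prod_@partitioning, "additive")
  expect_equal(Reduce(`+`, prod_@blocks), crossprod(X), tolerance = 1e-12)
})

test_that("additive x aggregated products decode to the global product", {
  be <- shareBackend(newCtx(143))
  set.seed(143)
  A <- matrix(runif(9, -3, 3), 3, 3)
  blocksA <- list(A * 0.2, A * 0.5, A * 0.3)
  Iagg <- aggregateParts(partitionedMatrix(list(diag(3)), "additive"), be)
  res <- partitionedMatmul(partitionedMatrix(blocksA, "additive"), Iagg, be)
  total <- Reduce(smcAdd, res@blocks)
  expect_equal(reconstructSecret(total), A, tolerance = 1e-6)
  B <- matrix(runif(9, -3, 3), 3, 3)
  Bagg <- aggregateParts(partitionedMatrix(list(B), "additive"), be)
  res2 <- partitionedMatmul(partitionedMatrix(blocksA, "additive"), Bagg, be)
  expect_equal(reconstructSecret(Reduce(smcAdd, res2@blocks)), A %*% B,
               tolerance = 1e-6)
  expect_error(partitionedMatmul(partitionedMatrix(blocksA, "additive"),
                                 partitionedMatrix(blocksA, "additive"), be),
               "unsupported")
})

test_that("distributed linear fits equal the centralised fit", {
  be <- shareBackend(newCtx(144))
  # one party, tiny exact line
  w1 <- mheLinregFit(regressionModel("linear"), list(matrix(0:2)),
                     list(c(1, 3, 5)), be)
  expect_equal(as.numeric(reconstructSecret(w1)), c(2, 1), tolerance = 1e-3)
  # 3-party split of the same exact line, one row each
  w3 <- mheLinregFit(regressionModel("linear"),
                     list(matrix(0), matrix(1), matrix(2)),
                     list(1, 3, 5), be)
  expect_equal(as.numeric(reconstructSecret(w3)), c(2, 1), tolerance = 1e-3)
  # random 300 x 5 problem vs centralised closed form (GD path, p >= 4)
  set.seed(144)
  pb <- linearProblem(300, 5)
  blocks <- partitionRows(pb$X, 3L)
  yblocks <- partitionRows(pb$y, 3L)
  wD <- mheLinregFit(regressionModel("linear"), blocks, yblocks, be)
  Xt <- appendBias(pb$X)
  wCF <- as.numeric(solve(crossprod(Xt), crossprod(Xt, pb$y)))
  expect_lt(max(abs(as.numeric(reconstructSecret(wD)) - wCF)), 1e-3)
})

test_that("distributed logistic fit equals the centralised secure fit and
           aggregates the design exactly twice", {
  set.seed(145)
  X <- matrix(rnorm(400), 200, 2)
  y <- rbinom(200, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  model <- regressionModel("logistic", epochs = 120L)
  # centralised (one party)
  be1 <- shareBackend(newCtx(145))
  w1 <- as.numeric(reconstructSecret(
    mheLogregFit(model, list(X), list(y), be1)))
  # three parties
  be3 <- shareBackend(newCtx(146))
  agg0 <- backendLog(be3)$aggregations
  w3 <- as.numeric(reconstructSecret(
    mheLogregFit(model, partitionRows(X, 3L), partitionRows(y, 3L), be3)))
  expect_identical(backendLog(be3)$aggregations - agg0, 2L)
  expect_lt(max(abs(w3 - w1)), 1e-2)
  # and both match the plaintext fit
  wP <- coef(fitPlain(model, X, y))
  expect_lt(max(abs(w3 - wP)), 1e-2)
})

test_that("distributed MICE matches pooled plaintext MICE and is
           invariant to re-partitioning", {
  set.seed(146)
  X2 <- rnorm(600)
  Xexact <- cbind(2 * X2, X2)   # exactly linear: imputation oracle fixture
  maskE <- matrix(1, 600, 2); maskE[sample(600, 180), 1] <- 0
  yE <- 1 + rowSums(Xexact) + rnorm(600, 0, 0.1)
  be <- shareBackend(newCtx(147))
  res <- mheMiceAnalyze(partitionRows(Xexact * maskE, 3L),
                        partitionRows(yE, 3L), partitionRows(maskE, 3L),
                        k = 2L, backend = be, noiseVar = 0)
  imput <- res@imputed[[1L]]
  expect_lt(max(abs(imput[maskE[, 1] == 0, 1] -
                      Xexact[maskE[, 1] == 0, 1])), 1e-2)
  # permutation invariance needs a well-conditioned final Gramian
  X <- cbind(2 * X2 + rnorm(600, 0, 0.5), X2)
  mask <- maskE
  y <- 1 + rowSums(X) + rnorm(600, 0, 0.1)
  beA <- shareBackend(newCtx(148))
  resA <- mheMiceAnalyze(partitionRows(X * mask, 3L), partitionRows(y, 3L),
                         partitionRows(mask, 3L), k = 2L, backend = beA,
                         noiseVar = 0)
  beB <- shareBackend(newCtx(149))
  sizes <- c(100, 350, 150)
  cuts <- rep(1:3, sizes)
  split2 <- function(M) lapply(1:3, function(i) M[cuts == i, , drop = FALSE])
  resB <- mheMiceAnalyze(split2(X * mask), lapply(1:3, function(i)
                           y[cuts == i]), split2(mask), k = 2L,
                         backend = beB, noiseVar = 0)
  expect_lt(max(abs(resB@pooled - resA@pooled)), 1e-6)
  # one party, no missingness: centralised regression result
  be3 <- shareBackend(newCtx(150))
  resC <- mheMiceAnalyze(list(X), list(y), list(matrix(1, 600, 2)), k = 1L,
                         backend = be3)
  direct <- coef(fitPlain(regressionModel("linear"), X, y))
  expect_lt(max(abs(resC@pooled - direct)), 1e-3)
})
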