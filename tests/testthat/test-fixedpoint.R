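# Fixed-point ring: encoding, sharing, local arithmetic, Beaver products,
# truncation and the dealer.

test_that("fixed-point encode/decode round-trips within quantisation", {
  cfg <- fixedPointConfig()
  expect_identical(fpDecode(fpEncode(0, cfg), cfg), 0)
  expect_identical(fpDecode(fpEncode(1, cfg), cfg), 1)
  # 1.0 encodes to exactly 2^fracBits: decoding after dividing by 2 (one
  # public bit-shift worth) halves it exactly
  expect_identical(fpDecode(fpEncode(-1, cfg), cfg), -1)
  expect_equal(fpDecode(fpEncode(pi, cfg), cfg), pi, tolerance = 2^-31)
  set.seed(1)
  x <- runif(1e4, -100, 100)
  err <- abs(fpDecode(fpEncode(x, cfg), cfg) - x)
  expect_lt(max(err), 2^-32 + 1e-15)
})

test_that("encoding rejects out-of-range and non-finite values", {
  cfg <- fixedPointConfig()
  expect_error(fpEncode(2^31, cfg), "overflow")
  expect_error(fpEncode(NA_real_, cfg), "finite")
  expect_error(fixedPointConfig(fracBits = 70L), "fracBits")
  expect_error(fixedPointConfig(totalBits = 100L), "totalBits")
})

test_that("sharing reconstructs bit-exactly and masks the secret", {
  ctx <- newCtx(7)
  set.seed(7)
  for (i in 1:25) {
    M <- matrix(runif(12, -50, 50), 4, 3)
    s <- shareSecret(M, ctx)
    expect_identical(reconstructSecret(s), matrix(fpDecode(fpEncode(M)), 4, 3))
  }
  # a share of zero still has (almost surely) nonzero per-party values
  z <- shareSecret(matrix(0, 2, 2), ctx)
  expect_true(all(vapply(partyShares(z), function(r) any(r != as.raw(0)),
                         logical(1))))
  # more than two parties reconstruct as well (no truncation involved)
  ctx3 <- newCtx(8, parties = 4L)
  M <- matrix(rnorm(6), 2, 3)
  expect_equal(reconstructSecret(shareSecret(M, ctx3)), M, tolerance = 2^-31)
})

test_that("single-party shares look uniform (low-byte chi-squared)", {
  ctx <- newCtx(3)
  secret <- matrix(2.5)
  lows <- vapply(1:20000, function(i) {
    s <- shareSecret(secret, ctx)
    as.integer(partyShares(s)[[1]][1])
  }, integer(1))
  p <- suppressWarnings(chisq.test(tabulate(lows + 1L, 256))$p.value)
  expect_gt(p, 0.001)
})

test_that("local add/sub/scale act share-wise with no interaction", {
  ctx <- newCtx(11)
  A <- matrix(rnorm(6), 2, 3); B <- matrix(rnorm(6), 2, 3)
  sa <- shareSecret(A, ctx); sb <- shareSecret(B, ctx)
  sum_ <- smcAdd(sa, sb)
  # each party's output share is a function of its own input shares only
  for (p in 1:2)
    expect_identical(partyShares(sum_)[[p]],
                     secureMICE:::ring_add(partyShares(sa)[[p]],
                                           partyShares(sb)[[p]], 3L))
  expect_equal(reconstructSecret(sum_), A + B, tolerance = 2^-30)
  expect_equal(reconstructSecret(smcSub(sa, sb)), A - B, tolerance = 2^-30)
  expect_true(all(reconstructSecret(smcSub(sa, sa)) == 0))
  expect_equal(reconstructSecret(smcAddPublic(sa, 2.5)), A + 2.5,
               tolerance = 2^-30)
  expect_equal(reconstructSecret(smcScalePublic(sa, -1.25)), -1.25 * A,
               tolerance = 2^-29)
  expect_error(smcAdd(sa, shareSecret(matrix(1, 3, 2), ctx)), "shape")
})

test_that("power-of-two public scaling loses no extra precision", {
  ctx <- newCtx(12)
  x <- matrix(c(0.1, -3.75, 12.5, 100.25))
  s <- shareSecret(x, ctx)
  err1 <- max(abs(reconstructSecret(smcScalePublic(s, 2^-4)) - x * 2^-4))
  errOdd <- max(abs(reconstructSecret(smcScalePublic(s, 1 / 3)) - x / 3))
  expect_lt(err1, 2^-32 * 4)
  # general scalars also quantise the factor: error grows with |x|
  expect_lt(errOdd, (max(abs(x)) + 2) * 2^-32)
})

test_that("Beaver products match plaintext within 1e-6", {
  ctx <- newCtx(21)
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    A <- matrix(runif(64, -10, 10), 8, 8)
    B <- matrix(runif(64, -10, 10), 8, 8)
    P <- reconstructSecret(smcMatmul(shareSecret(A, ctx),
                                     shareSecret(B, ctx), ctx))
    worst <- max(worst, max(abs(P - A %*% B)))
  }
  expect_lt(worst, 1e-6)
  # scalar sanity and absorbing zero
  s2 <- shareSecret(matrix(2), ctx); s3 <- shareSecret(matrix(3), ctx)
  expect_equal(reconstructSecret(smcMulElem(s2, s3, ctx))[1], 6,
               tolerance = 2^-30)
  z <- reconstructSecret(smcMulElem(s2, shareSecret(matrix(0), ctx), ctx))
  expect_lt(abs(z), 2^-30)
})

test_that("explicit Beaver triples are exact, single-use and logged", {
  ctx <- newCtx(31)
  n0 <- triplesIssued(ctx)
  trs <- dealerIssueTriples(ctx, c(3L, 2L), c(2L, 4L), count = 5L)
  expect_identical(triplesIssued(ctx) - n0, 5L)
  for (tr in trs) {
    a <- reconstructSecret(tr@a, decode = FALSE)
    b <- reconstructSecret(tr@b, decode = FALSE)
    c <- reconstructSecret(tr@c, decode = FALSE)
    expect_identical(as.raw(secureMICE:::ring_matmul(a, b, 3L, 2L, 4L, 3L)),
                     as.raw(c))
  }
  # distinctness over a batch
  keys <- vapply(dealerIssueTriples(ctx, c(2L, 2L), count = 200L),
                 function(tr) paste(as.integer(tr@a@shares[[1]][1:16]),
                                    collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # single use
  tr <- dealerIssueTriples(ctx, c(2L, 2L), c(2L, 2L))[[1]]
  x <- shareSecret(diag(2), ctx)
  smcMul(x, x, tr)
  expect_error(smcMul(x, x, tr), "consumed")
})

test_that("probabilistic truncation divides and drift stays bounded", {
  ctx <- newCtx(41)
  x <- matrix(c(4, -4, 1024, 0.5))
  s <- shareSecret(x, ctx)
  t8 <- reconstructSecret(smcTruncate(s, 8L))
  expect_equal(t8, x / 256, tolerance = 2^-30)
  expect_error(smcTruncate(s, 40L), "fracBits")
  # 1000 chained multiplications by one: drift below 1e-4
  one <- shareSecret(matrix(1), ctx)
  acc <- shareSecret(matrix(1.5), ctx)
  for (i in 1:1000) acc <- smcMulElem(acc, one, ctx)
  expect_lt(abs(reconstructSecret(acc)[1] - 1.5), 1e-4)
})

test_that("structural share operations reorder without loss", {
  ctx <- newCtx(51)
  M <- matrix(rnorm(20), 4, 5)
  s <- shareSecret(M, ctx)
  expect_equal(reconstructSecret(ssmTranspose(s)), t(M), tolerance = 2^-31)
  expect_equal(reconstructSecret(ssmSubset(s, c(2, 4), c(1, 3, 5))),
               M[c(2, 4), c(1, 3, 5)], tolerance = 2^-31)
  v <- shareSecret(matrix(9:12 / 7), ctx)
  M2 <- reconstructSecret(ssmSetColumn(s, 2L, v))
  expect_equal(M2[, 2], 9:12 / 7, tolerance = 2^-31)
  expect_equal(M2[, -2], M[, -2], tolerance = 2^-31)
  ones <- reconstructSecret(ssmAppendOnes(s, ctx))
  expect_equal(ones[, 6], rep(1, 4), tolerance = 2^-31)
})
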