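# Linear and logistic regression, plaintext and secret-shared, sharing one
# contract: closed-form normal equations when the bias-augmented design has
# fewer than 4 columns, otherwise (mini-)batched gradient descent on the
# count-normalised Gramian.

#' Specify a regression model
#'
#' @param kind `"linear"` or `"logistic"`
#' @param epochs gradient-descent epochs (defaults: 2000 linear, 500
#'   logistic — enough for the full-batch update to agree with the closed
#'   form within 1e-3 on well-conditioned standardised problems)
#' @param step step size (defaults: 0.05 linear, 1.0 logistic; the update
#'   uses the count-normalised Gramian / mean gradient, so the stable step
#'   range does not depend on the sample size)
#' @param batchSize mini-batch size; `NA` (default) for full batch
#' @param sigmoid logistic response: `"chebyshev"` evaluates the same
#'   polynomial as the secure path (making the plaintext pipeline the exact
#'   plaintext mirror of the secure algorithm), `"exact"` uses the true
#'   sigmoid
#' @param sigmoidApprox the [ChebyshevApprox-class] used for `"chebyshev"`
#'   and by all secure logistic fits
#' @param standardize centre/scale features before a logistic fit
#' @return a [RegressionModel-class]
#' @export
regressionModel <- function(kind = c("linear", "logistic"), epochs = NULL,
                            step = NULL, batchSize = NA_integer_,
                            sigmoid = c("chebyshev", "exact"),
                            sigmoidApprox = NULL, standardize = NULL) {
  kind <- match.arg(kind)
  sigmoid <- match.arg(sigmoid)
  if (is.null(epochs)) epochs <- if (kind == "linear") 2000L else 500L
  if (is.null(step)) step <- if (kind == "linear") 0.05 else 1.0
  if (is.null(standardize)) standardize <- kind == "logistic"
  if (is.null(sigmoidApprox) && kind == "logistic")
    sigmoidApprox <- fitChebyshev("sigmoid", c(-8, 8), 13L)
  new("RegressionModel", kind = kind, weights = numeric(0),
      epochs = as.integer(epochs), step = step,
      batchSize = as.integer(batchSize), sigmoid = sigmoid,
      sigmoidApprox = sigmoidApprox, standardize = standardize)
}

setMethod("show", "RegressionModel", function(object) {
  cat(sprintf("RegressionModel: %s, epochs %d, step %g%s%s\n", object@kind,
              object@epochs, object@step,
              if (is.na(object@batchSize)) ", full batch"
              else sprintf(", batch %d", object@batchSize),
              if (length(object@weights)) " [fitted]" else ""))
})

#' Append a bias column
#'
#' Adds a column of ones as the last column.  Not idempotent by contract:
#' calling twice adds two columns.
#'
#' @param X data matrix (or a zero-column matrix, yielding just the ones)
#' @export
appendBias <- function(X) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  cbind(X, rep(1, nrow(X)))
}

checkDivergence <- function(w) {
  if (sqrt(sum(w^2)) > 1e6)
    stop("gradient descent diverged (weight norm exceeds 1e6); ",
         "reduce the step size")
}

batchIndices <- function(m, batchSize) {
  if (is.na(batchSize) || batchSize >= m) return(list(seq_len(m)))
  split(seq_len(m), ceiling(seq_len(m) / batchSize))
}

sigmoidFun <- function(model) {
  if (model@sigmoid == "exact") function(x) plogis(x)
  else function(x) evalPlain(model@sigmoidApprox, x)
}

standardizeMap <- function(mu, sdv) {
  p <- length(mu)
  rbind(cbind(diag(1 / sdv, p, p), rep(0, p)),
        c(-mu / sdv, 1))
}

#' Fit a regression model in plaintext
#'
#' Linear: with fewer than 4 design columns the closed form
#' `w = C^{-1} R` on the count-normalised Gramian `C = X'X/m`,
#' `R = X'y/m`; otherwise `epochs` sweeps of `w <- w + (R - C w) * step`
#' (mini-batches recompute per-batch Gramians).  Logistic: full-batch (or
#' mini-batch) gradient descent `w <- w - X'(sigma(Xw) - y) * step / m`
#' on standardised features, with weights mapped back to the original
#' scale.  Weights are initialised at zero for reproducibility.
#'
#' @param model a [RegressionModel-class]
#' @param X feature matrix (no bias column)
#' @param y response (0/1 for logistic)
#' @return the fitted model (weights of length `ncol(X) + 1`, bias last)
#' @examples
#' m <- fitPlain(regressionModel("linear"), matrix(0:2), c(1, 3, 5))
#' coef(m)  # slope 2, bias 1
#' @export
fitPlain <- function(model, X, y) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  y <- as.numeric(y)
  if (model@kind == "linear") {
    model@weights <- fitLinearPlain(model, X, y)
  } else {
    if (!all(y %in% c(0, 1))) stop("logistic response must be 0/1")
    model@weights <- fitLogisticPlain(model, X, y)
  }
  model
}

fitLinearPlain <- function(model, X, y) {
  Xt <- appendBias(X)
  m <- nrow(Xt); p <- ncol(Xt)
  if (m < p) stop("need at least as many rows as design columns")
  if (p < 4L) {
    C <- crossprod(Xt) / m
    R <- crossprod(Xt, y) / m
    w <- tryCatch(solve(C, R),
                  error = function(e) stop("singular Gramian: ", conditionMessage(e)))
    return(as.numeric(w))
  }
  w <- numeric(p)
  batches <- batchIndices(m, model@batchSize)
  if (length(batches) == 1L) {
    C <- crossprod(Xt) / m
    R <- crossprod(Xt, y) / m
    for (e in seq_len(model@epochs)) {
      w <- w + (R - C %*% w) * model@step
      if (e %% 100L == 0L) checkDivergence(w)
    }
  } else {
    for (e in seq_len(model@epochs)) {
      for (b in batches) {
        Cb <- crossprod(Xt[b, , drop = FALSE]) / length(b)
        Rb <- crossprod(Xt[b, , drop = FALSE], y[b]) / length(b)
        w <- w + (Rb - Cb %*% w) * model@step
      }
      if (e %% 100L == 0L) checkDivergence(w)
    }
  }
  as.numeric(w)
}

fitLogisticPlain <- function(model, X, y) {
  p0 <- ncol(X)
  if (model@standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv < 1e-12] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  } else {
    mu <- rep(0, p0); sdv <- rep(1, p0); Xs <- X
  }
  Xt <- appendBias(Xs)
  m <- nrow(Xt); p <- ncol(Xt)
  sig <- sigmoidFun(model)
  w <- numeric(p)
  batches <- batchIndices(m, model@batchSize)
  for (e in seq_len(model@epochs)) {
    for (b in batches) {
      Xb <- Xt[b, , drop = FALSE]
      A <- sig(as.numeric(Xb %*% w))
      w <- w - as.numeric(crossprod(Xb, A - y[b])) * model@step / length(b)
    }
    if (e %% 100L == 0L) checkDivergence(w)
  }
  as.numeric(standardizeMap(mu, sdv) %*% w)
}

#' @describeIn fitPlain fitted coefficients (bias last)
#' @param object a fitted [RegressionModel-class]
#' @param ... unused
#' @export
setMethod("coef", "RegressionModel", function(object, ...) object@weights)

#' Predict from a fitted model
#'
#' Linear: `X w + eps` with per-entry Gaussian noise of the supplied
#' variance (used as the stochastic component of imputation draws).
#' Logistic: the response probability `sigma(X w)`; callers threshold at
#' 0.5 for imputation and keep the probability for AUC.
#'
#' @param model a fitted [RegressionModel-class]
#' @param X feature matrix (no bias column)
#' @param noiseVar variance of the additive prediction noise (linear only)
#' @return numeric vector of predictions / probabilities
#' @export
predictModel <- function(model, X, noiseVar = 0) {
  if (!length(model@weights)) stop("model is not fitted")
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  eta <- as.numeric(appendBias(X) %*% model@weights)
  if (model@kind == "linear") {
    if (noiseVar > 0) eta <- eta + rnorm(length(eta), 0, sqrt(noiseVar))
    eta
  } else {
    sigmoidFun(model)(eta)
  }
}

# ---- secure fits -------------------------------------------------------

trivialZeros <- function(nrow, ncol, ctx)
  sharePublic(matrix(0, nrow, ncol), ctx)

#' Fit a regression model on secret shares
#'
#' Executes the same contract as [fitPlain()] entirely on shares: the
#' Gramian and right-hand side are formed by Beaver matrix products, the
#' closed form inverts the (at most 3 x 3) normalised Gramian with
#' [secureInverseSmall()], and gradient descent applies the identical
#' update.  Logistic fits standardise features using revealed aggregate
#' moments (column sums and sums of squares) so the linear predictor stays
#' inside the sigmoid approximation interval, evaluate the sigmoid with
#' [evalSecure()], and map the weights back to the original scale with a
#' public affine transform.  Decoded results agree with the plaintext fit
#' within about 1e-3 (linear) / 1e-2 (logistic) on well-conditioned
#' standardised problems.
#'
#' @param model a [RegressionModel-class]
#' @param Xs shared feature matrix (no bias column)
#' @param ys shared response (one column)
#' @param ctx a [DealerContext-class]
#' @return a [SecretSharedMatrix-class] of coefficients (bias last)
#' @export
fitSecure <- function(model, Xs, ys, ctx) {
  if (model@kind == "linear") fitLinearSecure(model, Xs, ys, ctx)
  else fitLogisticSecure(model, Xs, ys, ctx)
}

fitLinearSecure <- function(model, Xs, ys, ctx) {
  Xt <- ssmAppendOnes(Xs, ctx)
  m <- Xt@dim[1L]; p <- Xt@dim[2L]
  if (m < p) stop("need at least as many rows as design columns")
  Xtt <- ssmTranspose(Xt)
  C <- smcScalePublic(smcMatmul(Xtt, Xt, ctx), 1 / m)
  R <- smcScalePublic(smcMatmul(Xtt, ys, ctx), 1 / m)
  if (p < 4L) {
    Cinv <- secureInverseSmall(C, ctx)
    return(smcMatmul(Cinv, R, ctx))
  }
  # fused kernel: one Beaver product per epoch, protocol-identical to the
  # unfused smcMatmul/smcSub/smcScalePublic/smcAdd sequence
  cfg <- ctx@config
  stepEnc <- ring_encode(model@step, cfg@fracBits, cfg@valueBits, nlimbs(cfg))
  wSh <- smc_lin_gd(ctx@state$rng, C@shares, R@shares, p, model@epochs,
                    stepEnc, nlimbs(cfg), cfg@fracBits)
  ctx@state$triplesIssued <- ctx@state$triplesIssued + model@epochs
  newSSM(wSh, c(p, 1L), cfg)
}

fitLogisticSecure <- function(model, Xs, ys, ctx) {
  m <- Xs@dim[1L]; p0 <- Xs@dim[2L]
  if (model@standardize) {
    # aggregate moments are revealed: column sums and sums of squares only
    onesRow <- matrix(1, 1L, m)
    colSum <- as.numeric(reconstructSecret(smcMatmulPublic(onesRow, Xs)))
    sq <- smcMulElem(Xs, Xs, ctx)
    colSq <- as.numeric(reconstructSecret(smcMatmulPublic(onesRow, sq)))
    mu <- colSum / m
    v <- pmax(colSq / m - mu^2, 0) * m / (m - 1)
    sdv <- sqrt(v)
    sdv[sdv < 1e-12] <- 1
    Xstd <- smcScaleElementwise(smcAddPublic(Xs, matrix(-mu, m, p0, byrow = TRUE)),
                                rep(1 / sdv, each = m))
  } else {
    mu <- rep(0, p0); sdv <- rep(1, p0); Xstd <- Xs
  }
  Xt <- ssmAppendOnes(Xstd, ctx)
  p <- p0 + 1L
  Xtt <- ssmTranspose(Xt)
  w <- trivialZeros(p, 1L, ctx)
  for (e in seq_len(model@epochs)) {
    eta <- smcMatmul(Xt, w, ctx)
    A <- evalSecure(model@sigmoidApprox, eta, ctx)
    g <- smcMatmul(Xtt, smcSub(A, ys), ctx)
    w <- smcSub(w, smcScalePublic(g, model@step / m))
  }
  smcMatmulPublic(standardizeMap(mu, sdv), w)
}

#' Securely predict from shared weights
#'
#' `X w` on shares, with optional plaintext noise added by the
#' coordinating party (linear), or the polynomial sigmoid of the linear
#' predictor (logistic probabilities).
#'
#' @param kind `"linear"` or `"logistic"`
#' @param Xs shared feature matrix (no bias column)
#' @param ws shared coefficient vector (bias last)
#' @param ctx a [DealerContext-class]
#' @param noise plaintext noise vector to add (linear; already drawn by the
#'   coordinator)
#' @param sigmoidApprox approximant for the logistic response
#' @return a [SecretSharedMatrix-class] (one column)
#' @export
predictSecure <- function(kind, Xs, ws, ctx, noise = NULL,
                          sigmoidApprox = NULL) {
  Xt <- ssmAppendOnes(Xs, ctx)
  eta <- smcMatmul(Xt, ws, ctx)
  if (kind == "linear") {
    if (!is.null(noise) && any(noise != 0))
      eta <- smcAddPublic(eta, matrix(noise, ncol = 1L))
    eta
  } else {
    if (is.null(sigmoidApprox)) sigmoidApprox <- fitChebyshev("sigmoid")
    evalSecure(sigmoidApprox, eta, ctx)
  }
}

# ---- secure small-matrix inversion -------------------------------------

ssmGather <- function(s, idx, dim) {
  L <- nlimbs(s@config)
  shares <- lapply(s@shares, ring_subset, idx = as.integer(idx - 1L),
                   nlimbs = L)
  newSSM(shares, as.integer(dim), s@config)
}

adjugateIndices <- function(p) {
  # adj[i,j] = (-1)^(i+j) * minor(M, j, i); each minor is a 2x2 determinant
  pos1 <- pos2 <- neg1 <- neg2 <- integer(p * p)
  lin <- function(i, j) (j - 1L) * p + i
  for (j in 1:p) for (i in 1:p) {
    rr <- setdiff(1:p, j); cc <- setdiff(1:p, i)
    t1 <- c(lin(rr[1], cc[1]), lin(rr[2], cc[2]))
    t2 <- c(lin(rr[1], cc[2]), lin(rr[2], cc[1]))
    if ((i + j) %% 2L == 1L) { tmp <- t1; t1 <- t2; t2 <- tmp }
    k <- lin(i, j)
    pos1[k] <- t1[1]; pos2[k] <- t1[2]; neg1[k] <- t2[1]; neg2[k] <- t2[2]
  }
  list(pos1 = pos1, pos2 = pos2, neg1 = neg1, neg2 = neg2)
}

#' Invert a small shared symmetric positive-definite matrix
#'
#' Computes the adjugate by polynomial share arithmetic (element-wise
#' Beaver products of index-gathered cofactor factors), the determinant by
#' a cofactor expansion, and the determinant reciprocal by Newton-Raphson
#' iteration on shares.  The only revealed quantity is the trace, rounded
#' up to `tracePrecision`; the public Newton initial guess `1 / (t/p)^p`
#' is valid for SPD matrices because `(trace/p)^p >= det` by the
#' AM-GM inequality.
#'
#' @param Cs shared square matrix, dimension at most 3, SPD
#' @param ctx a [DealerContext-class]
#' @param iterations Newton-Raphson iterations (default 20)
#' @param tracePrecision granularity at which the trace is revealed
#' @return a [SecretSharedMatrix-class] holding the inverse (within about
#'   1e-3 of the plaintext inverse for well-scaled inputs)
#' @export
secureInverseSmall <- function(Cs, ctx, iterations = 20L,
                               tracePrecision = 0.01) {
  p <- Cs@dim[1L]
  if (Cs@dim[2L] != p) stop("matrix must be square")
  if (p > 3L) stop("secure inversion supports dimension <= 3 only")
  # revealed trace bound (configurable precision)
  diagIdx <- (seq_len(p) - 1L) * p + seq_len(p)
  dg <- ssmGather(Cs, diagIdx, c(p, 1L))
  tr <- sum(as.numeric(reconstructSecret(dg)))
  tr <- ceiling(tr / tracePrecision) * tracePrecision
  if (tr <= 0) stop("revealed trace bound is not positive; matrix not SPD?")
  if (p == 1L) {
    adj <- sharePublic(matrix(1, 1L, 1L), ctx)
    det <- Cs
  } else if (p == 2L) {
    # 1x1 cofactors: a pure share reordering with sign flips
    adj <- smcScaleElementwise(ssmGather(Cs, c(4L, 2L, 3L, 1L), c(2L, 2L)),
                               c(1, -1, -1, 1))
    firstCol <- ssmGather(Cs, 1:2, c(2L, 1L))
    adjRow1 <- ssmGather(adj, c(1L, 3L), c(2L, 1L))
    det <- smcMatmulPublic(matrix(1, 1L, 2L),
                           smcMulElem(firstCol, adjRow1, ctx))
  } else {
    ai <- adjugateIndices(p)
    adj <- smcSub(
      smcMulElem(ssmGather(Cs, ai$pos1, c(p, p)),
                 ssmGather(Cs, ai$pos2, c(p, p)), ctx),
      smcMulElem(ssmGather(Cs, ai$neg1, c(p, p)),
                 ssmGather(Cs, ai$neg2, c(p, p)), ctx))
    firstCol <- ssmGather(Cs, seq_len(p), c(p, 1L))
    adjRow1 <- ssmGather(adj, (seq_len(p) - 1L) * p + 1L, c(p, 1L))
    det <- smcMatmulPublic(matrix(1, 1L, p),
                           smcMulElem(firstCol, adjRow1, ctx))
  }
  y <- sharePublic(matrix(1 / (tr / p)^p, 1L, 1L), ctx)
  two <- sharePublic(matrix(2, 1L, 1L), ctx)
  for (it in seq_len(iterations)) {
    dy <- smcMulElem(det, y, ctx)
    y <- smcMulElem(y, smcSub(two, dy), ctx)
  }
  smcMulElem(adj, ssmBroadcast(y, c(p, p)), ctx)
}
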