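# The chained-equations imputation loop, the multiple-imputation driver and
# Rubin's-rules pooling.  The plaintext and secret-shared paths share one
# contract and consume the imputation-noise stream in the identical order,
# so a fixed seed gives decode-equal results across modes.

#' Create an imputation task
#'
#' @param data numeric matrix (individuals x variables); missing entries
#'   are zero-filled automatically
#' @param mask zero-one matrix of the same shape, 0 = missing (public
#'   throughout the protocol: positions, not values, of missing data leak)
#' @param y outcome vector; never used as an imputation predictor
#' @param columnKinds `"continuous"`/`"binary"` per column; by default a
#'   column is binary when all its observed entries are 0/1
#' @param noiseVar imputation-noise variance for continuous columns
#'   (default 0.01, i.e. N(0, 0.01) draws)
#' @return an [ImputationTask-class]
#' @export
imputationTask <- function(data, mask, y, columnKinds = NULL,
                           noiseVar = 0.01) {
  data <- as.matrix(data)
  mask <- as.matrix(mask)
  data[mask == 0] <- 0
  if (is.null(columnKinds))
    columnKinds <- vapply(seq_len(ncol(data)), function(j) {
      obs <- data[mask[, j] == 1, j]
      if (length(obs) && all(obs %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  new("ImputationTask", data = data, mask = mask, y = as.numeric(y),
      columnKinds = columnKinds, noiseVar = noiseVar)
}

setMethod("show", "ImputationTask", function(object) {
  nm <- sum(object@mask == 0)
  cat(sprintf("ImputationTask: %d x %d, %d missing entries (%.1f%%), noise var %g\n",
              nrow(object@data), ncol(object@data), nm,
              100 * nm / length(object@mask), object@noiseVar))
})

imputeModelFor <- function(kind, imputeSpec) {
  if (kind == "binary") imputeSpec$logistic else imputeSpec$linear
}

#' Default imputation model specification
#'
#' One linear and one logistic template; the column kind selects which is
#' fitted for each incomplete variable.
#'
#' @param linear,logistic [RegressionModel-class] templates
#' @export
imputeSpecDefault <- function(linear = regressionModel("linear"),
                              logistic = regressionModel("logistic")) {
  list(linear = linear, logistic = logistic)
}

#' Chained-equations imputation (single multiple-imputation draw)
#'
#' Visits columns in ascending index order; for each column with missing
#' entries it fits the column-appropriate regression of that column on all
#' other columns using the rows currently fully complete, predicts the
#' missing entries from the mask-zeroed data (so columns not yet visited
#' enter as zeros), adds N(0, `noiseVar`) noise for continuous columns
#' (binary predictions are thresholded at 0.5), writes the predictions into
#' the column and sets its mask to one so later columns reuse the imputed
#' values.  Columns without missing entries are skipped.  Observed entries
#' are never modified.
#'
#' In `"smc"` mode the data matrix is secret-shared and every fit and
#' prediction runs on shares; the mask stays public.  Noise is drawn by
#' the coordinator from R's RNG in the same order as in plaintext mode, so
#' injected draws are identical across modes.
#'
#' @param task an [ImputationTask-class]
#' @param imputeSpec see [imputeSpecDefault()]
#' @param sweeps number of chained passes (default 1)
#' @param mode `"plaintext"` or `"smc"`
#' @param ctx a [DealerContext-class] (required for `"smc"`)
#' @param data optional starting data override: a matrix (plaintext) or a
#'   [SecretSharedMatrix-class] (smc) replacing `task@data`
#' @return the completed data matrix (plaintext) or
#'   [SecretSharedMatrix-class] (smc), with the final all-ones effective
#'   mask in attribute `"mask"`
#' @export
chainedImpute <- function(task, imputeSpec = imputeSpecDefault(),
                          sweeps = 1L, mode = c("plaintext", "smc"),
                          ctx = NULL, data = NULL) {
  mode <- match.arg(mode)
  M <- task@mask
  for (j in seq_len(ncol(M)))
    if (all(M[, j] == 0)) stop("column ", j, " is entirely missing")
  if (mode == "plaintext")
    chainedImputePlain(task, imputeSpec, sweeps,
                       if (is.null(data)) task@data else data)
  else {
    if (is.null(ctx)) stop("'smc' mode needs a dealer context")
    Ds <- if (is.null(data)) shareSecret(task@data, ctx) else data
    chainedImputeSMC(task, imputeSpec, sweeps, Ds, ctx)
  }
}

chainedImputePlain <- function(task, imputeSpec, sweeps, D) {
  M <- task@mask
  for (s in seq_len(sweeps)) for (j in seq_len(ncol(D))) {
    miss <- which(M[, j] == 0)
    if (!length(miss)) next
    comp <- which(rowSums(M == 0) == 0)
    if (!length(comp)) stop("no fully observed rows available for the fit")
    kind <- task@columnKinds[j]
    model <- imputeModelFor(kind, imputeSpec)
    fit <- fitPlain(model, D[comp, -j, drop = FALSE], D[comp, j])
    Z <- (D * M)[miss, -j, drop = FALSE]
    if (kind == "continuous") {
      eps <- rnorm(length(miss), 0, sqrt(task@noiseVar))
      D[miss, j] <- predictModel(fit, Z) + eps
    } else {
      D[miss, j] <- as.numeric(predictModel(fit, Z) > 0.5)
    }
    M[, j] <- 1
  }
  attr(D, "mask") <- M
  D
}

chainedImputeSMC <- function(task, imputeSpec, sweeps, Ds, ctx) {
  M <- task@mask
  n <- ncol(M)
  for (s in seq_len(sweeps)) for (j in seq_len(n)) {
    miss <- which(M[, j] == 0)
    if (!length(miss)) next
    comp <- which(rowSums(M == 0) == 0)
    if (!length(comp)) stop("no fully observed rows available for the fit")
    kind <- task@columnKinds[j]
    model <- imputeModelFor(kind, imputeSpec)
    Xfit <- ssmSubset(Ds, comp, setdiff(seq_len(n), j))
    yfit <- ssmSubset(Ds, comp, j)
    ws <- fitSecure(model, Xfit, yfit, ctx)
    masked <- smcScaleElementwise(Ds, as.numeric(M))
    Z <- ssmSubset(masked, miss, setdiff(seq_len(n), j))
    if (kind == "continuous") {
      eps <- rnorm(length(miss), 0, sqrt(task@noiseVar))
      pred <- predictSecure("linear", Z, ws, ctx, noise = eps)
    } else {
      prob <- predictSecure("logistic", Z, ws, ctx,
                            sigmoidApprox = model@sigmoidApprox)
      # thresholding needs a comparison: the coordinator decodes the
      # probabilities, thresholds at 0.5 and re-shares (documented leakage)
      cls <- as.numeric(reconstructSecret(prob) > 0.5)
      pred <- shareSecret(matrix(cls, ncol = 1L), ctx)
    }
    Ds <- ssmSetEntries(Ds, miss, j, pred)
    M[, j] <- 1
  }
  attr(Ds, "mask") <- M
  Ds
}

# ---- multiple imputation driver ----------------------------------------

withinVariance <- function(kind, X, y, w, sigmoid = plogis) {
  Xt <- appendBias(X)
  m <- nrow(Xt); p <- ncol(Xt)
  if (kind == "linear") {
    resid <- y - as.numeric(Xt %*% w)
    sigma2 <- sum(resid^2) / max(m - p, 1L)
    G <- tryCatch(solve(crossprod(Xt)), error = function(e) NULL)
    if (is.null(G)) return(rep(NA_real_, p))
    sigma2 * diag(G)
  } else {
    pr <- sigmoid(as.numeric(Xt %*% w))
    wt <- pmin(pmax(pr * (1 - pr), 1e-8), 0.25)
    G <- tryCatch(solve(crossprod(Xt * sqrt(wt))), error = function(e) NULL)
    if (is.null(G)) return(rep(NA_real_, p))
    diag(G)
  }
}

#' Multiple imputation with final analysis and Rubin pooling
#'
#' Runs `k` independent chained imputations (fresh noise draws are the only
#' stochastic difference between them when the fits are deterministic),
#' fits the final-analysis model of `y` on each completed covariate matrix,
#' collects the `k` coefficient vectors and pools them by Rubin's rules
#' (arithmetic average — computed on shares without decryption in `"smc"`
#' mode).  Within-imputation variances, the Rubin total variance and Wald
#' p-values are attached for downstream discrepancy analysis; in secure
#' modes these are evaluation-time computations on the released output,
#' not part of the protocol.
#'
#' @inheritParams chainedImpute
#' @param finalSpec the final-analysis [RegressionModel-class]
#' @param k number of imputations (default 5)
#' @param retainImputed keep the completed datasets in the result
#' @return a [MICEResult-class]
#' @examples
#' set.seed(1)
#' X <- cbind(rnorm(80), rnorm(80))
#' mask <- matrix(1, 80, 2); mask[sample(80, 20), 1] <- 0
#' y <- 1 + rowSums(X) + rnorm(80, 0, 0.1)
#' task <- imputationTask(X, mask, y)
#' res <- multipleImputeAnalyze(task, k = 2)
#' pooledCoef(res)
#' @export
multipleImputeAnalyze <- function(task, imputeSpec = imputeSpecDefault(),
                                  finalSpec = regressionModel("linear"),
                                  k = 5L, mode = c("plaintext", "smc"),
                                  ctx = NULL, retainImputed = TRUE) {
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be at least 1")
  m <- nrow(task@data); n <- ncol(task@data)
  coefList <- vector("list", k)
  secureCoefs <- vector("list", k)
  imputedList <- vector("list", k)
  ysShared <- NULL
  for (i in seq_len(k)) {
    if (mode == "plaintext") {
      D <- chainedImpute(task, imputeSpec, mode = "plaintext")
      fit <- fitPlain(finalSpec, D, task@y)
      coefList[[i]] <- coef(fit)
      imputedList[[i]] <- D
    } else {
      Ds <- chainedImpute(task, imputeSpec, mode = "smc", ctx = ctx)
      if (is.null(ysShared)) ysShared <- shareSecret(task@y, ctx)
      ws <- fitSecure(finalSpec, Ds, ysShared, ctx)
      secureCoefs[[i]] <- ws
      coefList[[i]] <- as.numeric(reconstructSecret(ws))
      imputedList[[i]] <- reconstructSecret(Ds)
    }
  }
  C <- do.call(rbind, coefList)
  pooled <- if (mode == "smc") {
    as.numeric(reconstructSecret(rubinPoolSecure(secureCoefs)))
  } else {
    rubinPool(C)
  }
  sig <- if (finalSpec@kind == "logistic" && finalSpec@sigmoid == "chebyshev")
    function(x) evalPlain(finalSpec@sigmoidApprox, x) else plogis
  within <- do.call(rbind, lapply(seq_len(k), function(i)
    withinVariance(finalSpec@kind, imputedList[[i]], task@y, C[i, ], sig)))
  if (k >= 2L) {
    totalVar <- rubinVariance(C, within)
    pv <- 2 * pnorm(-abs(pooled) / sqrt(totalVar))
  } else {
    totalVar <- rep(NA_real_, ncol(C))
    pv <- rep(NA_real_, ncol(C))
  }
  new("MICEResult", coefficients = C, pooled = as.numeric(pooled),
      within = within, totalVar = totalVar, pvalues = pv,
      imputed = if (retainImputed) imputedList else list(), mode = mode)
}

setMethod("show", "MICEResult", function(object) {
  cat(sprintf("MICEResult (%s): %d imputations, %d coefficients\n",
              object@mode, nrow(object@coefficients),
              ncol(object@coefficients)))
  cat("pooled: ", paste(signif(object@pooled, 4), collapse = " "), "\n")
})

#' @describeIn multipleImputeAnalyze pooled coefficient vector (bias last)
#' @param res a [MICEResult-class]
#' @export
pooledCoef <- function(res) res@pooled

#' @describeIn multipleImputeAnalyze Wald p-values from the Rubin total
#'   variance
#' @export
pooledPValues <- function(res) res@pvalues

#' Rubin's-rules pooling of coefficients
#'
#' The pooled coefficient vector is the column-wise arithmetic mean of the
#' per-imputation coefficient rows.
#'
#' @param C k x p coefficient matrix (one imputation per row)
#' @return pooled coefficient vector
#' @export
rubinPool <- function(C) {
  if (!length(C)) stop("empty coefficient input")
  if (!is.matrix(C)) C <- matrix(C, nrow = 1L)
  colMeans(C)
}

#' @rdname rubinPool
#' @param shares list of [SecretSharedMatrix-class] coefficient vectors;
#'   averaging is performed on shares without decryption
#' @export
rubinPoolSecure <- function(shares) {
  if (!length(shares)) stop("empty coefficient input")
  acc <- shares[[1L]]
  for (s in shares[-1L]) acc <- smcAdd(acc, s)
  smcScalePublic(acc, 1 / length(shares))
}

#' Rubin total variance
#'
#' `T = Wbar + (1 + 1/k) B` with `Wbar` the mean within-imputation
#' variance and `B` the between-imputation coefficient variance — the
#' standard completion needed for Wald p-values.
#'
#' @param C k x p coefficient matrix, k >= 2
#' @param within k x p within-imputation variance matrix
#' @return total variance vector (length p)
#' @export
rubinVariance <- function(C, within) {
  if (!is.matrix(C)) C <- matrix(C, ncol = length(C))
  k <- nrow(C)
  if (k < 2L) stop("Rubin total variance needs k >= 2 imputations")
  Wbar <- colMeans(within)
  B <- apply(C, 2, var)
  Wbar + (1 + 1 / k) * B
}
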