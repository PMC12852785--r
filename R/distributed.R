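# Partitioned dataflow for horizontally distributed data: local Gramians in
# the clear at each party, aggregation and downstream algebra behind a
# pluggable secure vector backend.  The default backend is the additive
# secret-sharing engine; slot count and scale of a lattice (CKKS-style)
# backend are carried as contract metadata and every protected operation is
# logged so an alternative backend can drop in and be audited.

#' Create the secure vector backend
#'
#' @param ctx a [DealerContext-class] (its party count must equal the
#'   number of data-holding parties)
#' @param slotCount SIMD slot metadata (default 8192)
#' @param scaleLog2 default scale metadata (default 34)
#' @return a [ShareBackend-class]
#' @export
shareBackend <- function(ctx, slotCount = 8192L, scaleLog2 = 34L) {
  lg <- new.env(parent = emptyenv())
  lg$aggregations <- 0L
  lg$multiplications <- 0L
  lg$localProducts <- 0L
  lg$decryptions <- 0L
  new("ShareBackend", ctx = ctx, slotCount = as.integer(slotCount),
      scaleLog2 = as.integer(scaleLog2), log = lg)
}

setMethod("show", "ShareBackend", function(object) {
  cat(sprintf("ShareBackend: %d parties, %d slots, scale 2^%d\n",
              object@ctx@partyCount, object@slotCount, object@scaleLog2))
  cat(sprintf("  log: %d aggregations, %d protected products, %d local products, %d decryptions\n",
              object@log$aggregations, object@log$multiplications,
              object@log$localProducts, object@log$decryptions))
})

#' @describeIn shareBackend snapshot of the backend operation log
#' @param backend a [ShareBackend-class]
#' @export
backendLog <- function(backend) as.list(backend@log)

#' Construct a partitioned matrix
#'
#' @param blocks per-party matrices (rows for `horizontal`, columns for
#'   `vertical`, summands for `additive`)
#' @param partitioning `"horizontal"`, `"vertical"` or `"additive"`
#' @return a [PartitionedMatrix-class]
#' @export
partitionedMatrix <- function(blocks,
                              partitioning = c("horizontal", "vertical",
                                               "additive")) {
  partitioning <- match.arg(partitioning)
  blocks <- lapply(blocks, as.matrix)
  d <- switch(partitioning,
    horizontal = c(sum(vapply(blocks, nrow, 1L)), ncol(blocks[[1L]])),
    vertical = c(nrow(blocks[[1L]]), sum(vapply(blocks, ncol, 1L))),
    additive = dim(blocks[[1L]]))
  if (partitioning == "vertical" &&
      length(unique(vapply(blocks, nrow, 1L))) != 1L)
    stop("vertical blocks must share a row count")
  if (partitioning == "horizontal" &&
      length(unique(vapply(blocks, ncol, 1L))) != 1L)
    stop("horizontal blocks must share a column count")
  if (partitioning == "additive" &&
      !all(vapply(blocks, function(b) all(dim(b) == d), logical(1))))
    stop("additive blocks must share one shape")
  new("PartitionedMatrix", partitioning = partitioning, blocks = blocks,
      value = NULL, globalDim = as.integer(d))
}

setMethod("show", "PartitionedMatrix", function(object) {
  cat(sprintf("PartitionedMatrix (%s): global %d x %d, %s\n",
              object@partitioning, object@globalDim[1L], object@globalDim[2L],
              if (object@partitioning == "aggregated") "backend-protected"
              else sprintf("%d blocks", length(object@blocks))))
})

#' Split a matrix into contiguous horizontal partitions
#'
#' @param X matrix (or vector) to split by rows
#' @param parties number of parties
#' @return list of row blocks (sizes as equal as possible, in row order)
#' @export
partitionRows <- function(X, parties) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  m <- nrow(X)
  sizes <- rep(m %/% parties, parties) + c(rep(1L, m %% parties),
                                           rep(0L, parties - m %% parties))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(parties), function(i)
    X[seq(starts[i], length.out = sizes[i]), , drop = FALSE])
}

newAggregated <- function(ssm, globalDim) {
  new("PartitionedMatrix", partitioning = "aggregated", blocks = list(),
      value = ssm, globalDim = as.integer(globalDim))
}

# embed local blocks into the share domain without re-randomisation (used
# for values like local label partitions that are only ever combined
# locally with protected operands)
stackLocalSSM <- function(blocks, ctx, globalDim, what = c("rows", "sum")) {
  what <- match.arg(what)
  P <- ctx@partyCount
  acc <- NULL
  ofs <- 0L
  for (i in seq_along(blocks)) {
    party <- ((i - 1L) %% P) + 1L
    g <- matrix(0, globalDim[1L], globalDim[2L])
    if (what == "rows") {
      r <- nrow(blocks[[i]])
      if (r > 0L) g[ofs + seq_len(r), ] <- blocks[[i]]
      ofs <- ofs + r
    } else {
      g <- g + blocks[[i]]
    }
    s <- sharePublic(g, ctx, party = party)
    acc <- if (is.null(acc)) s else smcAdd(acc, s)
  }
  acc
}

#' Aggregate a partitioned matrix into backend-protected form
#'
#' Additive blocks are protected and summed; horizontal / vertical blocks
#' are protected and concatenated.  Every party afterwards holds the same
#' backend-protected value; a fresh zero-sharing re-randomises the result.
#' Blocks that are already protected (results of protected products) are
#' summed share-wise.
#'
#' @param p a [PartitionedMatrix-class]
#' @param backend a [ShareBackend-class]
#' @return an aggregated [PartitionedMatrix-class]
#' @export
aggregateParts <- function(p, backend) {
  ctx <- backend@ctx
  backend@log$aggregations <- backend@log$aggregations + 1L
  if (p@partitioning == "aggregated") return(p)
  blocks <- p@blocks
  if (is(blocks[[1L]], "SecretSharedMatrix")) {
    acc <- blocks[[1L]]
    for (b in blocks[-1L]) acc <- smcAdd(acc, b)
    return(newAggregated(acc, p@globalDim))
  }
  shapes <- lapply(blocks, dim)
  if (p@partitioning != "additive" ||
      all(vapply(blocks, function(b) all(dim(b) == p@globalDim), logical(1)))) {
    NULL
  } else stop("mixed-shape additive blocks")
  gd <- p@globalDim
  P <- ctx@partyCount
  acc <- NULL
  rofs <- 0L; cofs <- 0L
  for (i in seq_along(blocks)) {
    party <- ((i - 1L) %% P) + 1L
    g <- matrix(0, gd[1L], gd[2L])
    b <- blocks[[i]]
    if (p@partitioning == "horizontal") {
      if (nrow(b) > 0L) g[rofs + seq_len(nrow(b)), ] <- b
      rofs <- rofs + nrow(b)
    } else if (p@partitioning == "vertical") {
      if (ncol(b) > 0L) g[, cofs + seq_len(ncol(b))] <- b
      cofs <- cofs + ncol(b)
    } else {
      g <- b
    }
    s <- sharePublic(g, ctx, party = party)
    acc <- if (is.null(acc)) s else smcAdd(acc, s)
  }
  acc <- smcAdd(acc, shareSecret(matrix(0, gd[1L], gd[2L]), ctx))
  newAggregated(acc, gd)
}

#' Decode an aggregated value (evaluation-time decryption)
#'
#' @param p an aggregated [PartitionedMatrix-class]
#' @param backend a [ShareBackend-class]
#' @export
decodeAggregated <- function(p, backend) {
  if (p@partitioning != "aggregated") stop("value is not aggregated")
  backend@log$decryptions <- backend@log$decryptions + 1L
  reconstructSecret(p@value)
}

#' Partitioned matrix multiplication
#'
#' The two pairings the dataflow needs: a vertical partition times a
#' horizontal partition is an additive partition computed locally per party
#' with no communication (the sum of local block products is the global
#' product); an additive partition times an aggregated operand multiplies
#' each local block against the protected value.  Two aggregated operands
#' use a protected (Beaver) product.
#'
#' @param a,b [PartitionedMatrix-class] operands
#' @param backend a [ShareBackend-class]
#' @return a [PartitionedMatrix-class]
#' @export
partitionedMatmul <- function(a, b, backend) {
  ctx <- backend@ctx
  if (a@partitioning == "vertical" && b@partitioning == "horizontal") {
    if (length(a@blocks) != length(b@blocks))
      stop("block counts must agree")
    backend@log$localProducts <- backend@log$localProducts + 1L
    out <- mapply(function(x, y) x %*% y, a@blocks, b@blocks,
                  SIMPLIFY = FALSE)
    return(partitionedMatrix(out, "additive"))
  }
  if (a@partitioning == "additive" && b@partitioning == "aggregated") {
    backend@log$multiplications <- backend@log$multiplications +
      length(a@blocks)
    out <- lapply(a@blocks, function(x) smcMatmulPublic(x, b@value, "left"))
    res <- new("PartitionedMatrix", partitioning = "additive",
               blocks = out, value = NULL,
               globalDim = c(a@globalDim[1L], b@globalDim[2L]))
    return(res)
  }
  if (a@partitioning == "aggregated" && b@partitioning == "aggregated") {
    backend@log$multiplications <- backend@log$multiplications + 1L
    return(newAggregated(smcMatmul(a@value, b@value, ctx),
                         c(a@globalDim[1L], b@globalDim[2L])))
  }
  stop("unsupported partitioning pairing: ", a@partitioning, " x ",
       b@partitioning)
}

# ---- distributed regression fits ---------------------------------------

#' Distributed linear regression over horizontal partitions
#'
#' Local bias-augmented Gramians and right-hand sides are computed in the
#' clear at each party with zero communication (normalised by the pooled
#' row count).  With fewer than 4 design columns both are aggregated, the
#' Gramian is inverted with [secureInverseSmall()] and the closed-form
#' weights are a protected product.  Otherwise each gradient-descent epoch
#' aggregates the current weights and updates the local weight summands
#' against the local Gramian blocks, which reproduces the pooled full-batch
#' update exactly.
#'
#' @param model a linear [RegressionModel-class]
#' @param Xlist,ylist per-party local feature blocks / label blocks
#' @param backend a [ShareBackend-class]
#' @return a [SecretSharedMatrix-class] of coefficients (bias last)
#' @export
mheLinregFit <- function(model, Xlist, ylist, backend) {
  ctx <- backend@ctx
  Xt <- lapply(Xlist, appendBias)
  m <- sum(vapply(Xt, nrow, 1L))
  p <- ncol(Xt[[1L]])
  if (m < p) stop("need at least as many pooled rows as design columns")
  Cb <- lapply(Xt, function(x) crossprod(x) / m)
  Rb <- mapply(function(x, y) crossprod(x, as.numeric(y)) / m, Xt, ylist,
               SIMPLIFY = FALSE)
  if (p < 4L) {
    Cagg <- aggregateParts(partitionedMatrix(Cb, "additive"), backend)
    Ragg <- aggregateParts(partitionedMatrix(Rb, "additive"), backend)
    Cinv <- secureInverseSmall(Cagg@value, ctx)
    backend@log$multiplications <- backend@log$multiplications + 1L
    return(smcMatmul(Cinv, Ragg@value, ctx))
  }
  P <- ctx@partyCount
  cfg <- ctx@config
  L <- nlimbs(cfg)
  Rs <- lapply(seq_along(Rb), function(i)
    sharePublic(Rb[[i]], ctx, party = ((i - 1L) %% P) + 1L))
  Cenc <- lapply(Cb, function(Ci)
    ring_encode(as.numeric(Ci), cfg@fracBits, cfg@valueBits, L))
  stepEnc <- ring_encode(model@step, cfg@fracBits, cfg@valueBits, L)
  # fused kernel: per epoch, the weight summands are aggregated once and
  # each block applies its local update against the protected aggregate
  wSh <- mhe_lin_gd(Cenc, lapply(Rs, function(s) s@shares), p,
                    model@epochs, stepEnc, L, cfg@fracBits)
  backend@log$aggregations <- backend@log$aggregations + model@epochs + 1L
  backend@log$multiplications <- backend@log$multiplications +
    model@epochs * length(Cenc)
  newSSM(wSh, c(p, 1L), cfg)
}

#' Distributed logistic regression over horizontal partitions
#'
#' Pooled standardisation moments are assembled from local sums (revealed
#' aggregate statistics).  The bias-augmented standardised design and its
#' transpose are aggregated exactly once each before the loop — aggregating
#' the data rather than the weights keeps the per-epoch cost to two
#' protected products — and each epoch evaluates the polynomial sigmoid of
#' the protected linear predictor and applies the mean-gradient update with
#' the labels entering as local partitions.
#'
#' @inheritParams mheLinregFit
#' @return a [SecretSharedMatrix-class] of coefficients (bias last),
#'   mapped back to the original feature scale
#' @export
mheLogregFit <- function(model, Xlist, ylist, backend) {
  ctx <- backend@ctx
  m <- sum(vapply(Xlist, nrow, 1L))
  p0 <- ncol(Xlist[[1L]])
  if (model@standardize) {
    colSum <- Reduce(`+`, lapply(Xlist, colSums))
    colSq <- Reduce(`+`, lapply(Xlist, function(x) colSums(x^2)))
    mu <- colSum / m
    v <- pmax(colSq / m - mu^2, 0) * m / (m - 1)
    sdv <- sqrt(v); sdv[sdv < 1e-12] <- 1
    Xlist <- lapply(Xlist, function(x)
      sweep(sweep(x, 2, mu), 2, sdv, "/"))
  } else {
    mu <- rep(0, p0); sdv <- rep(1, p0)
  }
  Xt <- lapply(Xlist, appendBias)
  p <- p0 + 1L
  Xagg <- aggregateParts(partitionedMatrix(Xt, "horizontal"), backend)
  XTagg <- aggregateParts(partitionedMatrix(lapply(Xt, t), "vertical"),
                          backend)
  ys <- stackLocalSSM(lapply(ylist, function(y) matrix(as.numeric(y))),
                      ctx, c(m, 1L), "rows")
  w <- trivialZeros(p, 1L, ctx)
  for (e in seq_len(model@epochs)) {
    eta <- smcMatmul(Xagg@value, w, ctx)
    backend@log$multiplications <- backend@log$multiplications + 1L
    A <- evalSecure(model@sigmoidApprox, eta, ctx)
    g <- smcMatmul(XTagg@value, smcSub(A, ys), ctx)
    backend@log$multiplications <- backend@log$multiplications + 1L
    w <- smcSub(w, smcScalePublic(g, model@step / m))
  }
  smcMatmulPublic(standardizeMap(mu, sdv), w)
}

#' Distributed multiple imputation with final analysis
#'
#' The chained-equations loop over horizontally partitioned data: each
#' party filters its own complete rows locally (so per-party complete-row
#' counts leak, but masks stay local), imputation models are fitted with
#' the distributed fits, missing entries are predicted per party against
#' the protected weights and decoded only to the party that owns the rows,
#' and the final-analysis coefficients are pooled by Rubin's rules on
#' shares.  With one party and no missingness this reduces to the
#' centralised regression.
#'
#' @param Xlist,ylist,Mlist per-party local data, label and mask blocks
#' @param imputeSpec see [imputeSpecDefault()]
#' @param finalSpec the final-analysis [RegressionModel-class]
#' @param k number of imputations
#' @param backend a [ShareBackend-class]
#' @param columnKinds per-column `"continuous"`/`"binary"` (default: inferred
#'   from the pooled observed entries)
#' @param noiseVar imputation-noise variance (default 0.01)
#' @param retainImputed keep pooled completed datasets in the result
#' @return a [MICEResult-class] (mode `"mhe"`)
#' @export
mheMiceAnalyze <- function(Xlist, ylist, Mlist,
                           imputeSpec = imputeSpecDefault(),
                           finalSpec = regressionModel("linear"), k = 5L,
                           backend, columnKinds = NULL, noiseVar = 0.01,
                           retainImputed = TRUE) {
  ctx <- backend@ctx
  Xlist <- lapply(Xlist, as.matrix)
  Mlist <- lapply(Mlist, as.matrix)
  n <- ncol(Xlist[[1L]])
  pooled0 <- do.call(rbind, Xlist)
  Mpooled <- do.call(rbind, Mlist)
  if (is.null(columnKinds))
    columnKinds <- vapply(seq_len(n), function(j) {
      obs <- pooled0[Mpooled[, j] == 1, j]
      if (length(obs) && all(obs %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  Xlist <- mapply(function(x, mk) { x[mk == 0] <- 0; x }, Xlist, Mlist,
                  SIMPLIFY = FALSE)
  coefList <- vector("list", k)
  secureCoefs <- vector("list", k)
  imputedList <- vector("list", k)
  for (imp in seq_len(k)) {
    D <- Xlist
    M <- Mlist
    for (j in seq_len(n)) {
      missIdx <- lapply(M, function(mk) which(mk[, j] == 0))
      if (!sum(lengths(missIdx))) next
      comp <- lapply(M, function(mk) which(rowSums(mk == 0) == 0))
      if (!sum(lengths(comp)))
        stop("no fully observed rows available for the fit")
      kind <- columnKinds[j]
      model <- imputeModelFor(kind, imputeSpec)
      Xf <- mapply(function(d, cr) d[cr, -j, drop = FALSE], D, comp,
                   SIMPLIFY = FALSE)
      yf <- mapply(function(d, cr) d[cr, j], D, comp, SIMPLIFY = FALSE)
      ws <- if (kind == "binary") mheLogregFit(model, Xf, yf, backend)
            else mheLinregFit(model, Xf, yf, backend)
      # per-party local prediction against the protected weights
      for (i in seq_along(D)) {
        mi <- missIdx[[i]]
        if (!length(mi)) next
        Z <- (D[[i]] * M[[i]])[mi, -j, drop = FALSE]
        etaS <- smcMatmulPublic(appendBias(Z), ws, "left")
        backend@log$multiplications <- backend@log$multiplications + 1L
        eta <- as.numeric(reconstructSecret(etaS))
        backend@log$decryptions <- backend@log$decryptions + 1L
        if (kind == "continuous") {
          D[[i]][mi, j] <- eta + rnorm(length(mi), 0, sqrt(noiseVar))
        } else {
          D[[i]][mi, j] <- as.numeric(evalPlain(model@sigmoidApprox, eta) > 0.5)
        }
      }
      M <- lapply(M, function(mk) { mk[, j] <- 1; mk })
    }
    ws <- if (finalSpec@kind == "logistic")
      mheLogregFit(finalSpec, D, ylist, backend)
    else mheLinregFit(finalSpec, D, ylist, backend)
    secureCoefs[[imp]] <- ws
    coefList[[imp]] <- as.numeric(reconstructSecret(ws))
    imputedList[[imp]] <- do.call(rbind, D)
  }
  C <- do.call(rbind, coefList)
  pooled <- as.numeric(reconstructSecret(rubinPoolSecure(secureCoefs)))
  yPooled <- as.numeric(unlist(ylist))
  sig <- if (finalSpec@kind == "logistic" && finalSpec@sigmoid == "chebyshev")
    function(x) evalPlain(finalSpec@sigmoidApprox, x) else plogis
  within <- do.call(rbind, lapply(seq_len(k), function(i)
    withinVariance(finalSpec@kind, imputedList[[i]], yPooled, C[i, ], sig)))
  if (k >= 2L) {
    totalVar <- rubinVariance(C, within)
    pv <- 2 * pnorm(-abs(pooled) / sqrt(totalVar))
  } else {
    totalVar <- rep(NA_real_, ncol(C)); pv <- rep(NA_real_, ncol(C))
  }
  new("MICEResult", coefficients = C, pooled = pooled, within = within,
      totalVar = totalVar, pvalues = pv,
      imputed = if (retainImputed) imputedList else list(), mode = "mhe")
}
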