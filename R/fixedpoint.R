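# Fixed-point encoding, additive secret sharing and the dealer-assisted
# Beaver-multiplication protocol.

#' Create a fixed-point ring configuration
#'
#' @param totalBits ring width (64, 128 or 192); the modulus is
#'   `2^totalBits` (power-of-two ring, so truncation and the
#'   two's-complement embedding are plain shifts)
#' @param fracBits fractional bits
#' @param valueBits whole fixed-point value width
#' @param paddingBits statistical-security padding
#' @return a [FixedPointConfig-class]
#' @examples
#' cfg <- fixedPointConfig()
#' fpDecode(fpEncode(pi, cfg), cfg)
#' @export
fixedPointConfig <- function(totalBits = 192L, fracBits = 32L,
                             valueBits = 64L, paddingBits = 64L) {
  new("FixedPointConfig", totalBits = as.integer(totalBits),
      fracBits = as.integer(fracBits), valueBits = as.integer(valueBits),
      paddingBits = as.integer(paddingBits))
}

nlimbs <- function(cfg) cfg@totalBits %/% 64L

#' @describeIn fixedPointConfig base-2 logarithm of the ring modulus
#' @param cfg a [FixedPointConfig-class]
#' @export
ringModulusLog2 <- function(cfg) cfg@totalBits

setMethod("show", "FixedPointConfig", function(object) {
  cat(sprintf("FixedPointConfig: Z_2^%d, %d fractional / %d value / %d padding bits\n",
              object@totalBits, object@fracBits, object@valueBits,
              object@paddingBits))
})

#' Fixed-point encode / decode
#'
#' `fpEncode` maps reals to ring elements as `round(x * 2^fracBits)`
#' embedded in `[0, 2^totalBits)` with negatives as `modulus - |.|`;
#' `fpDecode` inverts it up to the quantisation `2^-fracBits` (elements
#' above `modulus/2` decode as negative).  Matrix shape is preserved via a
#' `dim` attribute on the opaque raw encoding.
#'
#' @param x numeric scalar, vector or matrix with
#'   `|x| < 2^(valueBits - fracBits - 1)`
#' @param cfg a [FixedPointConfig-class]
#' @return `fpEncode`: raw ring encoding; `fpDecode`: numeric
#' @export
fpEncode <- function(x, cfg = fixedPointConfig()) {
  e <- ring_encode(as.numeric(x), cfg@fracBits, cfg@valueBits, nlimbs(cfg))
  attr(e, "ringdim") <- if (is.matrix(x)) dim(x) else c(length(x), 1L)
  e
}

#' @rdname fpEncode
#' @param e raw ring encoding produced by `fpEncode`
#' @export
fpDecode <- function(e, cfg = fixedPointConfig()) {
  v <- ring_decode(e, cfg@fracBits, nlimbs(cfg))
  d <- attr(e, "ringdim")
  if (!is.null(d) && d[2] > 1L) dim(v) <- d
  v
}

# ---- dealer context ----------------------------------------------------

#' Create a trusted-dealer protocol context
#'
#' The dealer holds a seeded generator used for all correlated randomness
#' (shares and Beaver triples) and logs every issued triple.  It never
#' receives a data share.  Runs are fully reproducible from `seed`.
#'
#' @param seed integer seed for the dealer generator
#' @param partyCount number of computing parties (default 2, aided by the
#'   dealer)
#' @param config ring configuration
#' @return a [DealerContext-class]
#' @examples
#' ctx <- dealerContext(seed = 1)
#' s <- shareSecret(matrix(1:6 / 7, 2), ctx)
#' reconstructSecret(s)
#' @export
dealerContext <- function(seed, partyCount = 2L, config = fixedPointConfig()) {
  st <- new.env(parent = emptyenv())
  st$rng <- rng_create(as.numeric(seed))
  st$triplesIssued <- 0L
  st$triplesByShape <- list()
  st$messages <- 0L
  new("DealerContext", partyCount = as.integer(partyCount), config = config,
      seed = as.numeric(seed), state = st)
}

setMethod("show", "DealerContext", function(object) {
  cat(sprintf("DealerContext: %d computing parties + dealer, seed %s\n",
              object@partyCount, format(object@seed)))
  cat(sprintf("  ring: Z_2^%d (frac %d); triples issued: %d\n",
              object@config@totalBits, object@config@fracBits,
              object@state$triplesIssued))
})

#' @describeIn dealerContext number of Beaver triples issued so far
#' @param ctx a [DealerContext-class]
#' @export
triplesIssued <- function(ctx) ctx@state$triplesIssued

logTriple <- function(ctx, shape) {
  ctx@state$triplesIssued <- ctx@state$triplesIssued + 1L
  key <- paste(shape, collapse = "x")
  cur <- ctx@state$triplesByShape[[key]]
  ctx@state$triplesByShape[[key]] <- if (is.null(cur)) 1L else cur + 1L
  invisible(ctx)
}

# ---- sharing / reconstruction ------------------------------------------

newSSM <- function(shares, dim, cfg) {
  new("SecretSharedMatrix", shares = shares, dim = as.integer(dim),
      config = cfg)
}

#' Secret-share a matrix
#'
#' Encodes `x` in fixed point and splits it additively: the first `P - 1`
#' shares are uniform over the ring, the last is the secret minus their sum
#' (mod `2^totalBits`).
#'
#' @param x numeric matrix or vector (vectors become one-column matrices)
#' @param ctx a [DealerContext-class]
#' @return a [SecretSharedMatrix-class]
#' @export
shareSecret <- function(x, ctx) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  cfg <- ctx@config
  L <- nlimbs(cfg)
  enc <- ring_encode(as.numeric(x), cfg@fracBits, cfg@valueBits, L)
  P <- ctx@partyCount
  shares <- vector("list", P)
  acc <- raw(length(enc))
  for (p in seq_len(P - 1L)) {
    r <- ring_random(ctx@state$rng, length(x), L)
    shares[[p]] <- r
    acc <- ring_add(acc, r, L)
  }
  shares[[P]] <- ring_sub(enc, acc, L)
  newSSM(shares, dim(x), cfg)
}

#' Share a public matrix
#'
#' Embeds a publicly known matrix into the shared domain: one designated
#' party contributes the encoding and a fresh zero-sharing re-randomises
#' the shares.  Re-randomisation matters for correctness, not just
#' hygiene: local probabilistic truncation assumes uniformly distributed
#' shares, so un-randomised trivial shares of negative values would
#' truncate incorrectly downstream.
#'
#' @inheritParams shareSecret
#' @param party index of the contributing party (default 1)
#' @param rerandomize mask the trivial sharing with a fresh zero-sharing
#'   (default TRUE; disable only for values never fed to truncation)
#' @export
sharePublic <- function(x, ctx, party = 1L, rerandomize = TRUE) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  cfg <- ctx@config
  L <- nlimbs(cfg)
  enc <- ring_encode(as.numeric(x), cfg@fracBits, cfg@valueBits, L)
  P <- ctx@partyCount
  shares <- replicate(P, raw(length(enc)), simplify = FALSE)
  shares[[party]] <- enc
  if (rerandomize) {
    acc <- raw(length(enc))
    for (p in seq_len(P - 1L)) {
      r <- ring_random(ctx@state$rng, length(x), L)
      shares[[p]] <- ring_add(shares[[p]], r, L)
      acc <- ring_add(acc, r, L)
    }
    shares[[P]] <- ring_sub(shares[[P]], acc, L)
  }
  newSSM(shares, dim(x), cfg)
}

#' Reconstruct a secret-shared matrix
#'
#' Element-wise modular sum of all party shares — exact at ring level; the
#' only loss relative to the original real matrix is the fixed-point
#' quantisation.
#'
#' @param s a [SecretSharedMatrix-class]
#' @param decode decode the ring sum to numeric (default); `FALSE` returns
#'   the raw ring encoding
#' @return numeric matrix (or raw encoding)
#' @export
reconstructSecret <- function(s, decode = TRUE) {
  L <- nlimbs(s@config)
  acc <- s@shares[[1L]]
  for (p in seq_along(s@shares)[-1L]) acc <- ring_add(acc, s@shares[[p]], L)
  if (!decode) {
    attr(acc, "ringdim") <- s@dim
    return(acc)
  }
  v <- ring_decode(acc, s@config@fracBits, L)
  matrix(v, s@dim[1L], s@dim[2L])
}

setMethod("show", "SecretSharedMatrix", function(object) {
  cat(sprintf("SecretSharedMatrix: %d x %d over Z_2^%d, %d party shares\n",
              object@dim[1L], object@dim[2L], object@config@totalBits,
              length(object@shares)))
})

setMethod("dim", "SecretSharedMatrix", function(x) x@dim)

#' @describeIn shareSecret list of per-party raw shares
#' @param s a [SecretSharedMatrix-class]
#' @export
partyShares <- function(s) s@shares

# ---- local (communication-free) arithmetic -----------------------------

checkConformable <- function(s, t) {
  if (!all(s@dim == t@dim) || length(s@shares) != length(t@shares))
    stop("shape mismatch between secret-shared operands")
}

#' Local secure arithmetic on shares
#'
#' Addition, subtraction and scaling by a public constant are computed
#' locally per party with no communication.  Public-constant addition is
#' applied by a single designated party; scaling by a public real multiplies
#' every share by the encoded constant and locally truncates `fracBits` bits
#' to restore the scale.
#'
#' @param s,t conformable [SecretSharedMatrix-class] operands
#' @return a [SecretSharedMatrix-class]
#' @export
smcAdd <- function(s, t) {
  checkConformable(s, t)
  L <- nlimbs(s@config)
  newSSM(mapply(ring_add, s@shares, t@shares,
                MoreArgs = list(nlimbs = L), SIMPLIFY = FALSE),
         s@dim, s@config)
}

#' @rdname smcAdd
#' @export
smcSub <- function(s, t) {
  checkConformable(s, t)
  L <- nlimbs(s@config)
  newSSM(mapply(ring_sub, s@shares, t@shares,
                MoreArgs = list(nlimbs = L), SIMPLIFY = FALSE),
         s@dim, s@config)
}

#' @rdname smcAdd
#' @param x public numeric constant (scalar or conformable matrix)
#' @export
smcAddPublic <- function(s, x) {
  cfg <- s@config
  L <- nlimbs(cfg)
  xm <- if (length(x) == 1L) matrix(x, s@dim[1L], s@dim[2L]) else x
  enc <- ring_encode(as.numeric(xm), cfg@fracBits, cfg@valueBits, L)
  shares <- s@shares
  shares[[1L]] <- ring_add(shares[[1L]], enc, L)
  newSSM(shares, s@dim, cfg)
}

#' @rdname smcAdd
#' @param a public real scalar
#' @export
smcScalePublic <- function(s, a) {
  cfg <- s@config
  L <- nlimbs(cfg)
  # exact power-of-two scaling is loss-free: no truncation needed when the
  # scaled encoding is an integer shift
  enc <- ring_encode(a, cfg@fracBits, cfg@valueBits, L)
  P <- length(s@shares)
  shares <- lapply(s@shares, ring_mul_scalar, s = enc, nlimbs = L)
  shares <- lapply(seq_len(P), function(p)
    ring_trunc_share(shares[[p]], cfg@fracBits, p == P, L))
  newSSM(shares, s@dim, cfg)
}

#' @rdname smcAdd
#' @param v public numeric vector, one scale factor per element (recycled
#'   down columns like ordinary R arithmetic)
#' @export
smcScaleElementwise <- function(s, v) {
  cfg <- s@config
  L <- nlimbs(cfg)
  vm <- matrix(v, s@dim[1L], s@dim[2L])
  enc <- ring_encode(as.numeric(vm), cfg@fracBits, cfg@valueBits, L)
  P <- length(s@shares)
  shares <- lapply(s@shares, ring_mul, b = enc, nlimbs = L)
  shares <- lapply(seq_len(P), function(p)
    ring_trunc_share(shares[[p]], cfg@fracBits, p == P, L))
  newSSM(shares, s@dim, cfg)
}

#' Probabilistic truncation of shares
#'
#' Locally divides the shared value by `2^bits`: all parties logically
#' shift their shares; the last party uses the negate-shift-negate rule.
#' The decoded value is exact up to one unit in the last place per party,
#' with a wrap-around failure probability of about `2^-paddingBits`.
#'
#' @param s a [SecretSharedMatrix-class]
#' @param bits number of bits to divide by (at most `fracBits`)
#' @export
smcTruncate <- function(s, bits) {
  cfg <- s@config
  if (bits > cfg@fracBits) stop("bits must not exceed fracBits")
  L <- nlimbs(cfg)
  P <- length(s@shares)
  shares <- lapply(seq_len(P), function(p)
    ring_trunc_share(s@shares[[p]], as.integer(bits), p == P, L))
  newSSM(shares, s@dim, cfg)
}

# ---- Beaver triples and secure multiplication --------------------------

#' Issue Beaver triples from the dealer
#'
#' Batch-generates `count` triples of shares of random `a` (`dimA`), `b`
#' (`dimB`) and `c = a %*% b` (or `a * b` element-wise), exact in ring
#' arithmetic.  Each triple is single-use; issuance is logged by shape in
#' the dealer context (so triples can be precomputed and cached ahead of a
#' protocol run).
#'
#' @param ctx a [DealerContext-class]
#' @param dimA,dimB dimensions of the triple factors
#' @param count number of triples
#' @param elementwise element-wise instead of matrix product
#' @return list of [BeaverTriple-class]
#' @export
dealerIssueTriples <- function(ctx, dimA, dimB = dimA, count = 1L,
                               elementwise = FALSE) {
  cfg <- ctx@config
  L <- nlimbs(cfg)
  if (elementwise) dimB <- dimA
  if (!elementwise && dimA[2L] != dimB[1L])
    stop("inner dimensions of the triple factors must agree")
  out <- vector("list", count)
  for (i in seq_len(count)) {
    tr <- dealer_triple(ctx@state$rng, dimA[1L], dimA[2L],
                        if (elementwise) dimA[2L] else dimB[2L],
                        elementwise, L, ctx@partyCount)
    aSh <- lapply(tr, `[[`, 1L)
    bSh <- lapply(tr, `[[`, 2L)
    cSh <- lapply(tr, `[[`, 3L)
    dimC <- if (elementwise) dimA else c(dimA[1L], dimB[2L])
    st <- new.env(parent = emptyenv()); st$used <- FALSE
    out[[i]] <- new("BeaverTriple",
                    a = newSSM(aSh, dimA, cfg), b = newSSM(bSh, dimB, cfg),
                    c = newSSM(cSh, dimC, cfg),
                    kind = if (elementwise) "elementwise" else "matmul",
                    state = st)
    logTriple(ctx, c(dimA, dimB))
  }
  out
}

setMethod("show", "BeaverTriple", function(object) {
  cat(sprintf("BeaverTriple (%s): a %dx%d, b %dx%d%s\n", object@kind,
              object@a@dim[1L], object@a@dim[2L], object@b@dim[1L],
              object@b@dim[2L], if (object@state$used) " [consumed]" else ""))
})

#' Secure multiplication with an explicit Beaver triple
#'
#' Runs the Beaver protocol: the parties open `d = s - a` and `e = t - b`,
#' combine `c + d b + a e + d e` locally, and truncate `fracBits` bits so
#' the fixed-point scale is preserved.  The triple is consumed and cannot
#' be reused.
#'
#' @param s,t [SecretSharedMatrix-class] operands
#' @param triple a fresh [BeaverTriple-class] of matching shape
#' @return a [SecretSharedMatrix-class] holding the (matrix or
#'   element-wise) product
#' @export
smcMul <- function(s, t, triple) {
  if (triple@state$used) stop("Beaver triple has already been consumed")
  cfg <- s@config
  L <- nlimbs(cfg)
  elementwise <- triple@kind == "elementwise"
  if (!all(s@dim == triple@a@dim) || !all(t@dim == triple@b@dim))
    stop("triple shape does not match the operands")
  if (elementwise && !all(s@dim == t@dim))
    stop("element-wise product needs conformable operands")
  if (!elementwise && s@dim[2L] != t@dim[1L])
    stop("inner dimensions must agree")
  triple@state$used <- TRUE
  P <- length(s@shares)
  d <- reconstructSecret(smcSub(s, triple@a), decode = FALSE)
  e <- reconstructSecret(smcSub(t, triple@b), decode = FALSE)
  m <- s@dim[1L]; k <- s@dim[2L]; n <- t@dim[2L]
  de <- if (elementwise) ring_mul(d, e, L) else ring_matmul(d, e, m, k, n, L)
  shares <- vector("list", P)
  for (p in seq_len(P)) {
    db <- if (elementwise) ring_mul(d, triple@b@shares[[p]], L)
          else ring_matmul(d, triple@b@shares[[p]], m, k, n, L)
    ae <- if (elementwise) ring_mul(triple@a@shares[[p]], e, L)
          else ring_matmul(triple@a@shares[[p]], e, m, k, n, L)
    z <- ring_add(triple@c@shares[[p]], ring_add(db, ae, L), L)
    if (p == 1L) z <- ring_add(z, de, L)
    shares[[p]] <- ring_trunc_share(z, cfg@fracBits, p == P, L)
  }
  newSSM(shares, if (elementwise) s@dim else c(m, n), cfg)
}

#' Secure products with dealer-supplied triples (fused fast path)
#'
#' Convenience wrappers that let the dealer issue the triple and run the
#' whole Beaver protocol in one step.  The message and round structure is
#' identical to [smcMul()] with [dealerIssueTriples()]; the fused kernel
#' only avoids interpreter overhead inside gradient-descent loops.
#'
#' @param s,t [SecretSharedMatrix-class] operands
#' @param ctx a [DealerContext-class]
#' @return a [SecretSharedMatrix-class]
#' @export
smcMatmul <- function(s, t, ctx) {
  if (s@dim[2L] != t@dim[1L]) stop("inner dimensions must agree")
  cfg <- ctx@config
  L <- nlimbs(cfg)
  sh <- smc_mul_fused(ctx@state$rng, s@shares, t@shares,
                      s@dim[1L], s@dim[2L], t@dim[2L], FALSE, L,
                      cfg@fracBits)
  logTriple(ctx, c(s@dim, t@dim))
  newSSM(sh, c(s@dim[1L], t@dim[2L]), cfg)
}

#' @rdname smcMatmul
#' @export
smcMulElem <- function(s, t, ctx) {
  checkConformable(s, t)
  cfg <- ctx@config
  L <- nlimbs(cfg)
  sh <- smc_mul_fused(ctx@state$rng, s@shares, t@shares,
                      s@dim[1L], s@dim[2L], t@dim[2L], TRUE, L, cfg@fracBits)
  logTriple(ctx, c(s@dim, s@dim))
  newSSM(sh, s@dim, cfg)
}

#' Multiply a public matrix with a shared matrix (local)
#'
#' Multiplication by a publicly known matrix needs no Beaver triple: each
#' party multiplies its share by the encoded public operand and locally
#' truncates.  Used for bias columns, standardisation maps and the
#' partitioned dataflow where local plaintext blocks meet protected values.
#'
#' @param a public numeric matrix
#' @param s a [SecretSharedMatrix-class]
#' @param side `"left"` for `a %*% s`, `"right"` for `s %*% a`
#' @export
smcMatmulPublic <- function(a, s, side = c("left", "right")) {
  side <- match.arg(side)
  cfg <- s@config
  L <- nlimbs(cfg)
  if (!is.matrix(a)) a <- matrix(a, nrow = if (side == "left") length(a) else 1L)
  enc <- ring_encode(as.numeric(a), cfg@fracBits, cfg@valueBits, L)
  P <- length(s@shares)
  if (side == "left") {
    if (ncol(a) != s@dim[1L]) stop("inner dimensions must agree")
    m <- nrow(a); k <- ncol(a); n <- s@dim[2L]
    shares <- lapply(s@shares, function(sh)
      ring_matmul(enc, sh, m, k, n, L))
    outDim <- c(m, n)
  } else {
    if (s@dim[2L] != nrow(a)) stop("inner dimensions must agree")
    m <- s@dim[1L]; k <- s@dim[2L]; n <- ncol(a)
    shares <- lapply(s@shares, function(sh)
      ring_matmul(sh, enc, m, k, n, L))
    outDim <- c(m, n)
  }
  shares <- lapply(seq_len(P), function(p)
    ring_trunc_share(shares[[p]], cfg@fracBits, p == P, L))
  newSSM(shares, outDim, cfg)
}

# ---- structural helpers (public mask-driven indexing) ------------------

ssmIndex <- function(s, rows, cols) {
  m <- s@dim[1L]
  idx <- outer(rows - 1L, (cols - 1L) * m, `+`)
  as.integer(idx)
}

#' Structural operations on shared matrices
#'
#' Row/column subsetting, transposition, column assignment and binding of
#' shared matrices are pure share reorderings driven by public indices
#' (e.g. the public missingness mask); they involve no communication and no
#' arithmetic.
#'
#' @param s a [SecretSharedMatrix-class]
#' @param rows,cols integer index vectors
#' @export
ssmSubset <- function(s, rows = seq_len(s@dim[1L]),
                      cols = seq_len(s@dim[2L])) {
  L <- nlimbs(s@config)
  idx <- ssmIndex(s, as.integer(rows), as.integer(cols))
  shares <- lapply(s@shares, ring_subset, idx = idx, nlimbs = L)
  newSSM(shares, c(length(rows), length(cols)), s@config)
}

#' @rdname ssmSubset
#' @export
ssmTranspose <- function(s) {
  L <- nlimbs(s@config)
  m <- s@dim[1L]; n <- s@dim[2L]
  idx <- as.integer(t(matrix(seq_len(m * n) - 1L, m, n)))
  shares <- lapply(s@shares, ring_subset, idx = idx, nlimbs = L)
  newSSM(shares, c(n, m), s@config)
}

#' @rdname ssmSubset
#' @param j column index to overwrite
#' @param v a one-column [SecretSharedMatrix-class] of matching length
#' @export
ssmSetColumn <- function(s, j, v) {
  if (v@dim[1L] != s@dim[1L]) stop("column length mismatch")
  L <- nlimbs(s@config)
  idx <- as.integer((j - 1L) * s@dim[1L] + seq_len(s@dim[1L]) - 1L)
  shares <- mapply(function(sh, vh) ring_assign(sh, idx, vh, L),
                   s@shares, v@shares, SIMPLIFY = FALSE)
  newSSM(shares, s@dim, s@config)
}

#' @rdname ssmSubset
#' @param rowIdx rows to overwrite within column `j`
#' @export
ssmSetEntries <- function(s, rowIdx, j, v) {
  L <- nlimbs(s@config)
  idx <- as.integer((j - 1L) * s@dim[1L] + as.integer(rowIdx) - 1L)
  shares <- mapply(function(sh, vh) ring_assign(sh, idx, vh, L),
                   s@shares, v@shares, SIMPLIFY = FALSE)
  newSSM(shares, s@dim, s@config)
}

#' @rdname ssmSubset
#' @param t a second shared matrix with the same row count
#' @export
ssmCbind <- function(s, t) {
  if (s@dim[1L] != t@dim[1L]) stop("row counts must agree")
  L <- nlimbs(s@config)
  shares <- mapply(function(a, b) c(a, b), s@shares, t@shares,
                   SIMPLIFY = FALSE)
  newSSM(shares, c(s@dim[1L], s@dim[2L] + t@dim[2L]), s@config)
}

#' @rdname ssmSubset
#' @param ctx a [DealerContext-class] (supplies the ring configuration)
#' @export
ssmAppendOnes <- function(s, ctx) {
  ones <- sharePublic(matrix(1, s@dim[1L], 1L), ctx)
  ssmCbind(s, ones)
}

#' @rdname ssmSubset
#' @param dim target dimensions for broadcasting a 1x1 shared scalar
#' @export
ssmBroadcast <- function(s, dim) {
  if (prod(s@dim) != 1L) stop("only 1x1 shared scalars can be broadcast")
  L <- nlimbs(s@config)
  idx <- integer(prod(dim))
  shares <- lapply(s@shares, ring_subset, idx = idx, nlimbs = L)
  newSSM(shares, as.integer(dim), s@config)
}
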