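# Chebyshev interpolation of the logistic sigmoid (and natural log), with
# plaintext and secret-shared polynomial evaluation.  The secure logistic
# fits evaluate the sigmoid as a polynomial because exact comparison-based
# nonlinearities are unavailable on shares.

targetFunction <- function(target) {
  switch(target,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         log = function(x) log(x),
         stop("unknown target '", target, "'"))
}

#' Fit a Chebyshev polynomial approximation
#'
#' Interpolates `target` through the `degree + 1` Chebyshev nodes of the
#' interval.  Deterministic.  The default secure sigmoid uses degree 13 on
#' `[-8, 8]`: the smallest degree of this family whose uniform error is
#' comfortably below 1e-2 (about 3e-3; degree 9 only reaches 1.3e-2),
#' still at a modest secure multiplication depth.  The natural-log
#' approximant (same degree on `[0.01, 1]`) exists for loss reporting
#' only.
#'
#' @param target `"sigmoid"`, `"log"`, or a function (then labelled
#'   `"custom"`)
#' @param interval approximation interval `(lo, hi)`; `log` requires
#'   `lo > 0`
#' @param degree polynomial degree
#' @return a [ChebyshevApprox-class]
#' @examples
#' ap <- fitChebyshev("sigmoid", c(-8, 8), 9)
#' max(abs(evalPlain(ap, seq(-8, 8, 0.01)) - plogis(seq(-8, 8, 0.01))))
#' @export
fitChebyshev <- function(target = "sigmoid",
                         interval = if (identical(target, "log"))
                           c(0.01, 1) else c(-8, 8),
                         degree = 13L) {
  if (is.function(target)) {
    f <- target
    label <- "custom"
  } else {
    label <- target
    if (label == "log" && interval[1] <= 0)
      stop("log requires a strictly positive interval")
    f <- targetFunction(label)
  }
  if (!(interval[1] < interval[2])) stop("interval must satisfy lo < hi")
  N <- degree + 1L
  theta <- pi * (seq_len(N) - 0.5) / N
  u <- cos(theta)
  mid <- mean(interval); half <- diff(interval) / 2
  fv <- f(mid + half * u)
  if (any(!is.finite(fv))) stop("target not finite on the interval")
  coefCheb <- vapply(0:degree, function(j)
    (2 / N) * sum(fv * cos(j * theta)), numeric(1))
  coefCheb[1] <- coefCheb[1] / 2
  # monomial coefficients in u via the T_{k+1} = 2u T_k - T_{k-1} recurrence
  Tprev <- c(1, numeric(degree))
  Tcur <- c(0, 1, numeric(max(0, degree - 1L)))
  mono <- coefCheb[1] * Tprev
  if (degree >= 1L) mono <- mono + coefCheb[2] * Tcur
  if (degree >= 2L) for (k in 2:degree) {
    Tnext <- 2 * c(0, Tcur[-N]) - Tprev
    mono <- mono + coefCheb[k + 1L] * Tnext
    Tprev <- Tcur; Tcur <- Tnext
  }
  new("ChebyshevApprox", target = label, interval = as.numeric(interval),
      degree = as.integer(degree), coefCheb = coefCheb, coefMono = mono)
}

setMethod("show", "ChebyshevApprox", function(object) {
  cat(sprintf("ChebyshevApprox: %s, degree %d on [%g, %g]\n", object@target,
              object@degree, object@interval[1], object@interval[2]))
})

#' Evaluate a Chebyshev approximant in plaintext
#'
#' Inputs outside the approximation interval are clipped to the endpoints;
#' the polynomial is then evaluated by Horner's rule in the normalised
#' variable.
#'
#' @param approx a [ChebyshevApprox-class]
#' @param x numeric vector
#' @return numeric vector of approximant values
#' @export
evalPlain <- function(approx, x) {
  lo <- approx@interval[1]; hi <- approx@interval[2]
  x <- pmin(pmax(x, lo), hi)
  u <- (2 * x - lo - hi) / (hi - lo)
  cf <- approx@coefMono
  acc <- rep(cf[length(cf)], length(u))
  if (length(cf) > 1L) for (j in (length(cf) - 1L):1L) acc <- acc * u + cf[j]
  acc
}

#' Evaluate a Chebyshev approximant on secret shares
#'
#' Applies the public affine map to the normalised variable, builds the
#' required powers of the shared input by square-and-multiply Beaver
#' products, and combines them with the encoded monomial coefficients in a
#' single local linear combination (one truncation).  Unlike the plaintext
#' evaluator, the input cannot be clipped without revealing it: the
#' polynomial is unbounded outside the interval and callers must
#' range-control the input (the logistic fits standardise features for this
#' reason).
#'
#' @param approx a [ChebyshevApprox-class]
#' @param s a [SecretSharedMatrix-class]
#' @param ctx a [DealerContext-class] supplying Beaver triples
#' @return a [SecretSharedMatrix-class] of approximant values
#' @export
evalSecure <- function(approx, s, ctx) {
  cfg <- ctx@config
  L <- nlimbs(cfg)
  lo <- approx@interval[1]; hi <- approx@interval[2]
  u <- smcScalePublic(smcAddPublic(s, -(lo + hi) / 2), 2 / (hi - lo))
  deg <- approx@degree
  cf <- approx@coefMono
  powers <- vector("list", max(deg, 1L))
  powers[[1L]] <- u
  if (deg >= 2L) for (j in 2:deg) {
    powers[[j]] <- if (j %% 2L == 0L)
      smcMulElem(powers[[j %/% 2L]], powers[[j %/% 2L]], ctx)
    else
      smcMulElem(powers[[j - 1L]], u, ctx)
  }
  # local linear combination at double scale, then one truncation
  P <- length(s@shares)
  acc <- replicate(P, raw(length(u@shares[[1L]])), simplify = FALSE)
  for (j in seq_len(deg)) {
    if (cf[j + 1L] == 0) next
    enc <- ring_encode(cf[j + 1L], cfg@fracBits, cfg@valueBits, L)
    for (p in seq_len(P))
      acc[[p]] <- ring_add(acc[[p]],
                           ring_mul_scalar(powers[[j]]@shares[[p]], enc, L),
                           L)
  }
  # constant term at double scale: encode(c0) * encode(1)
  c0 <- ring_mul_scalar(ring_encode(rep(cf[1L], prod(s@dim)), cfg@fracBits,
                                    cfg@valueBits, L),
                        ring_encode(1, cfg@fracBits, cfg@valueBits, L), L)
  acc[[1L]] <- ring_add(acc[[1L]], c0, L)
  shares <- lapply(seq_len(P), function(p)
    ring_trunc_share(acc[[p]], cfg@fracBits, p == P, L))
  newSSM(shares, s@dim, cfg)
}
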