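# Shared fixtures: a dealer context per test file keeps runs reproducible.

newCtx <- function(seed = 42, parties = 2L) dealerContext(seed, parties)

# random SPD matrix with eigenvalues in [lo, hi]
randomSPD <- function(p, lo = 0.3, hi = 3) {
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  Q %*% diag(runif(p, lo, hi), p) %*% t(Q)
}

# small synthetic linear problem with known weights
linearProblem <- function(m, p, wTrue = NULL, noise = 0.05) {
  X <- matrix(rnorm(m * p), m, p)
  if (is.null(wTrue)) wTrue <- c(rnorm(p), 0.5)
  y <- as.numeric(appendBias(X) %*% wTrue) + rnorm(m, 0, noise)
  list(X = X, y = y, w = wTrue)
}
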