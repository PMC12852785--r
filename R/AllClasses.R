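# S4 classes for the secret-sharing engine and the imputation machinery.

#' Fixed-point ring configuration
#'
#' Describes the integer ring and fixed-point layout used by the
#' secret-sharing engine: values are encoded as `round(x * 2^fracBits)`
#' embedded two's-complement-style in `Z_{2^totalBits}`.  The default layout
#' (192 total bits, 32 fractional, 64 for a whole fixed-point value and 64
#' bits of statistical-security padding) balances truncation noise against
#' the failure probability of probabilistic truncation.
#'
#' @slot totalBits ring width in bits; must be a multiple of 64, at most 192
#' @slot fracBits bits reserved for the fractional part
#' @slot valueBits width of a whole fixed-point value (integer + fraction)
#' @slot paddingBits statistical-security margin
#' @export
setClass("FixedPointConfig",
  representation(totalBits = "integer", fracBits = "integer",
                 valueBits = "integer", paddingBits = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@totalBits %% 64L != 0L || object@totalBits < 64L ||
        object@totalBits > 192L)
      msg <- c(msg, "totalBits must be 64, 128 or 192")
    if (object@fracBits >= object@valueBits)
      msg <- c(msg, "fracBits must be smaller than valueBits")
    if (object@valueBits + object@paddingBits > object@totalBits)
      msg <- c(msg, "valueBits + paddingBits must not exceed totalBits")
    if (length(msg)) msg else TRUE
  })

#' Additively secret-shared fixed-point matrix
#'
#' One raw vector of ring elements per computing party; the element-wise sum
#' of the party shares modulo `2^totalBits` reconstructs the encoded secret.
#' Ring elements are stored little-endian, 8 bytes per 64-bit limb,
#' column-major.
#'
#' @slot shares list of raw vectors, one per party
#' @slot dim integer matrix dimensions (rows, cols)
#' @slot config the [FixedPointConfig-class] in force
#' @export
setClass("SecretSharedMatrix",
  representation(shares = "list", dim = "integer",
                 config = "FixedPointConfig"),
  validity = function(object) {
    L <- object@config@totalBits / 64L
    want <- 8L * L * prod(object@dim)
    ok <- vapply(object@shares, function(s) is.raw(s) && length(s) == want,
                 logical(1))
    if (length(object@shares) < 1L) return("at least one party share needed")
    if (!all(ok)) return("all party shares must have identical shape")
    TRUE
  })

#' Beaver multiplication triple
#'
#' Dealer-issued shares of random `a`, `b` and `c = a * b` (matrix or
#' element-wise product, exact in ring arithmetic).  Triples are single-use;
#' [smcMul()] marks them consumed and refuses reuse.
#'
#' @slot a,b,c [SecretSharedMatrix-class] shares of the triple
#' @slot kind `"matmul"` or `"elementwise"`
#' @slot state environment holding the `used` flag
#' @export
setClass("BeaverTriple",
  representation(a = "SecretSharedMatrix", b = "SecretSharedMatrix",
                 c = "SecretSharedMatrix", kind = "character",
                 state = "environment"))

#' Trusted dealer / protocol context
#'
#' Holds the party count, ring configuration and the dealer's seeded
#' generator, plus an issued-triple log.  The dealer distributes correlated
#' randomness only and never receives a data share.  A protocol run is fully
#' reproducible from the context seed.
#'
#' @slot partyCount number of computing parties (default 2)
#' @slot config [FixedPointConfig-class]
#' @slot seed integer seed for the dealer generator
#' @slot state environment: xoshiro RNG pointer and operation counters
#' @export
setClass("DealerContext",
  representation(partyCount = "integer", config = "FixedPointConfig",
                 seed = "numeric", state = "environment"),
  validity = function(object) {
    if (object@partyCount < 2L) "at least 2 computing parties required"
    else TRUE
  })

#' Chebyshev polynomial approximation of a scalar function
#'
#' Interpolation through Chebyshev nodes of the given degree on a fixed
#' interval.  Coefficients are kept both in the Chebyshev basis (used by the
#' clipped plaintext Clenshaw evaluator) and as monomial coefficients in the
#' normalised variable `u = (2x - lo - hi) / (hi - lo)` (used by the secure
#' evaluator, which cannot clip).
#'
#' @slot target function identifier (`"sigmoid"`, `"log"`, or `"custom"`)
#' @slot interval approximation interval `(lo, hi)`
#' @slot degree polynomial degree
#' @slot coefCheb Chebyshev-basis coefficients (length `degree + 1`)
#' @slot coefMono monomial coefficients in `u` (length `degree + 1`)
#' @export
setClass("ChebyshevApprox",
  representation(target = "character", interval = "numeric",
                 degree = "integer", coefCheb = "numeric",
                 coefMono = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@interval) != 2L ||
        !(object@interval[1] < object@interval[2]))
      msg <- c(msg, "interval must be non-degenerate (lo < hi)")
    if (object@degree != length(object@coefCheb) - 1L)
      msg <- c(msg, "degree must equal length(coefficients) - 1")
    if (length(msg)) msg else TRUE
  })

#' Regression model specification
#'
#' Shared contract of the plaintext and secure linear/logistic fits.  The
#' closed-form normal-equations path is taken when the bias-augmented design
#' has fewer than 4 columns; otherwise full-batch (or mini-batch) gradient
#' descent on the count-normalised Gramian is run for `epochs` sweeps of
#' step `step`.
#'
#' @slot kind `"linear"` or `"logistic"`
#' @slot weights fitted coefficient vector, bias last (empty until fitted)
#' @slot epochs gradient-descent epochs
#' @slot step gradient-descent step size
#' @slot batchSize mini-batch size, `NA` for full batch
#' @slot sigmoid `"chebyshev"` (plaintext mirror of the secure path) or
#'   `"exact"` for the logistic response
#' @slot sigmoidApprox the [ChebyshevApprox-class] used when
#'   `sigmoid == "chebyshev"` and by every secure logistic fit
#' @slot standardize centre/scale features before a logistic fit (required
#'   so the linear predictor stays inside the sigmoid approximation
#'   interval); weights are mapped back to the original scale afterwards
#' @export
setClass("RegressionModel",
  representation(kind = "character", weights = "numeric", epochs = "integer",
                 step = "numeric", batchSize = "integer", sigmoid = "character",
                 sigmoidApprox = "ANY", standardize = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("linear", "logistic"))
      msg <- c(msg, "kind must be 'linear' or 'logistic'")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@step <= 0) msg <- c(msg, "step must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Imputation task
#'
#' The inputs of a chained-equations run: the (zero-filled) data matrix, the
#' public zero-one missingness mask (0 = missing), the outcome vector, the
#' per-column variable kind and the imputation-noise variance.  The outcome
#' is never used as an imputation predictor.
#'
#' @slot data numeric matrix, missing entries zero-filled
#' @slot mask zero-one matrix of the same shape (0 = missing)
#' @slot y outcome vector (length `nrow(data)`)
#' @slot columnKinds `"continuous"` or `"binary"` per column
#' @slot noiseVar variance of the Gaussian imputation noise (default 0.01)
#' @export
setClass("ImputationTask",
  representation(data = "matrix", mask = "matrix", y = "numeric",
                 columnKinds = "character", noiseVar = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@mask) == dim(object@data)))
      msg <- c(msg, "mask shape must equal data shape")
    if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask must be zero-one")
    if (length(object@y) != nrow(object@data))
      msg <- c(msg, "outcome length must equal row count")
    if (length(object@columnKinds) != ncol(object@data))
      msg <- c(msg, "one column kind per column required")
    if (any(object@data[object@mask == 0] != 0))
      msg <- c(msg, "masked entries of the input data must be zero-filled")
    for (j in seq_len(ncol(object@data)))
      if (object@columnKinds[j] == "binary" &&
          !all(object@data[object@mask[, j] == 1, j] %in% c(0, 1))) {
        msg <- c(msg, "binary columns may contain only 0/1 at observed entries")
        break
      }
    if (length(msg)) msg else TRUE
  })

#' Multiple-imputation analysis result
#'
#' Per-imputation final-analysis coefficient vectors, their Rubin's-rules
#' pooling (arithmetic mean; on shares, without decryption, in the secure
#' modes), the within/between/total variance decomposition and the Wald
#' p-values derived from it.
#'
#' @slot coefficients k x p matrix of per-imputation coefficients (bias last)
#' @slot pooled pooled coefficient vector
#' @slot within k x p within-imputation coefficient variances
#' @slot totalVar Rubin total variance per coefficient (NA when k < 2)
#' @slot pvalues two-sided normal-approximation Wald p-values
#' @slot imputed list of completed data matrices (optional retention)
#' @slot mode execution mode that produced the result
#' @export
setClass("MICEResult",
  representation(coefficients = "matrix", pooled = "numeric",
                 within = "matrix", totalVar = "numeric", pvalues = "numeric",
                 imputed = "list", mode = "character"),
  validity = function(object) {
    p <- colMeans(object@coefficients)
    if (max(abs(p - object@pooled)) > 1e-8 * (1 + max(abs(p))))
      "pooled coefficients must be the mean of the per-imputation rows"
    else TRUE
  })

#' Partitioned matrix for the distributed dataflow
#'
#' A matrix distributed between parties: `horizontal` / `vertical` blocks
#' concatenate (by rows / columns) to the global matrix, `additive` blocks
#' sum to it, and an `aggregated` value is held by every party only in
#' backend-protected form.
#'
#' @slot partitioning one of `"horizontal"`, `"vertical"`, `"additive"`,
#'   `"aggregated"`
#' @slot blocks per-party plaintext matrices (or protected values for
#'   additive results of protected products)
#' @slot value the backend-protected replicated value (aggregated only)
#' @slot globalDim dimensions of the global matrix
#' @export
setClass("PartitionedMatrix",
  representation(partitioning = "character", blocks = "list", value = "ANY",
                 globalDim = "integer"),
  validity = function(object) {
    if (!object@partitioning %in%
        c("horizontal", "vertical", "additive", "aggregated"))
      return("unknown partitioning")
    if (object@partitioning == "aggregated") {
      if (!is(object@value, "SecretSharedMatrix"))
        return("aggregated matrices hold a backend-protected value")
      return(TRUE)
    }
    if (length(object@blocks) < 1L) return("at least one block required")
    TRUE
  })

#' Secure vector backend (contract)
#'
#' The protection layer behind aggregated values in the distributed
#' dataflow.  The default backend is the additive-secret-sharing engine; the
#' slot count and scale of a lattice-based (CKKS-style) backend are recorded
#' as contract metadata, and every aggregate / multiply / decrypt call is
#' counted in an operation log so an alternative backend can drop in and be
#' audited.
#'
#' @slot ctx the [DealerContext-class] the engine runs under
#' @slot slotCount SIMD slot count metadata (default 8192)
#' @slot scaleLog2 default scale metadata (default 34)
#' @slot log environment of operation counters
#' @export
setClass("ShareBackend",
  representation(ctx = "DealerContext", slotCount = "integer",
                 scaleLog2 = "integer", log = "environment"))

#' Simulation scenario specification
#'
#' The six synthetic designs used to evaluate the method: ten i.i.d.
#' standard-normal predictors with one incomplete (continuous or binary)
#' column missing completely at random at 30% (scenarios 1-2), and
#' two-variable designs with `X2 ~ U(-3,3)` and `X1` either
#' `N(0.2 - 0.5 X2, 1)` or `Bernoulli(sigmoid(0.2 - 0.5 X2))`, missing at
#' random through `X2` at 50% (scenarios 3-4) or not at random through `X1`
#' itself at 55% / 60% (scenarios 5-6).  The outcome is
#' `Y = 1 + sum_i X_i + eps` with per-row
#' `eps ~ N(0, |1 + sum_i X_i| / 100)`, computed on the complete data before
#' masking.
#'
#' @slot scenarioId 1-6
#' @slot nIndividuals sample size
#' @slot nVariables number of predictors (10 for scenarios 1-2, 2 for 3-6)
#' @slot incompleteKind `"continuous"` or `"binary"`
#' @slot missingRate target missingness fraction of the incomplete column
#' @slot mechanism `"MCAR"`, `"MAR-on-X2"` or `"MNAR-self"`
#' @slot theta true regression weights, intercept first (all ones)
#' @slot seed integer seed
#' @export
setClass("ScenarioSpec",
  representation(scenarioId = "integer", nIndividuals = "integer",
                 nVariables = "integer", incompleteKind = "character",
                 missingRate = "numeric", mechanism = "character",
                 theta = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@scenarioId %in% 1:6) msg <- c(msg, "scenarioId must be 1-6")
    if (object@missingRate <= 0 || object@missingRate >= 1)
      msg <- c(msg, "missingRate must lie in (0, 1)")
    ok <- switch(object@mechanism,
                 "MCAR" = object@scenarioId %in% 1:2,
                 "MAR-on-X2" = object@scenarioId %in% 3:4,
                 "MNAR-self" = object@scenarioId %in% 5:6, FALSE)
    if (!ok) msg <- c(msg, "mechanism inconsistent with scenarioId")
    if (length(msg)) msg else TRUE
  })

#' Simulated dataset
#'
#' Ground-truth complete matrix, the missingness mask, the outcome vector
#' (computed on complete data before masking) and the truth record.
#'
#' @slot X complete ground-truth matrix
#' @slot mask zero-one missingness mask (0 = missing)
#' @slot y outcome vector
#' @slot theta true weights, intercept first
#' @slot spec the generating [ScenarioSpec-class]
#' @export
setClass("SimulatedDataset",
  representation(X = "matrix", mask = "matrix", y = "numeric",
                 theta = "numeric", spec = "ScenarioSpec"))
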