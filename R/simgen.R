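# Generators for the six simulation scenarios: predictor distributions,
# missingness mechanisms (MCAR / MAR / MNAR with calibrated logistic
# selection) and the outcome model, under full seed control.

scenarioDefaults <- list(
  list(nVariables = 10L, incompleteKind = "continuous", missingRate = 0.30,
       mechanism = "MCAR"),
  list(nVariables = 10L, incompleteKind = "binary", missingRate = 0.30,
       mechanism = "MCAR"),
  list(nVariables = 2L, incompleteKind = "continuous", missingRate = 0.50,
       mechanism = "MAR-on-X2"),
  list(nVariables = 2L, incompleteKind = "binary", missingRate = 0.50,
       mechanism = "MAR-on-X2"),
  list(nVariables = 2L, incompleteKind = "continuous", missingRate = 0.55,
       mechanism = "MNAR-self"),
  list(nVariables = 2L, incompleteKind = "binary", missingRate = 0.60,
       mechanism = "MNAR-self"))

#' Specify a simulation scenario
#'
#' Fills the design parameters of scenarios 1-6 (see
#' [ScenarioSpec-class]); only the sample size and seed usually need
#' choosing.  True regression weights are all ones (intercept included).
#'
#' @param scenarioId 1-6
#' @param nIndividuals sample size (500 or 5000 in the reference studies)
#' @param seed integer seed
#' @param missingRate override the scenario's target missingness rate
#' @return a [ScenarioSpec-class]
#' @export
scenarioSpec <- function(scenarioId, nIndividuals = 500L, seed = 1L,
                         missingRate = NULL) {
  scenarioId <- as.integer(scenarioId)
  if (!scenarioId %in% 1:6) stop("scenarioId must be 1-6")
  d <- scenarioDefaults[[scenarioId]]
  if (is.null(missingRate)) missingRate <- d$missingRate
  new("ScenarioSpec", scenarioId = scenarioId,
      nIndividuals = as.integer(nIndividuals), nVariables = d$nVariables,
      incompleteKind = d$incompleteKind, missingRate = missingRate,
      mechanism = d$mechanism, theta = rep(1, d$nVariables + 1L),
      seed = as.integer(seed))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec %d: n=%d, %d variables, %s incomplete, %s at %.0f%%\n",
              object@scenarioId, object@nIndividuals, object@nVariables,
              object@incompleteKind, object@mechanism,
              100 * object@missingRate))
})

# calibrate the intercept of a logistic selection model so the realised
# expected missingness rate matches the target on this sample
calibrateIntercept <- function(driver, rate) {
  f <- function(a) mean(plogis(a + driver)) - rate
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("missingness-rate calibration failed: target rate unreachable")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a simulation scenario dataset
#'
#' Draws the predictors, the outcome `Y = 1 + sum_i X_i + eps` with
#' per-row `eps ~ N(0, |1 + sum_i X_i| / 100)` (computed on complete data
#' before masking), and the missingness mask of the first column:
#' uniformly at random for scenarios 1-2, logistic in `X2` (slope 1,
#' intercept calibrated to the target rate) for scenarios 3-4, and
#' logistic in `X1` itself for scenarios 5-6.  Identical seeds give
#' bit-identical datasets.
#'
#' @param spec a [ScenarioSpec-class]
#' @return a [SimulatedDataset-class]
#' @examples
#' ds <- genScenario(scenarioSpec(1, 500, seed = 7))
#' mean(ds@mask[, 1] == 0)  # about 0.30
#' @export
genScenario <- function(spec) {
  set.seed(spec@seed)
  n <- spec@nIndividuals
  if (spec@scenarioId %in% 1:2) {
    X <- matrix(rnorm(n * spec@nVariables), n, spec@nVariables)
    if (spec@incompleteKind == "binary") X[, 1] <- rbinom(n, 1, 0.5)
  } else {
    X2 <- runif(n, -3, 3)
    X1 <- if (spec@incompleteKind == "continuous")
      rnorm(n, 0.2 - 0.5 * X2, 1)
    else
      rbinom(n, 1, plogis(0.2 - 0.5 * X2))
    X <- cbind(X1, X2)
  }
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  lin <- 1 + rowSums(X)
  y <- lin + rnorm(n, 0, sqrt(abs(lin) / 100))
  mask <- matrix(1, n, ncol(X))
  pMiss <- switch(spec@mechanism,
    "MCAR" = rep(spec@missingRate, n),
    "MAR-on-X2" = plogis(calibrateIntercept(X[, 2], spec@missingRate) + X[, 2]),
    "MNAR-self" = plogis(calibrateIntercept(X[, 1], spec@missingRate) + X[, 1]))
  mask[, 1] <- 1 - rbinom(n, 1, pMiss)
  if (all(mask[, 1] == 0))
    stop("degenerate draw: the incomplete column is entirely missing")
  new("SimulatedDataset", X = X, mask = mask, y = y,
      theta = spec@theta, spec = spec)
}

#' Generate a scenario with a binary outcome
#'
#' Same predictors and mask as [genScenario()], with the outcome replaced
#' by `Bernoulli(sigmoid(Y - median(Y)))`, giving prevalence about 0.5 for
#' exercising the logistic final-analysis path.
#'
#' @inheritParams genScenario
#' @export
genBinaryOutcome <- function(spec) {
  ds <- genScenario(spec)
  lin <- ds@y
  ds@y <- rbinom(length(lin), 1, plogis(lin - median(lin)))
  ds
}

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: scenario %d, %d x %d, %d masked entries\n",
              object@spec@scenarioId, nrow(object@X), ncol(object@X),
              sum(object@mask == 0)))
})

#' Convert a simulated dataset to an imputation task
#'
#' Zero-fills the masked entries; the ground-truth values stay in the
#' dataset object for evaluation only.
#'
#' @param ds a [SimulatedDataset-class]
#' @param noiseVar imputation-noise variance
#' @return an [ImputationTask-class]
#' @export
asImputationTask <- function(ds, noiseVar = 0.01) {
  kinds <- rep("continuous", ncol(ds@X))
  if (ds@spec@incompleteKind == "binary") kinds[1] <- "binary"
  imputationTask(ds@X * ds@mask, ds@mask, ds@y, columnKinds = kinds,
                 noiseVar = noiseVar)
}
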