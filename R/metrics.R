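# Benchmark statistics: coefficient bias/SD/rMSE over repeated runs,
# imputation and final-analysis error, rank AUC, and the discrepancy count
# between a base and a target analysis.

#' Coefficient bias, standard deviation and root mean squared error
#'
#' Over `R` repeated runs with estimated coefficient vectors `Theta_r`:
#' `bias = ||mean_r Theta_r - theta||_2`,
#' `sd = sqrt(mean_r ||Theta_r - mean Theta||_2^2)` and
#' `rmse = sqrt(mean_r ||Theta_r - theta||_2^2)`, so that
#' `rmse^2 = bias^2 + sd^2` holds exactly.
#'
#' @param thetaRuns R x p matrix of per-run coefficient vectors
#' @param thetaTrue true coefficient vector
#' @return named vector `c(bias, sd, rmse)`
#' @export
thetaStats <- function(thetaRuns, thetaTrue) {
  if (!is.matrix(thetaRuns)) thetaRuns <- matrix(thetaRuns, nrow = 1L)
  if (ncol(thetaRuns) != length(thetaTrue))
    stop("coefficient length mismatch")
  m <- colMeans(thetaRuns)
  bias <- sqrt(sum((m - thetaTrue)^2))
  sdv <- sqrt(mean(rowSums(sweep(thetaRuns, 2, m)^2)))
  rmse <- sqrt(mean(rowSums(sweep(thetaRuns, 2, thetaTrue)^2)))
  c(bias = bias, sd = sdv, rmse = rmse)
}

#' Imputation error over originally missing entries
#'
#' Continuous columns: mean and standard deviation of the absolute
#' difference between imputed and ground-truth values, restricted to the
#' masked (originally missing) entries.  Binary columns: accuracy of the
#' thresholded imputations and rank AUC of the imputation probabilities on
#' the masked entries.
#'
#' @param imputed completed data matrix
#' @param truth ground-truth complete matrix
#' @param mask zero-one mask (0 = originally missing)
#' @param kind `"continuous"` or `"binary"`
#' @param probs imputation probabilities (binary; defaults to the imputed
#'   0/1 values, which yields a degenerate but well-defined AUC)
#' @return named vector `c(mean, sd)` or `c(accuracy, auc)`
#' @export
imputationError <- function(imputed, truth, mask,
                            kind = c("continuous", "binary"),
                            probs = NULL) {
  kind <- match.arg(kind)
  sel <- mask == 0
  if (!any(sel)) stop("mask marks no missing entries")
  if (kind == "continuous") {
    d <- abs(imputed[sel] - truth[sel])
    c(mean = mean(d), sd = sd(d))
  } else {
    truthv <- truth[sel]
    predv <- imputed[sel]
    if (is.null(probs)) probs <- predv else probs <- probs[sel]
    c(accuracy = mean(predv == truthv),
      auc = if (length(unique(truthv)) < 2L) NA_real_
            else aucRank(probs, truthv))
  }
}

#' Final-analysis prediction error
#'
#' Linear: mean and standard deviation of `|X w - y|` on the full
#' (imputed) dataset.  Logistic: accuracy of the thresholded response and
#' rank AUC of the probabilities.
#'
#' @param weights pooled coefficient vector (bias last)
#' @param X imputed feature matrix (no bias column)
#' @param y ground-truth outcome
#' @param kind `"linear"` or `"logistic"`
#' @return named vector `c(mean, sd)` or `c(accuracy, auc)`
#' @export
predictionError <- function(weights, X, y, kind = c("linear", "logistic")) {
  kind <- match.arg(kind)
  eta <- as.numeric(appendBias(X) %*% weights)
  if (kind == "linear") {
    d <- abs(eta - y)
    c(mean = mean(d), sd = sd(d))
  } else {
    pr <- plogis(eta)
    c(accuracy = mean(as.numeric(pr > 0.5) == y), auc = aucRank(pr, y))
  }
}

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a random positive outranks a random negative; ties
#' contribute one half, so all-tied scores give exactly 0.5.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels, both classes present
#' @export
aucRank <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discrepancy count between two pooled analyses
#'
#' A variable is a discrepancy when it is significant in the base analysis
#' (p <= `alpha`) and either loses significance in the target (p > `alpha`)
#' or its coefficient sign flips between the two.  The definition is
#' directional: swapping base and target can change the count.
#'
#' @param base,target [MICEResult-class] objects, or lists with elements
#'   `pooled` and `pvalues`
#' @param alpha significance level (default 0.05)
#' @param dropBias exclude the bias term from the count (default TRUE; the
#'   intercept is not a study variable)
#' @return integer discrepancy count
#' @export
discrepancyCount <- function(base, target, alpha = 0.05, dropBias = TRUE) {
  get <- function(x) {
    if (is(x, "MICEResult")) list(coef = x@pooled, p = x@pvalues)
    else list(coef = x$pooled, p = x$pvalues)
  }
  b <- get(base); t <- get(target)
  if (length(b$coef) != length(t$coef))
    stop("analyses expose different variable sets")
  idx <- seq_along(b$coef)
  if (dropBias) idx <- idx[-length(idx)]
  disc <- b$p[idx] <= alpha &
    (t$p[idx] > alpha | sign(b$coef[idx]) != sign(t$coef[idx]))
  sum(disc, na.rm = TRUE)
}
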