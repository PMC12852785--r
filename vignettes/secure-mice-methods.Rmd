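---
title: "Methods: secure multiple imputation by chained equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secure multiple imputation by chained equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secureMICE)
```

This vignette is the package's own account of its statistical and
cryptographic design: the models, the parameters that matter, the
numerical choices, what the synthetic data emulate, and what the secure
protocol does and does not protect.

## The procedure

secureMICE runs the classical impute-then-analyse workflow in three
interchangeable execution modes. Given an individuals-by-variables matrix
$X$ with a public zero-one missingness mask $M$ (0 = missing) and an
outcome $y$:

1. **Chained imputation.** Columns are visited in ascending index order.
   For an incomplete column $j$, the column-appropriate regression (linear
   for continuous, logistic for binary) of column $j$ on all other columns
   is fitted on the rows currently fully complete; missing entries are
   predicted from the mask-zeroed matrix $(X \cdot M)_{:,k\neq j}$, with
   $N(0,\sigma^2_{imp})$ noise added to continuous predictions and binary
   probabilities thresholded at $1/2$; the predictions are written back
   and $M_{:,j} \leftarrow 1$, so later columns reuse the imputed values.
   One sweep is the default (configurable). The outcome never enters an
   imputation model.
2. **Final analysis.** $y$ is regressed on the completed covariates; this
   is repeated for $k$ independent imputations (fresh noise draws are the
   only stochastic difference when fits are deterministic).
3. **Rubin pooling.** The pooled coefficients are the arithmetic mean of
   the $k$ coefficient vectors — averaged on shares, without decryption,
   in the secure modes. For inference the total variance
   $T = \bar W + (1 + 1/k)B$ combines the mean within-imputation
   covariance diagonal $\bar W$ with the between-imputation variance $B$;
   Wald $z = \hat\theta/\sqrt{T}$ with a plain normal reference gives the
   p-values used by the discrepancy statistic. No degrees-of-freedom
   small-sample correction is applied; with the simulation sample sizes
   used here the correction is immaterial, and the discrepancy statistic
   only compares p-values *between* analyses computed the same way.

**Assumptions.** Imputation by regression on observed covariates is
consistent under data missing (completely) at random; the
missing-not-at-random designs are included to measure degradation, not
because the model handles them. The mask is public by protocol design:
the *positions* of missing values leak, their values do not.

## Regression engines

Both fits share one contract across plaintext and secure modes, with
weights initialised at zero for reproducibility:

* **Linear.** With fewer than 4 design columns (features + bias) the
  closed form $w = C^{-1}R$ on the count-normalised Gramian
  $C = \tilde X^\top \tilde X/m$, $R = \tilde X^\top y/m$. Otherwise
  full-batch gradient descent $w \leftarrow w + (R - Cw)\eta$ for $e$
  epochs (a mini-batch option recomputes per-batch Gramians). Defaults
  $\eta = 0.05$, $e = 2000$: with the count-normalised Gramian the
  contraction per epoch is $1 - \eta\lambda$ for each Gramian eigenvalue
  $\lambda$ (order 1 on standardised data), so 2000 epochs reach the
  closed form to well below $10^{-3}$ while $\eta$ stays safely inside
  the stability region $\eta < 2/\lambda_{max}$. A divergence detector
  aborts when the weight norm exceeds $10^6$.
* **Logistic.** Mean-gradient descent
  $w \leftarrow w - \tilde X^\top(\sigma(\tilde X w) - y)\,\eta/m$ with
  defaults $\eta = 1$, $e = 500$ (the logistic mean Hessian is bounded by
  $\lambda_{max}/4$, so $\eta = 1$ is stable on standardised features).
  Features are standardised by revealed aggregate moments — column sums
  and sums of squares only — so the linear predictor stays inside the
  sigmoid approximation interval; the returned weights are mapped back to
  the original scale by a public affine transform.

The plaintext logistic reference evaluates the *same* Chebyshev sigmoid
polynomial as the secure path by default, making the plaintext pipeline
the exact plaintext mirror of the secure algorithm; an exact-sigmoid
option exists for off-the-shelf-style fits.

## Fixed-point secret sharing

Reals are encoded as $\mathrm{round}(x\,2^{f})$ with $f = 32$ fractional
bits in the ring $\mathbb{Z}_{2^{192}}$ (64 bits for a whole value, 64
bits of statistical-security padding; negatives via the two's-complement
embedding). A power-of-two modulus makes truncation and sign handling
plain bit-shifts; the ring, fraction and padding widths are configurable
through `fixedPointConfig()`.

* **Sharing.** $P-1$ shares uniform over the ring, the last the secret
  minus their sum. Two computing parties aided by a trusted dealer is the
  default and the setting in which every protocol guarantee below holds.
* **Multiplication.** Dealer-issued Beaver triples at matrix granularity
  (one triple per matrix product, so triples can be precomputed and the
  round count stays low); triples are single-use and logged. The fused
  gradient-descent kernels run the identical protocol with the dealer
  inlined, purely to avoid interpreter overhead.
* **Truncation.** Rescaling after multiplication uses local probabilistic
  truncation: all parties logically shift their shares, the last party
  negates-shifts-negates. This is exact up to one unit in the last place
  with wrap failure probability about $2^{-64}$ **only for two computing
  parties** — with more parties the share-sum wrap corrupts the result by
  multiples of $2^{192-f}$, which is why truncation-bearing protocol runs
  are pinned at $P = 2$. Re-randomisation of publicly contributed shares
  (`sharePublic`) is part of the same correctness argument: truncation
  assumes uniformly distributed shares.
* **Small-matrix inversion.** Shared Gramians of dimension $\le 3$ are
  inverted by computing the adjugate with element-wise Beaver products,
  the determinant by cofactor expansion, and $1/\det$ by 20
  Newton–Raphson iterations $y \leftarrow y(2 - dy)$ from the public
  initial guess $1/(t/p)^p$, where the trace $t$ is revealed rounded up
  to $10^{-2}$. By AM–GM, $(t/p)^p \ge \det$ for symmetric positive
  definite input, so the iteration starts inside its convergence region;
  20 doublings push the relative error below $10^{-4}$ whenever
  $\det/(t/p)^p \gtrsim 10^{-5}$, i.e. for any reasonably conditioned
  normalised Gramian. The trace reveal is the only leakage of this step
  beyond the output.
* **Binary imputation.** Secure comparison is out of scope, so the
  threshold at $1/2$ is applied by the coordinating party on decoded
  probabilities, which are then re-shared. This deliberately leaks the
  imputed binary values (not the observed data) and is documented as a
  protocol choice; a garbled-circuit comparison could remove it.

## Sigmoid approximation

The secure sigmoid is the Chebyshev interpolant of degree 13 on
$[-8, 8]$: uniform error about $3\times 10^{-3}$, strictly monotone on
$[-5, 5]$ (beyond that the true sigmoid slope falls below the
approximation ripple), values within $[-0.02, 1.02]$ on the interval.
Degree 9 — a natural first choice — misses a $10^{-2}$ uniform-error
budget (measured $1.3\times 10^{-2}$), which is why 13 is the default;
the degree is a parameter. The secure evaluator maps the input to the
normalised variable by a public affine transform, builds powers by
square-and-multiply Beaver products, and combines them with the encoded
monomial coefficients in a single local linear combination (one
truncation). It cannot clip: inputs outside the interval follow the
polynomial, which is unbounded, so callers must range-control the input —
the reason the logistic fits standardise features. The plaintext
evaluator clips to the interval endpoints. A natural-log approximant on
$[0.01, 1]$ ships for loss reporting only.

## Partitioned dataflow

For horizontally distributed data the package mirrors a multiparty-HE
deployment without re-implementing lattice cryptography (explicitly out
of scope): local blocks stay plaintext at their holding party, local
Gramians $\tilde X_i^\top \tilde X_i$ are computed with zero
communication (the product of vertically and horizontally partitioned
matrices is additively partitioned), and only aggregated quantities are
protected by the `ShareBackend`, whose slot count (8192) and scale
($2^{34}$) are carried as contract metadata and whose operation log
records every aggregation, protected product and decryption. In the
logistic loop the design matrix and its transpose are aggregated exactly
once each before the epochs — aggregating data rather than weights keeps
the per-epoch cost at two protected products — and the log makes that
auditable. The closed-form path aggregates the partitioned Gramian before
inversion. Per-party local filtering of complete rows means per-party
complete-row counts leak; masks themselves stay local in this mode.
Imputed values are decoded only to the party owning the rows.

## Synthetic scenarios

`genScenario()` implements six designs: (1) ten i.i.d. $N(0,1)$
predictors, column 1 missing completely at random at 30%; (2) as (1)
with column 1 $\sim$ Bernoulli(0.5); (3)/(5) $X_2 \sim U(-3,3)$,
$X_1 \sim N(0.2 - 0.5X_2, 1)$; (4)/(6) $X_1 \sim$
Bernoulli$(\sigma(0.2 - 0.5X_2))$ — the published parameterisation of
the binary designs is self-referential and exceeds 1, so the mean
structure of the continuous designs is mirrored. Missingness is logistic
with slope 1 in $X_2$ (missing at random, scenarios 3–4, 50%) or in
$X_1$ itself (not at random, scenarios 5–6, 55%/60%), with the intercept
calibrated by root finding on the realised sample. The outcome is
$Y = 1 + \sum_i X_i + \epsilon$ with per-row
$\epsilon \sim N(0, |1 + \sum_i X_i|/100)$, computed before masking; the
absolute value is the only reading of the stated variance that is valid
row-wise. The ten predictors of scenarios 1–2 are mutually independent
as literally specified.

What the generator does *not* emulate: correlation among the complete
covariates, covariate shift between sites, multiple simultaneously
incomplete columns, measurement error, or real-cohort marginals. Passing
tests therefore certify protocol fidelity and the statistical behaviour
of the method under these stylised conditions, not performance on real
clinical data.

## Evaluation statistics

Over repeated runs with estimates $\Theta_r$:
bias $\|\mathbb{E}\Theta - \tilde\Theta\|_2$, spread
$\sqrt{\mathbb{E}\|\Theta - \mathbb{E}\Theta\|_2^2}$ and rMSE
$\sqrt{\mathbb{E}\|\Theta - \tilde\Theta\|_2^2}$, which satisfy
$\mathrm{rMSE}^2 = \mathrm{bias}^2 + \mathrm{sd}^2$ exactly. Imputation
error is the mean/sd of $|{\rm imputed} - {\rm truth}|$ restricted to the
originally missing entries (accuracy and rank AUC for binary columns) —
the masked-entries convention is the one consistent with the half-normal
limit $\mathbb{E}|N(0,1)| = \sqrt{2/\pi} \approx 0.798$,
$\mathrm{sd} = \sqrt{1 - 2/\pi} \approx 0.603$ when the imputed column is
independent of its predictors. Final-analysis error is $|\tilde X c - y|$
on the completed data. The discrepancy count between a base and a target
analysis is the number of variables with base $p \le 0.05$ whose target
$p > 0.05$ or whose coefficient sign flips; the definition is
directional by construction.

## Parameters at a glance

| parameter | default | meaning / rationale |
|---|---|---|
| `totalBits/fracBits/valueBits/paddingBits` | 192/32/64/64 | ring width and fixed-point layout; padding sets the truncation failure probability |
| computing parties | 2 (+ dealer) | the setting in which local truncation is exact |
| `k` | 5 | number of multiple imputations |
| imputation noise variance | 0.01 | $N(0, 0.01)$ draws on continuous predictions |
| linear GD | $\eta=0.05$, $e=2000$ | converges to the closed form within $10^{-3}$ |
| logistic GD | $\eta=1$, $e=500$ | stable mean-gradient step on standardised features |
| closed-form threshold | design columns $< 4$ | small-feature normal-equations path |
| sigmoid approximant | degree 13 on $[-8,8]$ | uniform error $\approx 3\times10^{-3}$ |
| Newton iterations / trace precision | 20 / $10^{-2}$ | reciprocal of the shared determinant |
| backend metadata | 8192 slots, scale $2^{34}$ | recorded contract of a lattice backend |

## Numerical and degenerate-input behaviour

Singular plaintext Gramians raise an error; the secure inverse cannot
detect singularity without decryption (it would silently amplify noise),
so callers owe it a positive-definite, reasonably conditioned input —
near-collinear designs are the known hazard. Columns that are entirely
missing, and masks leaving no fully complete row, raise errors before any
fitting. Ties in binary thresholding at exactly $1/2$ go to 0; rank-AUC
ties contribute one half. All stochastic draws flow from explicit seeds:
scenario generation and imputation noise use R's generator, ring
randomness uses an independent xoshiro generator per dealer context, so
plaintext and secure runs consume identical noise streams and are
comparable run-for-run.

One behavioural property worth knowing: with near-collinear predictors,
stochastic imputation noise of the same order as a column's conditional
residual attenuates that column's final-analysis coefficient, because the
imputation model never sees the outcome. The package's parameter-recovery
test therefore exercises the noise-free (conditional-mean) limit; with
the default noise the attenuation is real and expected, not a bug.

## Problem sizes used in the tests

The test suite runs the full cross-mode agreement check on all six
scenarios at $n = 500$ with $k = 5$; the reference-table reproduction at
$n = 5000$ with 100 plaintext repetitions and 5 repetitions per secure
mode; the half-normal limit at $n = 10^5$; crypto-layer property checks
on small random matrices; and the partitioned-fit equivalence for 1–4
data-holding parties. These sizes were chosen so each property is
exercised at a scale where its expected value is sharp.

## Known limitations

Honest-but-curious security only — no MACs, no malicious security, no
constant-time guarantees; parties are simulated in-process (the message
contract is explicit, a socket transport would not change results). The
mask is public (SMC mode) or local-with-leaky-row-counts (partitioned
mode). Binary thresholding decodes at the coordinator. MNAR data are
handled by the same MAR machinery and inherit its bias. Real lattice
encryption, differential privacy and trusted-execution variants are out
of scope by design.
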