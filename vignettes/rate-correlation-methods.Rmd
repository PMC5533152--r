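---
title: "Correlated trait evolution from rate matrices on tree samples: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated trait evolution from rate matrices on tree samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecorr)
```

# The question and the model

`ratecorr` asks whether two continuous traits — in the motivating application,
log10 sternal keel length and log10 ilium length in birds — evolved in a
correlated way, after the shared effect of body size is removed. The engine is
the multivariate Brownian-motion (BM) model on a phylogeny: a trait vector
diffuses along each branch, gaining a mean-zero Gaussian increment whose
covariance is the branch duration times the **evolutionary rate matrix** $R$.
The diagonal of $R$ holds the per-trait rates ($\sigma^2$, in squared trait
units per Ma); the off-diagonal holds the evolutionary covariance. The derived
**evolutionary correlation**

$$ r = \frac{R_{12}}{\sqrt{R_{11} R_{22}}} $$

is the quantity of scientific interest: it measures whether the *changes* in
the two traits along the tree covary, which is not the same thing as the
static correlation across species.

Under BM the tip trait matrix $X$ ($n$ tips $\times$ $p=2$ traits) is
matrix-normal with among-tip covariance $C$ — the phylogenetic
variance–covariance matrix, $C_{ij}$ being the root-to-MRCA path length of
tips $i, j$ — and among-trait covariance $R$:

$$
\log L(a, R) = -\tfrac12\Big[ np\log 2\pi + p\log|C| + n\log|R|
  + \mathrm{tr}\big(R^{-1} (X - 1a^\top)^\top C^{-1} (X - 1a^\top)\big)\Big],
$$

with root state $a$. The ML estimates are closed-form GLS moments:
$\hat a = (1^\top C^{-1} 1)^{-1} 1^\top C^{-1} X$ and
$\hat R = (X - 1\hat a^\top)^\top C^{-1} (X - 1\hat a^\top)/n$.
`fit_rate_matrix()` implements exactly this; tests verify both against a
brute-force multivariate-normal density with the full Kronecker covariance
$R \otimes C$ and against an independent general-purpose optimizer, and
cross-check against `phytools::evol.vcv`.

Two scaling conventions were open and are fixed as follows: $\hat R$ uses ML
($1/n$) rather than REML ($1/(n-1)$) scaling, consistent with the likelihood
above (a REML variant is a one-line change in `fit_rate_matrix`); the
parameter count for AICc is $k = 2 + 3 = 5$ (two root states, three distinct
rate-matrix entries), with the number of tips as the AICc sample size. Because
$k$ and $n$ are constant across the trees of a sample, Akaike weights are
insensitive to both conventions — only AICc *differences* across trees enter.

# Phylogenetic size-correction

Keel and ilium length both scale with body size, so the raw interspecific
correlation is dominated by allometry. Each log10 trait is therefore regressed
on a log10 size variable (body mass for extant datasets; femur length for
fossil datasets, where mass is unavailable) by **generalized least squares
under the BM covariance** $C$, and the residuals are the size-corrected traits
passed to the rate-matrix fit. The GLS residuals satisfy
$1^\top C^{-1} e = x^\top C^{-1} e = 0$; tests assert this to $10^{-8}$ and
check the estimator against the textbook normal-equations oracle and
`phytools::phyl.resid`. The residual model is pure BM — no Pagel's lambda
optimization — because the residual covariance the rate-matrix step assumes is
also pure BM; mixing signal-strength models between the two stages would make
the ensemble incoherent.

The two traits are corrected by *independent univariate* GLS fits (not a
common-slope bivariate model): size-correction is a per-trait preprocessing
contract, and the downstream fit re-estimates the full bivariate covariance of
whatever the residuals are.

Per-specimen measurements are averaged on the millimetre scale *before*
log-transformation (`average_specimens()`), so a species is represented by its
mean individual rather than its geometric mean.

# Tree samples and the ensemble

A single point estimate of $r$ on a single tree ignores two things: dating
uncertainty and topological uncertainty. The pipeline therefore fits the rate
matrix on *every* tree of a calibration sample and combines the per-tree
estimates:

1. Akaike weights from the per-tree AICc,
   $w_i \propto \exp(-\Delta_i/2)$, computed with min-subtraction so any
   finite AICc values are overflow-safe. Trees on which the BM model fits the
   data better are believed more.
2. Fisher transformation $z = \operatorname{atanh}(r)$ before averaging —
   correlations are bounded and skewed, so averaging on the $z$ scale and
   back-transforming ($\bar r = \tanh(\sum_i w_i z_i)$) is the
   variance-stabilized path. Equal-weight averaging of $r = \{0.6, 0.8\}$
   gives $\tanh((\operatorname{atanh} 0.6 + \operatorname{atanh} 0.8)/2)
   = 5/7 \approx 0.714$, not the arithmetic $0.7$ — the transform is
   consequential, which is why it is applied before, not after, weighting.
3. A 95% interval. The default is the **weighted empirical 2.5/97.5
   percentile** of the per-tree $r$ distribution (inclusive cumulative-weight
   convention: quantile $q$ is the smallest $r$ whose cumulative weight
   reaches $q$), which is the across-tree uncertainty a 1,000-tree design
   targets. The alternative `ci_method = "fisher-se"` returns
   $\tanh(\bar z \pm 1.96\,\mathrm{SE})$ with SE from the weighted $z$
   variance. How the original analyses computed their intervals is not
   documented, so the method label is stored in every result; the interval —
   not the point estimate — is the main reproducibility caveat.

Degenerate edge case: if every per-tree $r$ is identical (including the
collinear-trait case $r = 1$), the ensemble returns that value with a
zero-width interval, bypassing the transform (which is undefined at
$|r| = 1$). Elsewhere $|r| \ge 1$ is an error; clamping to $1 - 10^{-12}$
exists in `fisher_z()` but only as an explicit opt-in.

Per-fit sampling intervals use the classical Fisher approximation,
$z \pm 1.96/\sqrt{n-3}$ (`confint()` on a fit). After whitening by the
Cholesky factor of $C$, the centered cross-product matrix is Wishart with
$n-1$ degrees of freedom *regardless of tree shape*, so the iid-derived
approximation carries over with the tip count as $n$; simulation tests
confirm 90–99% empirical coverage at $n = 200$.

# Time-scaling fossil cladograms

Fossil trees arrive as a cladogram plus per-tip stratigraphic age ranges
(min/max, Ma before present). Calibration is stochastic and a-posteriori:

- **Tip ages** are drawn uniformly within each range, independently per tip
  and per draw.
- **"Basic" dating** sets each internal node's age to the oldest age among
  its descendant tips, making branch lengths parent age minus child age.
  This creates zero-length branches wherever a node ties its oldest child.
- **"Equal" redistribution** first extends the root back by
  `root_extension` Ma, then removes every zero-length branch by sliding its
  child node back in time, taking the needed duration from the nearest
  ancestral branch of positive length and sharing it *equally* among that
  donor and the whole contiguous chain of zero-length branches below it —
  each branch involved ends with the same positive length. Tip ages are never
  touched; tests assert their conservation to $10^{-9}$ and strict positivity
  of all output branches across randomized cladograms.

Where a donor's chain forks (several zero-branch paths below one donor),
chains are resolved one at a time toward the lexicographically smallest tip
first, with node ages updated between chains — an arbitrary but deterministic
order that makes outputs bit-stable.

`root_extension` is the one knob of this stage with no documented value in the
motivating analyses; it defaults to 1 Ma, is surfaced in the API and recorded
in outputs. Repeating draw–date–redistribute `n_draws` times (with per-draw
seeds derived from a master seed by draw index) yields the calibration sample
consumed by the ensemble, so the reported correlation carries the dating
uncertainty.

# The synthetic-data generator

Every input the pipeline consumes can be generated with the statistical
structure the analysis assumes, so the full chain is testable without any
external files:

- **Trees**: Yule (pure-birth), via `ape::rphylo`. The analysis conditions on
  trees, so tree-shape realism beyond "ultrametric with time units" is
  irrelevant to correctness.
- **Traits**: branchwise forward BM simulation in preorder — identical in
  distribution to factorizing the $np \times np$ Kronecker covariance, at
  linear cost — with a chosen true rate matrix, plus an allometric overlay
  `alpha + beta * size + residual` with the size variable itself a univariate
  BM. This is precisely the structure size-correction is meant to remove, so
  recovery of the generating residual correlation is an end-to-end test.
- **Fossils**: terminal branches of a Yule tree are truncated by a uniform
  fraction (each fossil sampled somewhere along its lineage), the root is
  placed at a geological age, and age ranges of half-width `half_width` are
  emitted around the true tip ages, truncated at zero. Ranges contain their
  generating age by construction, and the truth is returned for recovery
  tests.

The two study presets fix the emulated conditions once: the extant preset uses
137 species, a 1,000-tree sample (branch-length jitter, lognormal sd 0.1,
emulating alternative calibrations of one underlying tree — topological
variation is *not* emulated), generating correlation 0.77, residual BM rate
0.002 per Ma on a ~75 Ma Yule tree (birth 0.065/Ma), body-mass BM rate 0.004
(masses spanning roughly two orders of magnitude) and allometric slope 1/3
(length-on-mass isometry). The fossil preset uses 10 taxa rooted at 131 Ma
with tip ages near 120 Ma, generating correlation 0.90, femur length as size
with slope 1 (length-on-length), and stratigraphic half-width 3 Ma — a
Jehol-like uncertainty. These mirror the sample sizes and reported estimates
of the motivating study; the rates and uncertainties are the package's own
choices of realistic magnitudes.

What passing synthetic tests do **not** show: robustness to measurement
error, to model misspecification (non-BM processes, rate heterogeneity), to
topological error in the tree sample, or to non-random taxon sampling. Real
megatree tip sets also mismatch museum trait tables; the pipeline drops
mismatched labels with a manifest (exact matching after trimming and
whitespace-to-underscore normalization; `strict = TRUE` upgrades this to an
error), but no fuzzy reconciliation is attempted.

# Numerical choices

- All solves against $C$ go through its Cholesky factor; $C^{-1}$ is never
  formed. Results match the explicit-inverse textbook formulas to $10^{-8}$
  in tests.
- Matrices and trait tables are aligned to the canonical lexicographic tip
  order before any linear algebra.
- A singular $C$ (coincident tips from zero-length terminal pairs) gets a
  logged ridge of $10^{-8} \max(\mathrm{diag}\,C)$; singularity is detected
  by Cholesky failure *or* reciprocal condition below $10^{-12}$, since
  exactly-duplicated rows can slip through floating-point Cholesky.
- A singular $\hat R$ (collinear traits) is reported with its exact derived
  $r$ ($\pm 1$); the log-likelihood is evaluated under a $10^{-10}$ ridge
  with a warning.
- Hard polytomies are accepted (the BM likelihood is well defined on them);
  a tree is rejected as unrooted only when it has the unrooted-binary node
  count, because `ape::is.rooted` alone would misclassify star trees.
- AICc requires $n > k + 1 = 6$ tips; smaller trees are a hard error rather
  than a silent AIC fallback.

# Problem sizes in the test suite

The suite exercises the estimator oracles on 3–10-tip trees, property
invariants on hundreds of randomized trees, bias/coverage of $\hat r$ on 200
replicates of 200-tip trees per generating correlation, and the full pipeline
at the emulated study scale (137 tips with a 100-tree sample in the test
suite; the analysis scripts and the acceptance script run the full 1,000).
The complete suite runs in well under five minutes on one core.

# Known limitations

- Only the single-regime, two-trait BM model is exposed; no
  Ornstein–Uhlenbeck or early-burst alternatives, no multi-regime rate
  matrices, and no model comparison across processes.
- The ensemble treats trees as exchangeable alternatives weighted by fit; it
  is not a Bayesian posterior over trees.
- The "equal" method is the only zero-branch policy implemented (no "cal3",
  "mbl" or "aba" variants).
- Measurement error and intraspecific variance are ignored beyond specimen
  averaging.
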