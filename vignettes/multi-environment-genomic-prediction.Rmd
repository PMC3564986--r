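---
title: "Multi-environment genomic prediction in NAM-style RIL panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment genomic prediction in NAM-style RIL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namGP)
```

## The problem

Plant breeders evaluating recombinant inbred lines (RILs) across several
environments face two linked questions: how much is gained by modelling the
*across-environment* covariance of genetic and residual effects rather than
analysing each environment separately, and whether genome-wide prediction
(all markers, ridge-type shrinkage) beats prediction from mapped QTL only.
`namGP` implements the full experimental machinery needed to study these
questions on nested association mapping (NAM) panels — several biparental
RIL families sharing one common parent — including a synthetic-data
generator, so every stage is testable without any external download.

## Models

### Multi-environment RR-BLUP

For $n$ lines from $p$ populations phenotyped in $m$ environments, the
stacked model is

$$ Y = X\beta + Z\alpha + \varepsilon, $$

where $X$ carries an overall-mean column plus population indicators,
$Z$ is the $n \times k$ marker matrix coded $+1$ (common-parent homozygote),
$-1$ (diverse-parent homozygote) or $0$, and $\alpha$ holds
environment-specific marker effects with prior
$\alpha \sim N(0,\, (G_0/d) \otimes I_k)$, $d = 2\sum_h p_h(1-p_h)$.
Residual rows are correlated across environments,
$\varepsilon \sim N(0,\, R_0 \otimes I_n)$. $G_0$ ($\sigma^2_{ii}$,
$\rho_{ij}$) and $R_0$ ($e^2_{ii}$, $r_{ij}$) are the $m \times m$ genetic
and residual covariance matrices. The line-level equivalent uses the genomic
relationship matrix

$$ A = \frac{M M^{\mathsf T}}{2\sum_i p_i (1 - p_i)}, $$

taken literally with the *uncentred* coded matrix $M$; for fully homozygous
$\pm 1$ lines the diagonal of $A$ is the constant $k/d \approx 2$, so
model-scale variances convert to line-level variances by
$\mathrm{diag}(A)$. `fitSERRBLUP()` and `fitMERRBLUP()` solve Henderson's
mixed-model equations directly (dense factorisation; system sizes here stay
in the low thousands). For unbalanced records — the CV2 scheme below — the
marker matrices differ per environment and `fitMEUnbalanced()` solves the
observation-level GLS with
$G_{ij,lq} = Z_{il} Z_{jq}^{\mathsf T}\,\sigma^2_{ij}/d$ and
$R_{ij,lq} = e^2_{ij}$ for records of the same line (zero otherwise), then
back-transforms to marker effects via
$\hat\alpha = (G_0/d \otimes I_k) Z_s^{\mathsf T} V^{-1}(y - X\hat\beta)$ —
an exact identity with the marker-level solve, verified against dense
oracles in the test suite.

Predictions deliberately use only
$\hat y_i = \hat\mu_e + \sum_j z_{ij}\hat\alpha_{je}$: the
environment-specific overall mean plus marker effects, never population
deviations. The fixed effects are parameterised with a leading ones column
and sum-to-zero population contrasts so that $\hat\mu_e$ *is* the overall
mean; a ones column plus full indicators would be rank deficient.

### Variance components

$G_0$ and $R_0$ are estimated by restricted maximum likelihood on the
line-level model with covariance $G_0 \otimes A + R_0 \otimes I$ over the
observed cells (`remlMultivariate()`). The multivariate likelihood is
sensitive to starting values, so estimation is staged: univariate REML per
environment (Brent search over the variance ratio on the eigen-rotated
model, with a coarse global grid first because the small-$n$ profile can be
multimodal) supplies the diagonals, bivariate EM fits per pair supply the
off-diagonals, and the multivariate EM starts from there. The EM itself is
the classical expected-complete-data update with the fixed effects
integrated out, which guarantees a monotonically non-decreasing restricted
log-likelihood — asserted per iteration in the tests. Balanced data use a
fast path: rotate lines by the eigenvectors of $A$ and simultaneously
diagonalise $(G_0, R_0)$ each iteration, reducing the E-step to elementwise
work on an $n \times m$ grid. Unbalanced data use a dense observed-cell
implementation sized for a few thousand observations. Convergence is
declared at $|\Delta \log L| < 10^{-6}$ (at most 200 iterations;
non-convergence is flagged, not an error), variances are floored at
$10^{-8}$ times the phenotypic variance, and any non-PSD intermediate is
projected back by eigenvalue clipping. With $m = 1$ the multivariate entry
point delegates to the univariate solver so the reduction is exact rather
than EM-tolerance-exact.

The four covariance structures compared in the cross-validation experiments
are imposed by `applyStructure()` on the unconstrained ("UG-UR") estimate:
"SG-" zeroes the genetic off-diagonals, "-SR" the residual ones; diagonals
are never modified. With both matrices diagonal the ME model decouples into
the per-environment SE fits, an identity the tests check to $10^{-8}$.

### Composite interval mapping and QTL-based prediction

The QTL route scans the genome on a 1 cM grid (snapped to include every
marker position exactly) with background cofactors:
$Y = X\beta + W s + Q\alpha + \varepsilon$. The unobserved QTL genotype $Q$
is replaced by its conditional expectation given the closest flanking
markers under the selfed-RIL two-state chain with switch probability
$R = 2r/(1+2r)$, $r$ the Haldane recombination fraction. Cofactors are
chosen by forward selection with backward elimination at the entry level
$\alpha_{\mathrm{enter}}$ ($10^{-4}$ across-population, $0.01$
within-population, where the smaller training sets need the relaxed level),
with ties broken by map order; cofactors within 10 cM of the tested position
are dropped from that test (standard CIM practice). The test statistic is
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$ in one
environment and the residual-scatter determinant ratio
$(n/2)\log_{10}(|S_0|/|S_1|)$ in the joint multi-environment scan.
Genome-wide thresholds come from permutations at significance level 0.05
(5,000 by default; the calibration tests use fewer): single-environment
permutations shuffle phenotype values within each population, joint
permutations shuffle whole multi-environment rows so the correlation
structure is preserved. Above-threshold runs separated by less than 20 cM
on a chromosome merge into one region; each region contributes one QTL at
its (leftmost) maximum. Called QTL are then refitted *jointly* by
multivariate multiple regression with the population effects, and QTL-based
prediction (QP) applies the same prediction equation restricted to the
called positions. Under CV2, the joint-scan route first completes missing
cells by iterated conditional-expectation imputation
(`imputePhenotypes()`), using $G_0 + R_0$ as the conditioning covariance
when available and the residual covariance of the completed data otherwise.

### Cross-validation design

Two schemes: **CV1** splits each population 60/40 (training size
$\lfloor 0.6\,n\rfloor$) and masks validation lines in *all* environments —
predicting wholly untested lines; **CV2** masks each (line, environment)
cell independently with probability 0.4 — predicting missing records of
partially tested lines; lines losing all $m$ cells are dropped (expected
fraction $0.4^4 = 2.56\%$ at $m = 4$). Two scopes: **WP** trains within the
test population, **AP** trains on the other populations (CV1) or on all
populations' observed cells (CV2). `runExperiment()` shares one split/mask
per replicate across all compared models so gains
$(R_A - R_B)/R_B$ and paired $t$-tests (replicate-level pairing,
$\mathrm{df} = \mathrm{replicates} - 1$) always compare identical validation
sets. Accuracy is the Pearson correlation between predicted values and the
held-out *observed phenotypes* per population and environment; undefined
correlations (constant vectors) are excluded from averages and counted.
`densitySweep()` repeats CV1 at a series of marker-thinning spacings
(greedy left-to-right thinning that always keeps chromosome-end markers),
holding the splits fixed across densities; a sweep at a single spacing of
zero reproduces the plain experiment exactly.

Variance components and permutation thresholds are estimated once per data
set from the full phenotype records (per population for WP, once on the
combined panel for AP) and reused across replicates — the design treats
them as properties of the data set, not of a split, and this matches how
the threshold and structure-comparison machinery is meant to be used.

## What the generator emulates — and what it does not

`simulateMap()` places markers uniformly at random on equal-length
chromosomes with both ends pinned; `simulateRILGenotypes()` draws
final-generation RILs directly from the two-state Markov chain with the
Haldane–Waddington selfed-RIL map function (no generation-by-generation
selfing, no residual heterozygosity — generated genotypes are pure
$\pm 1$). `traitArchitecture()` places a configurable number of QTL (default
70, "many small effects") *at marker positions*, draws their
environment-specific effects i.i.d. from $N(0, G_0/s)$ with $s$ the summed
QTL-genotype variance, and then applies one final $m \times m$ rotation so
the realized line-level genetic covariance equals the target $G_0$ exactly;
per-environment line-mean heritability is
$h^2 = G_{0,ee}/(G_{0,ee} + R_{0,ee})$, 0.74 by default.
Population-by-environment intercepts are drawn once with standard deviation
0.5 (trait units; their magnitude is a free choice — they are absorbed by
fixed effects and never predicted). Default panel scale mirrors a maize NAM
panel: 25 populations of 165 lines, 10 chromosomes, ~819 markers over
~1,389 cM (≈1.6–1.7 cM mean spacing), $m = 4$ environments with genetic
correlations 0.77 and residual correlations 0.31.

The generator does **not** emulate: replicated multi-location plot
structure (only line-by-environment means), epistasis or dominance,
genotype-by-year decompositions beyond generic environments, marker
ascertainment, or QTL between markers. Passing tests therefore demonstrate
the *statistical machinery* under a clean additive multivariate-normal
world; they do not certify performance on real field data, where
misspecification (QTL off markers, non-normal residuals, estimated-versus-
true covariance mismatches) can change the small contrasts in particular.

## Numerical and design choices

* **Scale convention.** Because $\mathrm{diag}(A) = k/d \approx 2$ for
  inbred $\pm 1$ coding, REML variances are model-scale; line-level
  variances multiply by $\mathrm{diag}(A)$, and the reported univariate
  $h^2$ already uses this conversion. Marker-effect priors divide $G_0$ by
  $d$, keeping $G = G_0 \otimes A$ internally consistent.
* **Complete-LD deduplication** treats only *exactly identical* adjacent
  genotype columns as complete LD and keeps the leftmost.
* **Determinism.** Every stochastic operation takes one integer seed; all
  sub-draws derive from it by a fixed stream-splitting rule, so whole
  experiments replay bit-for-bit.
* **Singular systems** fall back to flagged minimum-norm (pseudo-inverse)
  solutions; near-singular $G_0$/$R_0$ are regularised by eigenvalue
  clipping and logged in the fit diagnostics.
* **Problem sizes.** The package's own acceptance analyses run at a
  reduced scale chosen to keep the full pipeline interactive: 3 populations
  of 300 lines, 2 environments, 200 markers over 330 cM (preserving the
  ~1.65 cM mean spacing that anchors the density sweep), 70 QTL, 30
  cross-validation replicates, 200-permutation thresholds with a 2 cM scan
  grid, and 1,000-permutation/200-data-set threshold calibration. REML
  recovery checks use 20 panels of 1,000 lines with $m = 4$.

## Known limitations

* The observed-cell REML path builds dense covariance matrices; it is meant
  for panels up to a few thousand observed cells, not biobank scale.
* In CV2, because the true residual correlation is genuinely nonzero and
  well estimated here, modelling it (SG-UR) yields a *small* positive
  accuracy effect rather than the zero-to-negative effect often seen on
  real data — the dominant driver of multi-environment gains remains the
  genetic covariance (UG-SR), by an order of magnitude.
* Replicate-paired $t$-tests on identical validation sets are extremely
  powerful; with 30+ replicates they can flag practically negligible
  (<0.005) accuracy differences as significant. Interpret significance
  together with the gain magnitude.
* Thinning-based density comparisons interact with the generator's
  QTL-at-marker placement: removing a QTL's own marker costs more accuracy
  here than on real panels where markers only tag QTL.
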