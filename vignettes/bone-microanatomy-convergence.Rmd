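---
title: "Quantifying bone microanatomy and testing convergence on timetrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone microanatomy and testing convergence on timetrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoconv)
```

## The scientific problem

Several mammalian lineages independently moved underground, and digging with
the forelimbs puts the humerus under unusual mechanical load. A recurring
observation is that subterranean species increase the bone fraction of the
humeral head, and that true moles push this phenotype far beyond other
diggers. Two statistical questions follow. First, after removing the effects
of body size and shared ancestry, do subterranean species differ from the
rest? Second, did the independent subterranean lineages *converge* — move
toward each other in trait space — rather than merely drift apart less?

`osteoconv` implements the full chain needed to answer both questions:
voxel-based quantification of the traits, timetree preparation (including
fossil placement), lambda-PGLS inference, and a univariate convergence test
with a simulation null. A synthetic-data layer generates trees, adaptive
regimes, traits and voxel phantoms with known ground truth, so every stage
is validated without any external download.

## Microanatomical quantities

**BV/TV** is the fraction of bone voxels inside a volume of interest (VOI).
For the humeral head the VOI is a cube (or sphere) centred in the epiphysis;
for the distal articulation `capitulum_voi_center()` reproduces the landmark
protocol: the proximodistal coordinate is the midpoint of the capitulum's
extremes, and the in-plane coordinates are the centre of the rectangle
bounded by the anterior and lateral capitulum edges, the maximal concavity
of the anterior articular surface, and the maximal posterior extension.
The VOI edge length is a configurable fraction of the head diameter (the
source protocol does not pin a universal value; we default to the operator's
choice and record it). Specimens whose VOI touches the epiphyseal line carry
an operator-set exclusion flag — detection of the line itself is a manual,
anatomical judgement we deliberately do not automate — and the measurement
functions refuse flagged VOIs with a typed condition.

**Mean Tb.Th** uses the model-independent local-thickness definition: the
value at a bone voxel is the diameter of the largest sphere fully contained
in bone that covers the voxel. We compute the exact Euclidean distance
transform (a three-pass separable algorithm) and then paint spheres from
candidate centres, keeping for each voxel the largest covering diameter; a
cheap dominance filter skips centres whose sphere is provably contained in a
neighbour's, which accelerates the computation without changing the result.
Distances are measured to actual background voxels only, so structures
touching the volume faces are not artificially eroded. The discrete radius
convention (centre-to-centre distances) makes an even-thickness plate exact
and carries at most a half-voxel bias elsewhere; the phantom tests bound
this below 10% at the element sizes we use (≥ 3 voxels, the documented
validity limit).

**Global compactness** summarizes the diaphysis: per transverse slice, bone
area divided by the area enclosed by the periosteal contour. The contour is
obtained by morphological closing (disk radius 3 voxels by default — enough
to bridge nutrient foramina at typical resolutions, configurable) followed
by hole filling; slices without bone are flagged and excluded from the
means. The per-slice total areas also yield the mean cross-sectional area
used for body-mass imputation.

**Thresholding.** Grayscale volumes are binarized by Otsu's
between-class-variance criterion on the volume (or VOI) histogram, with a
numeric override; the source protocol does not state a global threshold, so
a per-volume adaptive default is the defensible choice.

Ground truth comes from phantoms: uniform volumes, plate stacks, rod
lattices, a hollow tube (annulus compactness `(r_out^2 - r_in^2) / r_out^2`),
and Gaussian-random-field textures smoothed with kernel width
`element_thickness / 2` and thresholded at the quantile that makes the
achieved BV/TV match the target to within one voxel count — a monotone,
deterministic calibration. What the phantoms do *not* emulate: partial-volume
gray ramps at interfaces, scanner noise and beam hardening, or anisotropic
real trabecular architecture. Passing the phantom suite therefore validates
the measurement definitions and their discretization, not scanner-specific
segmentation quality.

## Timetrees and fossil placement

Trees are strictly binary with positive branch lengths; tip heights may
differ (fossil tips end above the present). `recalibrate_divergence()` moves
one node to an externally calibrated age, touching only adjacent branches.
`graft_fossil()` attaches a fossil of known age to the stem of a host clade
under three rules: an explicit fraction of the stem length (measured from
the older, rootward end — the convention we fixed since the source protocol
leaves it open), the midpoint between the stem's older end and the fossil
age, or a "push" that places the divergence a stated interval older than the
fossil, raising the host node where needed. Terminal branch length is always
divergence age minus fossil age and must be positive; infeasible requests
raise a calibration-conflict condition rather than silently clamping.

The lambda covariance `phylo_vcv(tree, lambda)` multiplies off-diagonal
shared path lengths by lambda and keeps the diagonal at the tip heights.
This matters on non-ultrametric trees: the diagonal is exactly the variance
heterogeneity that the regression weights must carry.

## Lambda-PGLS, ANCOVA, and pseudo-R²

`pgls_fit()` fits GLS with covariance
`sigma^2 S^{1/2} C(lambda) S^{1/2}`, `C(lambda)` the lambda-scaled
correlation and `S = diag(tip heights)` (option `weights = "none"` drops the
heterogeneity). This product equals the lambda-transformed Brownian
covariance, so the construction is identical to a Pagel correlation
structure plus fixed-variance weights, and the test suite verifies exact
agreement (coefficients, standard errors, and both ML and REML
log-likelihoods) with an independent GLS implementation at fixed lambda.
Lambda is profiled over [0, 1] by bounded one-dimensional optimization of
the restricted likelihood (REML default; ML exposed). We bound the search at
1 rather than the tree-specific maximum because the correlation-structure
convention guarantees positive-definiteness on [0, 1] and keeps estimates
comparable across trees. Coefficient tests are t-tests with `n - p` degrees
of freedom; p-values are two-sided and reported raw (no multiplicity
correction, matching standard practice for a handful of planned contrasts).

`phylo_ancova()` fits `trait ~ lifestyle + log10(body mass)` and reports the
group effect as a Wald F test (the squared t for two groups); factors need
at least three members per level. The Nagelkerke pseudo-R²
`1 - exp(-(2/n)(logLik_full - logLik_null))` compares ML (never REML)
likelihoods, re-optimizing lambda for each model; REML likelihoods of models
with different fixed effects are not comparable, which is why the refit is
internal. The ceiling-corrected variant
(`R² / (1 - exp((2/n) logLik_null))`) is available via `ceiling = TRUE`, but
for a continuous response the ceiling is essentially 1, so the plain
likelihood-ratio form is the default and reports name the variant used.

Body mass is imputed by PGLS of `log10(mass)` on `log10(cross-sectional
area)` over extant species with both known — the log-log scale is the
power-law allometry standard, and the resulting pseudo-R² is insensitive to
the base. Predictions (fixed effects only; no phylogenetic BLUP correction,
as is usual for imputation) cover fossils; species lacking a cross-sectional
area keep their database mass, flagged by `mass_source`. Size correction
takes residuals of `trait ~ log10(mass)`; with an intercept in the model the
residuals are invariant to mass-unit rescaling.

## The C1 convergence test

Each independent acquisition of the derived lifestyle is collapsed to one
tip at its clade's stem, with tip height the mean member height and trait
the arithmetic mean of member (size-corrected) values — so acquisitions,
not species counts, drive the test. Ancestral states are maximum-likelihood
Brownian reconstructions (computed by Gaussian message passing in linear
time; the suite checks them against a direct GLS solve from the joint
covariance matrix). For each focal pair, `Dtip` is the current trait
distance and `Dmax` the maximum distance between any two states on the
lineages back to the MRCA. Two conventions are deliberate and documented:

* tip states are included among the `Dmax` candidates, which fixes C1 = 0
  for lineages that only ever diverged (otherwise C1 could be undefined or
  negative for divergence);
* with more than two focal tips, `Dtip` and `Dmax` are summed across pairs
  *before* the ratio, matching the published multi-lineage form; the
  per-pair decomposition is also returned.

C1 is invariant to shifting and positive rescaling of the traits, and lies
in [0, 1] whenever some ancestral variation exists; all-equal states raise
an undefined-C1 condition. Significance: the Brownian rate is estimated by
REML (mean squared phylogenetically independent contrast) on the collapsed
tree, `n_sim` Brownian datasets are simulated from the ML root state
(default 1000 — the simulation count behind a published p is rarely stated,
so we pick one that gives ~0.001 resolution), C1 is recomputed on each, and
`p = (#{sim >= obs} + 1) / (n_valid + 1)` with the +1 correction avoiding
p = 0. Undefined replicates are dropped and counted, with a warning beyond
10%. Ancestral uncertainty is ignored (point ML states), as in the standard
implementation of this statistic; the p-value therefore calibrates the
statistic as defined, not a posterior over histories.

## Synthetic study conditions

The generator's defaults reproduce the study design: 155 species on a
160 Ma (therian-scale) Yule timetree, 11 non-nested subterranean
acquisitions painted by rejection sampling (matching the "independent
acquisitions" semantics; the largest is flagged talpid-like), two fossil
tips truncated above the present, and traits evolving by multi-optimum OU
simulated with the *exact* transition density (no Euler discretization
error), so that recovery tests measure the estimators, not the simulator.
Free parameters were set once, on scientific grounds, to mirror the
published regime: head BV/TV uses `sigma2 = 0.003`, `alpha = 0.15`
(phylogenetic half-life ~4.6 Ma, short against regime durations — a genuine
adaptive optimum) and optima 0.35 / 0.65 / 0.95 for background /
subterranean / talpid-like, putting the subterranean shift at ~3 stationary
standard deviations and the talpid-like clade clearly beyond it, as in the
published violin and phenogram patterns (strong lifestyle effect,
significant convergence, talpid overshoot so that excluding talpids raises
C1). The acceptance script's diaphyseal-compactness analogue instead uses a
weak pull (`alpha = 0.02`) and nearly shared optima — a trait whose
variation is mostly drift, mirroring the published non-result for
compactness. Body mass is an independent Brownian trait on the log10 scale
around 100 g, and cross-sectional area follows mass with slope 2/3 and
0.05 dex of lognormal scatter, so the imputation step has a known truth.

What the synthetic layer does not emulate: empirical tree shape (a Yule
topology, not the mammal tree), measurement error in the traits,
phylogenetic signal in body mass *residuals* of the allometry, or
correlated evolution between traits. Green tests therefore demonstrate
correctness and calibration of the estimators under the stated generating
processes, not that the empirical effect sizes are right.

## Numerical choices and problem sizes

* Lambda optimization: `optimize()` on [0, 1] with tolerance 1e-6, endpoint
  values compared explicitly so boundary optima are never missed.
* Weight matrices are Cholesky-factorized; non-positive-definite cases
  (impossible for lambda in [0, 1] with valid trees) raise a diagnostic
  error rather than a silent pseudo-inverse.
* Zero-length pendant edges are perturbed by 1e-8 with a warning before
  ancestral-state reconstruction; zero internal edges are refused.
* The grf phantom threshold is the empirical quantile of the smoothed field
  (type-1, deterministic), exact to one voxel count.
* Test and acceptance problem sizes, chosen to characterize the estimators
  well while keeping a full run in minutes: C1 null calibration uses
  200 meta-replicates of `n_sim = 500` on 100-tip trees with 11 focal tips;
  lambda recovery 50 replicates on 100-tip trees; ANCOVA power 100
  replicates (5-sigma offset) and permutation calibration 200 replicates;
  C1-oracle equivalence 40 random 4–6-tip trees checked exactly against
  exhaustive enumeration.

## Known limitations

* No trabecular anisotropy, connectivity or structure-model-index measures;
  the two implemented architectural parameters are the ones relevant for
  compacted trabeculae.
* The thickness map is voxel-discrete; sub-voxel strut thicknesses (< 3
  voxels) are not meaningful, and values carry up to a half-voxel bias.
* PGLS predictions ignore the phylogenetic covariance between new and
  training species (no BLUP), which slightly widens imputation error for
  fossils nested deep inside the reference clade.
* The permutation calibration of the ANCOVA holds approximately: permuting
  labels on regime-structured (OU) traits breaks exchangeability mildly, so
  its p-value distribution can deviate from uniform in unlucky draws.
* C1 inherits the known behaviour of its family: lineages that overshoot a
  shared optimum (the talpid-like clade) *lower* aggregate C1, which is why
  the with/without-exclusion pair of tests is always reported together.
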