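# osteoconv

Phylogenetic comparative analysis of long-bone microanatomy, built around the
question of how often — and how strongly — mammals that moved underground
converged on the same internal bone phenotype. The package covers the whole
chain from voxel data to evolutionary inference:

* **Microanatomy from voxel volumes.** Bone volume fraction (BV/TV = bone
  voxels / total voxels in a volume of interest), mean trabecular thickness
  (mean Tb.Th, the sphere-fitting local-thickness definition: at each bone
  voxel, the diameter of the largest sphere fully inside bone that contains
  it), and diaphyseal global compactness (per transverse slice, bone area
  over the area enclosed by the periosteal contour, averaged along the
  shaft). Otsu or manual thresholding, landmark-based VOI placement for the
  distal articulation, and an operator-set epiphyseal-line exclusion flag.
* **Timetree handling.** Newick I/O with strict contracts (binary topology,
  positive branch lengths, non-ultrametric allowed), divergence
  recalibration, fossil-tip grafting under midpoint / stem-fraction /
  push-node rules, and lambda-scaled phylogenetic covariance matrices whose
  diagonal keeps the (unequal) tip heights.
* **PGLS with Pagel's lambda.** `pgls_fit()` fits
  `y = X beta + e`, `e ~ N(0, sigma^2 S^{1/2} C(lambda) S^{1/2})`, where
  `C(lambda)` is the phylogenetic correlation matrix with off-diagonals
  scaled by lambda and `S` holds root-to-tip heights (species variance
  heterogeneity on non-ultrametric trees). Lambda is profiled over [0, 1] by
  REML (or ML). Phylogenetic ANCOVA (`trait ~ lifestyle + log10(mass)`),
  Nagelkerke pseudo-R², allometric body-mass imputation from humeral
  cross-sectional area, and size-correction residuals build on it.
* **Convergence.** The univariate C1 statistic on an acquisition-collapsed
  tree: each independent acquisition of the subterranean lifestyle becomes
  one tip carrying its clade's mean size-corrected value; for each focal
  pair, `Dtip = |x_i - x_j|` and `Dmax` is the largest distance between
  Brownian-ML ancestral states on the two lineages back to their MRCA (tips
  included); `C1 = 1 - sum(Dtip) / sum(Dmax)`. Significance comes from
  Brownian-motion simulation with the REML rate of the observed data.
* **Synthetic data.** Yule timetrees with fossil tips, non-nested regime
  paintings ("independent acquisitions", one optionally talpid-like with an
  extreme optimum), exact BM/OU trait simulation, and trabecular voxel
  phantoms (plates, rod lattices, calibrated Gaussian-random-field textures)
  with known ground truth — so the entire pipeline is testable offline.

## Worked example

The pipeline driver runs the full analysis on a synthetic dataset that
mirrors the study design: 155 therian-like species, 11 independent
subterranean acquisitions (one talpid-like clade with an extreme optimum),
two fossil tips, body mass imputed from cross-sectional area.

```r
library(osteoconv)

b <- run_pipeline(list(seed = 1, n_sim = 1000,
                       synth = list(n_tips = 155, n_shifts = 11,
                                    fossil_tips = 2, traits = "bvtv")))
b$variants$base$ancova
#>      trait   n    lambda        F df1 df2      p_group pseudo_r2   logLik
#> bvtv  bvtv 155 0.5928369 74.37456   1 152 7.936573e-15 0.3194751 120.3735

str(b$variants$base$c1$bvtv)
#> List of 3
#>  $ n_acquisitions: int 11
#>  $ all           :List of 4
#>   ..$ c1    : num 0.461
#>   ..$ p     : num 0.014
#>   ..$ n_sim : int 1000
#>   ..$ sigma2: num 0.000654
#>  $ excluding     :List of 6
#>   ..$ excluded      : chr "acq_talpid"
#>   ..$ n_acquisitions: int 10
#>   ..$ c1            : num 0.524
#>   ..$ p             : num 0.00599
#>   ..$ n_sim         : int 1000
#>   ..$ sigma2        : num 0.000654
```

The ANCOVA row says the subterranean lifestyle shifts head BV/TV after
controlling for body mass and phylogeny (group F-test, p ~ 8e-15; residual
lambda 0.59). The C1 section: the 11 acquisitions are significantly
convergent (C1 = 0.46, simulation p = 0.014 from 1000 Brownian null
datasets), and convergence is *stronger* when the extreme talpid-like clade
is excluded (C1 = 0.52) — that clade overshoots the optimum the other
subterranean lineages share. The group summary feeding violin plots:

```r
b$variants$base$summary
#>                group   n        mean      median         q25        q75
#> 1   fossorial_talpid  10  0.49569148  0.49518003  0.46709512 0.52605041
#> 2   non_subterranean 129 -0.03759232 -0.03500046 -0.09233859 0.02287265
#> 3 other_subterranean  16  0.18411016  0.22057612  0.08343606 0.28046540
```

Microanatomy on a calibrated phantom:

```r
ph <- generate_phantom(phantom_spec("grf", 64, element_thickness = 0.06,
                                    target_bvtv = 0.3, seed = 1))
ph
#> voxel_volume: 64 x 64 x 64 voxels, 0.01 mm/voxel, binary (BV/TV = 0.300)
mean_trabecular_thickness(ph)
#> [1] 0.07993238
```

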