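---
title: "Hindcast evaluation of species distribution models in dissimilar climates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hindcast evaluation of species distribution models in dissimilar climates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoshift)
```

## The question

Correlative species distribution models (CSDMs) learn a statistical
relationship between occurrences and climate; process-explicit models (PEMs)
predict performance from ecophysiological mechanism. Both are routinely
projected into climates unlike anything in their calibration data, and the
folk claim is that mechanism buys robustness. `paleoshift` builds a fully
synthetic, fully known testbed in which that claim becomes a measurable
contrast: how fast does hindcast skill decay with climatic dissimilarity for
each model family, when the truth is known exactly?

The pipeline mirrors a Holocene hindcasting design: models are calibrated on
a recent "reference" climate, then asked to predict species ranges backwards
through an abrupt deglacial-style warming, with dispersal simulated
explicitly and validation done against virtual fossil-pollen archives rather
than against the raw truth — so every evaluation artifact of real
paleo-validation (site sparsity, counting noise, age uncertainty,
taphonomic filters) is present but controlled.

## The synthetic world

**Climate.** `gen_climate_series()` produces 30-year windows every 250
model-years. Each cell, season and year gets a 3-month temperature mean and
precipitation sum: a north-south temperature gradient (8 °C across the grid
by default), an east-west precipitation modulation, iid interannual noise,
and a warming ramp of amplitude 8 °C completed between the changepoint
(11.5 kyr BP) and 11 kyr BP. Warming is damped southwards
(`south_damping = 0.5`): the northern edge feels the full amplitude, the
southern edge half of it. This polar-amplification profile is what keeps
southern refugia climatically viable in the cold state; without it the cold
period has no clearly suitable cell anywhere and the "truth" itself becomes
an artifact of marginal cells sitting at the habitability threshold. From
the seasonal fields we derive the covariates the models see: coldest-month
minimum temperature (winter mean − 6 °C), growing degree-days > 5 °C over
spring + summer, annual precipitation, and an early-summer water balance
(two-thirds of summer precipitation minus a linear
evapotranspiration demand of 9 mm per °C of summer warmth). These formulas
are deliberately simple; they only need to produce realistic gradients,
correlations and ranges, not meteorology.

**Species truth.** A `virtual_species()` is three logistic response curves —
frost survival in the coldest-month minimum, drought survival in summer
water balance, reproduction in degree-days — whose product is fitness in
[0, 1]. The shipped demo uses a beech-like species (frost midpoint −14 °C,
drought midpoint −60 mm, 900 degree-days) and a hardier oak-like species
(−18 °C, −110 mm, 1100 degree-days). True occupancy is fitness thresholded
at 0.1, rescaled, and run through the same migration automaton as the
models, so the truth is dispersal-limited too.

**Pollen.** Sites are scattered uniformly; a fraction (10%) is marked
marine. Per slice, a site yields a sample with probability 0.8; grain
totals are lognormal around ~320 (so a realistic share falls below the
200-grain filter), age uncertainties lognormal around ~150 yr (some exceed
the 500-yr filter), and reported ages are jittered by that uncertainty.
Detection is a two-level step function: an occupied cell gives the focal
taxon an expected relative abundance of 8%, an unoccupied one 0.2%, and
counts are multinomial. The step-function detection model is the simplest
model under which the standard abundance thresholds (1% beech/fir, 2.5%
oak) are meaningful; nothing in it encodes pollen productivity,
transport or basin size, which is the main sense in which passing tests
here do not certify behaviour on real archives.

## The three model families

* **Expert process model** — the true mechanism with its true parameters
  (the idealised limit of a well-measured PEM).
* **Fitted process model** — the same mechanistic form, but all six
  parameters re-estimated from reference-period occurrences by maximising
  AUC with a bounded (mu, lambda) Gaussian evolution strategy with restarts,
  keeping the best-AUC run. Parameters whose limits are not expressed in
  the reference climate (e.g. the frost midpoint when no cell is cold
  enough) are unidentified and stay wherever the prior bounds and the
  optimiser leave them — exactly the epistemic situation of inverse
  calibration.
* **Correlative model** — lasso-regularised logistic regression
  (`glmnet`) on standardised degree-2 polynomial climate features, trained
  on presence cells versus uniform background cells of the reference slice.
  One regularised linear-in-features classifier stands in for the usual
  CSDM ensemble: the analysis needs the correlative/mechanistic contrast,
  not an inter-algorithm spread.

All three are thresholded the same way: the TSS-maximising threshold on the
observed reference-period distribution (presence/absence over the domain,
the analogue of thresholding on inventory data), with ties broken towards
the smallest threshold (the more permissive presence rule). Above-threshold
suitability is rescaled by the frozen calibration-period maximum and treated
as a colonisation probability.

## Dispersal

The migration model is a cellular automaton on a fine grid nested inside
the coarse climate grid (factor 2 in the demo, i.e. 80 × 80 fine cells).
Once a year, each unoccupied cell receives propagules from occupied cells
through a discretised fat-tailed kernel (exponential-power by default,
`a = 400` m, `b = 1`, radius 5 cells of 500 m) and becomes colonised with
probability `p * (1 − Π(1 − k))` — arrival times establishment, the
standard automaton reading of "rescaled suitability is the probability of
becoming colonised", which keeps the zero-suitability contract exact.
Independently, each occupied cell fires a long-distance propagule with
probability 0.01 per year, at a tail-sampled distance and uniform angle;
off-grid landings are lost and grid edges absorb. When a slice update drops
a cell's probability to zero its population is vacated (the paper-style
"cannot survive" reading; no seed bank is kept). Occupancy starts from all
suitable cells of the first slice with any suitability, deferring up to
three slices when a model predicts no presence at the start. The
convolution is computed by FFT with arrival probabilities clamped at
`1e-9`/`1 − 1e-9`, so deterministic kernels behave exactly and FFT leakage
cannot colonise beyond the kernel radius.

## Scoring and statistics

Predictions are coarsened (a coarse cell is present iff any fine cell is
occupied) and compared with the pollen grid per 500-year bin, only over
cells that have retained pollen sites; Sørensen similarity
`2tp/(2tp+fp+fn)` is the headline skill score (immune to true-negative
inflation), TSS the secondary one. Climatic dissimilarity between each bin
and the reference slice is `1 −` the mean Sørensen overlap of bootstrapped
KDE hypervolumes built on the first three principal components of the
cell-by-year seasonal features (pooled standardisation by default; a
reference-only option exists because the real-world convention is genuinely
ambiguous). Finally `ordered_beta_fit()` regresses skill on dissimilarity
with a family-specific slope, point masses at 0 and 1 via ordered
cutpoints, and the bootstrap sd of dissimilarity treated as predictor
measurement error (marginalised by Gauss-Hermite quadrature); the Bayesian
path is an adaptive random-walk Metropolis sampler started at the posterior
mode under Normal(0, 5) priors on intercepts, slopes and cutpoints and an
Exponential(0.1) prior on the precision. A maximum-likelihood path on the
same marginal likelihood serves fast checks.

## Numerical choices worth knowing

* **Hypervolume bandwidths** are 2 × Silverman. Silverman's rule is tuned
  for density estimation, not boundary delineation; with it, the estimated
  95% region of a 1000-point 3-D normal sample comes out ~15% small and
  two bootstrap regions of the *same* distribution overlap only ~0.83.
  With the doubled bandwidth the region volume matches the closed-form
  chi-square ball to a few percent and self-dissimilarity drops to ~0.08.
  The boundary level is calibrated on densities of the original points
  (bootstrap duplicates would inflate the level).
* **Kernel discretisation** integrates the continuous density over each
  offset cell with a 5 × 5 subgrid of midpoints; a single midpoint
  overweights the origin cell of sharply peaked kernels.
* **Threshold ties** break to the smallest TSS-maximising score;
  **pollen presence** is inclusive at the abundance threshold; **binning**
  weights are inverse age uncertainty (plus 1 yr) times a triangular
  recency weight, falling back (flagged) to a plain mean when all weights
  vanish on bin edges.
* **Degenerate inputs** raise classed conditions rather than returning
  quiet values: empty suitability (`paleoshift_empty_map`), evaluations
  with no data cells (`paleoshift_empty_evaluation`), single-class labels,
  rank-deficient PCA references.

## The shipped demo and what the tests show

`run_demo(seed)` runs the full chain on a 40 × 40 coarse grid, two species,
twelve slices (12 → 9.25 kyr BP) in about a minute: climate, truth,
pollen, calibration, migration for 3 model families × 2 species, per-bin
dissimilarity (6 bootstrap hypervolumes per side, 500-point clouds,
400-row subsamples), and the ordered beta regression (14,000 iterations).
Problem sizes were chosen so the whole acceptance suite — including ten
demo replicates — runs on a laptop core; they are config fields, not
constants. The headline, directional result is that the correlative
family's fitted decline slope is more negative than the expert process
family's in at least nine of ten seeds. The absolute slopes are not
comparable to any real-data analysis — the synthetic world is smaller,
smoother and kinder than Europe — but the ordering is the mechanism the
package exists to expose: the correlative model has never seen the cold
tail of the niche, while the process truth carries it by construction, and
the fitted process model sits in between, limited by what the reference
period identifies.

```{r demo, eval = FALSE}
res <- run_demo(seed = 42)
res$fit$slopes          # per-family decline slopes with 95% intervals
res$dissimilarity       # per-bin climatic dissimilarity (mean, sd)
head(res$records)       # model x species x bin performance table
```

## Known limitations

* The climate generator has no spatial autocorrelation in the noise, no
  interannual persistence, and no orographic precipitation; dissimilarity
  levels are therefore cleaner than in reanalysis-driven work.
* Pollen detection ignores productivity differences and transport; the
  step-function detection model makes the abundance thresholds exactly
  meaningful, which flatters the pollen pipeline relative to reality.
* The expert model is the truth itself — an upper bound no real PEM
  attains. Interpret the demo's expert slope as "evaluation-noise floor",
  not as an attainable field result.
* Inverse calibration with a few hundred objective evaluations finds
  good-AUC, not global-optimum, parameter sets; its run-to-run spread is
  itself part of what the fitted-process family represents.
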