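# paleoshift

Do process-explicit species distribution models really hold up better than
correlative ones when the climate drifts away from everything they were
calibrated on? `paleoshift` is an R package that turns that question into a
controlled, fully reproducible experiment. It builds a synthetic
Holocene-like world with known ground truth — a gridded climate trajectory
with an abrupt early warming, a mechanistic species fitness surface, and
virtual fossil-pollen archives with realistic counting noise, age
uncertainty and taphonomic filters — then calibrates three surrogate model
families on the recent "reference" period, hindcasts species ranges
backwards through the warming with an explicit dispersal simulation, scores
the hindcasts against the pollen record, and asks how fast skill decays
with climatic dissimilarity for each family.

It is written for ecological modellers and biostatisticians who want a
transparent desk-scale testbed for model-transferability questions, with
every stage exposed as a tested function.

## The core quantities

* **Hindcast skill**: Sørensen similarity computed from the confusion
  matrix over pollen-informed cells only, `S = 2TP / (2TP + FP + FN)` —
  unaffected by inflated true negatives; TSS
  (`sensitivity + specificity − 1`) as the secondary metric.
* **Climatic dissimilarity**: `1 − Sørensen overlap` between bootstrapped
  Gaussian-KDE hypervolumes built on the first three principal components
  of seasonal climate features (3-month temperature means and precipitation
  sums), summarised as a mean and sd over all bootstrap pairs.
* **Transferability decline**: a Bayesian ordered beta regression of skill
  `y ∈ [0, 1]` on dissimilarity `x`, with point masses at the bounds via
  ordered cutpoints `c1 < c2`, a family-specific slope `β_g`, and the
  bootstrap sd of `x` treated as predictor measurement error
  (`x_obs ~ N(x_true, σ)`, marginalised by Gauss-Hermite quadrature).

The migration model is a cellular automaton at a fine resolution nested in
the coarse grid: annual colonisation through a discretised fat-tailed
kernel plus rare long-distance events (probability 0.01 per occupied cell
per year), driven by TSS-thresholded, rescaled suitability updated every
250 model-years.

## A worked example

```r
library(paleoshift)
res <- run_demo(seed = 42)   # ~1 minute: full pipeline, 2 species,
                             # 12 slices, 3 model families
res$fit$slopes
#>            group  estimate     lower      upper
#> 1    correlative -4.340706 -6.741084 -1.8297126
#> 2 expert-process -1.675096 -4.453178  1.0113669
#> 3 fitted-process -1.618215 -3.890667  0.6993861
res$dissimilarity
#>   bin_bp dissim_mean  dissim_sd
#> 1  12250  0.55660589 0.02537037
#> 2  11750  0.52966132 0.02965042
#> 3  11250  0.30199144 0.01915672
#> 4  10750  0.10204085 0.02204039
#> 5  10250  0.08882562 0.01740823
#> 6   9750  0.07261978 0.01296969
#> 7   9250  0.13617727 0.02304448
```

Read this as: the oldest, pre-warming bins are climatically far from the
reference period (dissimilarity ~0.55 versus ~0.1 for post-warming bins),
and skill declines with dissimilarity more than twice as steeply for the
correlative family (slope ≈ −4.3, 95% interval excluding zero) as for the
expert process family (≈ −1.7), with the inverse-calibrated process family
close to the expert one — the directional contrast the package is built to
expose.

`run_demo(seed, out_dir = "...")` additionally writes the climate, pollen
archive, presence grid, performance records, fit summary and a manifest of
stage seeds and md5 checksums; rerunning with the same seed reproduces the
checksums bit for bit. A thin command-line wrapper with `demo`,
`experiment` and `dissimilarity` subcommands ships in
`inst/cli/paleoshift.R`.

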