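# iridens

Corneal densitometry (CD) measured from Scheimpflug anterior-segment images
is used as a clinical proxy for corneal transparency — but the slit beam
also reflects off the iris and the corneoscleral periphery, and lightly
pigmented irises reflect far more than dark ones. Those reflections overlap
the corneal region and inflate CD in light-eyed subjects, mimicking a loss
of transparency that is not there. **iridens** is for imaging scientists and
ophthalmic researchers who want to quantify that bias: it implements the
whole measurement chain and validates it end to end on synthetic data with
known ground truth.

The core quantities:

* **Corneal densitometry** — the mean pixel intensity (MPI) of the
  segmented cornea, averaged over the acquisition's meridional frames
  (MPI and CD are used interchangeably).
* **Brightness artefacts** — per frame, an adaptive threshold
  `T = MPI + 3·SD` is set from the corneal pixels; the artefact load of the
  iris band and the lateral corneoscleral flanks is the percentage of
  region pixels strictly above `T`. The threshold moves with global
  illumination, so the percentages are shift-invariant.
* **IrisColor** — an objective, continuous iris-pigmentation index from
  slit-lamp photographs: convert to CIELAB (sRGB/D65), average `L*`, `a*`,
  `b*` over the iris ROI, normalize each component across the cohort by
  median and IQR, then combine as `IrisColor = −Lₙ + aₙ + bₙ`. Negative
  values are light irises, positive dark, zero indeterminate.
* **Association layer** — Pearson correlations and linear mixed-effects
  models with a per-subject random intercept (fellow eyes are not
  independent), a light/dark group comparison, and the bias summary
  `Δ = mean(light) − mean(dark)` with its relative size in percent of the
  dark-group mean.

Segmentation (median filter + Canny, boundary contours, region geometry) is
built in, but every metric also accepts externally supplied masks, so a
device-specific segmenter can be substituted without touching the metric
code.

## Worked example

Generate a phantom eye with a known 4% planted iris-artefact fraction,
segment it and measure:

```r
library(iridens)

ph <- makePhantom(phantomSpec(artefactFractionIris = 0.04, seed = 11))
masks <- segmentFrame(ph$frame)
masks
#> RegionMasks (155 x 300 px, automatic provenance)
#>   cornea: 7472 px | iris: 1200 px | lateral: 2400 px

analyzeFrame(ph$frame, masks)[, 3:8]
#>   mpiCornea sdCornea threshold pctIris pctLateral pctOverall
#> 1    48.048    2.982    56.994       4          0      1.333
```

The corneal MPI (48.0 a.u.) and SD (3.0) reproduce the phantom's planted
intensity distribution, the threshold is exactly `MPI + 3·SD`, and the
measured 4% iris artefact load equals the planted fraction.

A full synthetic cohort (47 subjects, 91 eyes, planted light-minus-dark CD
difference of 3.1 a.u.) through the statistics layer:

```r
co <- makeCohort(cohortSpec(seed = 42))
g <- compareGroups(co$table)
g$table[g$table$outcome == "cd", ]
#>   outcome meanLight sdLight meanDark sdDark       p
#> 1      cd    49.428   3.448   46.821  3.631 0.00024

c(deltaCd = g$deltaCd, relativeBias = g$relativeBias)
#>      deltaCd relativeBias
#>         2.61         5.57

fitLmm(co$table, "cd", "irisColor")[c("beta", "pBeta", "r")]
#> $beta  -0.751   $pBeta  0.00062   $r  -0.338
```

This seed recovers the planted 3.1 a.u. difference as 2.61 a.u. (within two
pooled standard errors), and CD falls significantly with increasing iris
pigmentation — darker irises, less reflected glare, lower measured CD. With
the reference group means of 50.3 and 47.2 a.u., the bias arithmetic gives

```r
biasSummary(50.3, 47.2)
#> $delta 3.1      # a.u.
#> $relative 6.57  # % overestimation relative to dark irises
```

A thin command-line front end covering segmentation, densitometry, iris
scoring, statistics and cohort simulation lives in
`inst/scripts/iridens.R`.

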