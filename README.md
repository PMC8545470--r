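# nacremeso

Quantifies **mesoscale order in nacre** (mother-of-pearl) from
cross-sectional micrographs and tablet-thickness profiles. Nacre is built
from aragonite tablets a few hundred nanometers thick separated by dark
organic sheaths; reading the sheath positions along the growth direction
turns a micrograph into an ordered sequence of layer spacings, and that
sequence carries the signature of how the animal keeps its layering
periodic. `nacremeso` is written for researchers in biomineralization and
for anyone benchmarking layered-material order metrics.

What it measures:

* **Sheath detection** — interlamellar sheaths as prominence-filtered
  intensity minima along transects perpendicular to the layering
  (structure-tensor auto-orientation, sub-pixel refinement), thickness
  profiles w_N = x_{N+1} − x_N, merged-layer flagging, thickness maps.
* **Pair correlation & paracrystallinity** — 1D pair-correlation function
  g(x) normalized by 1/(k·bw); joint Gaussian peak fits; broadening
  exponent β of σ_n = σ₁·n^β (β = ½ is an ideal paracrystal, where every
  spacing error displaces all subsequent layers); correlation length as the
  order where the pair-correlation envelope e^(−2π²σ₁²n/d²) drops below 10%
  of the first peak.
* **Corrective growth** — deviations from the rolling mean of three,
  dev_N = (2w_N − w_{N−1} − w_{N+1})/3, and the lag-1 Pearson correlation of
  adjacent deviations (analytically −2/3 even for independent thicknesses —
  the package reports a bias-aware companion estimator alongside).
* **1/f^α growth fluctuations** — 10-segment Bartlett PSD of the thickness
  series in cycles/tablet, log–log power-law fit over 0.0004–0.04
  (25–2,500 tablets), and high-frequency flattening/rise detection.
* **Angular order** — azimuthal half-width of the first-order ring in the
  2D FFT (early nacre ≈ ±15°, mature ≈ ±5°).
* **Topological defects** — screw-dislocation density as count/area with
  Poisson errors.
* **Synthetic nacre** — a generator with exact per-interface ground truth:
  AR(1) corrective stacking plus f^−1.5 environmental modulation, faceted
  or smooth interface roughness, BSE-like rendering (bright tablets, dark
  sheaths, blur, noise), and screw-dislocation insertion. Every estimator
  in the package is validated against it.

## Worked example

```r
library(nacremeso)

# simulate a mature-stage pearl fragment and analyze it end to end
report <- run_pipeline(pipeline_config(
  input = list(type = "simulate", stage = "mature", n_layers = 100),
  seed = 4))
report
#> <analysis_report>
#>   layers: 100 (mean 337.6 nm, SD 115.9 nm)
#>   adjacent-deviation correlation r = -0.859
#>   paracrystal: sigma1 = 252 nm, beta = -1.07 (crystal-like)
#>   spectral alpha = NA (high-f: rising)
#>   angular half-width = 8.68 deg
```

The detected mean and SD recover the generator's mature-stage statistics
(340 ± 120 nm). The adjacent-deviation correlation is strongly negative —
note that −2/3 of it is detrending bias (see the methods vignette). The
spectral exponent is not computed because 100 layers cannot resolve the
25–2,500-tablet band; on a ≥ 2,500-layer profile the same call reports α.

A full-pearl-scale run and the headline numbers it prints:

```r
prof <- make_thickness_profile(preset_growth("full_pearl", seed = 51))
s    <- render_transect(prof, render_spec(), seed = 52)      # 3 nm/px
iset <- detect_sheaths(s$transect)
nrow(iset) - 1                                    # 2615  (layer count, exact)
growth_rate(2615, 548, 340)$tablets_per_day       # 4.771898  tablets/day
growth_rate(2615, 548, 340)$microns_per_day       # 1.622445  um/day

set.seed(61)                                      # ideal paracrystal check
w  <- pmax(rnorm(1e5, 340, 30), 50)               # sigma1/d = 0.088
pc <- pair_correlation(c(0, cumsum(w)), bw = 340 / 40)
broadening_curve(fit_peaks(pc, n_max = 9))$beta   # 0.497  (ideal: 0.5)
correlation_length(pc)$layers                     # 16     (envelope < 10%)
```

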