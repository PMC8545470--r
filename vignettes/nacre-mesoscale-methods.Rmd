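---
title: "Quantifying mesoscale order in nacre: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mesoscale order in nacre: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Nacre — mother-of-pearl — is a layered composite of aragonite tablets a few
hundred nanometers thick, separated by thin (~10–20 nm) organic
interlamellar sheaths. In backscattered-electron SEM cross-sections the
mineral tablets are bright and the sheaths dark, so the stacking sequence
can be read off as the positions of intensity minima along a line
perpendicular to the layering. `nacremeso` turns that reading into a set of
quantitative order parameters: tablet-thickness statistics, the 1D
pair-correlation function and a paracrystal assessment, the
corrective-growth (adjacent-tablet) correlation, the spectral exponent of
long-range thickness fluctuations, the angular spread of interface
orientations, and topological-defect densities. Because real pearl
micrographs are not distributable, the package also ships a synthetic nacre
generator with exact per-interface ground truth, and every estimator is
validated against it.

## The synthetic growth model

`make_thickness_profile()` draws tablet thicknesses from

$$ w_N \;=\; \max\!\big(\bar d + e_N + c_N,\ \mathrm{floor}\big), $$

where

* $c_N = \phi\, c_{N-1} + \epsilon_N$ is a first-order autoregressive
  *corrective growth* term ($\epsilon_N$ i.i.d. Gaussian with SD
  `sigma_local`). Negative $\phi$ encodes the compensation seen in nacre: a
  tablet grown too thick tends to be followed by a thinner one. The default
  presets use $\phi = -0.4$.
* $e_N$ is a long-range *environmental modulation*: a zero-mean Gaussian
  sequence synthesized in the frequency domain with amplitudes
  $\propto f^{-\alpha_{env}/2}$ and uniform random phases
  (`powerlaw_noise()`), rescaled to an exact RMS `sigma_env`. The default
  exponent is $\alpha_{env} = 1.5$, the value mature nacre shows over the
  low-to-mid frequency band. Deterministic amplitudes mean the realized
  spectrum follows the target power law exactly in expectation, and exact
  RMS scaling removes seed-to-seed variance from delivered thickness SDs.
* the floor (default 50 nm) prevents non-physical near-zero tablets.
  Clipping, rather than resampling, preserves the spectral shape of the
  sequence; clip events are counted in the `n_clipped` attribute.

This stacking is *cumulative*: interface position is the running sum of
thicknesses, so with white disorder the variance of the N-th interface
position grows linearly in N — the defining property of a paracrystal.

**Stage presets.** Nacre matures: early nacre runs around 500 ± 300 nm and
±15° of interface-orientation spread, mature nacre around 340 ± 120 nm and
±5°. `preset_growth()` encodes these two stages (plus `"full_pearl"`, a
2,615-layer mature-statistics stack). Because the generator clips at the
floor, a preset parameterized naively at (500, 300) would *deliver* roughly
(509, 283). The preset constructor therefore solves the closed-form
clipped-normal moment equations for pre-clip parameters such that the
delivered distribution matches the stage statistics exactly. The noise
budget is split with about 1/6 of the variance in the environmental term and
the rest in the corrective AR term; this keeps the delivered SD stable
across seeds while still producing both spectral regimes (power-law decay at
low frequency from $e_N$, a rising high-frequency branch from $\phi < 0$).

Note one deliberate consequence of this model: a mature-preset profile has
white-dominated thickness SD of 120 nm, which corresponds to a
*positional* disorder of σ₁/d ≈ 0.35 — far more stacking disorder than real
mature nacre shows in its pair-correlation function (σ₁/d ≈ 0.09). Real
nacre evidently accumulates much of its thickness variance in slowly varying
components that do not destroy local lattice coherence. Tests of the
pair-correlation machinery therefore use dedicated cumulative-paracrystal
sequences at the documented σ₁/d, not the stage presets.

## Rendering and the interface field

`make_interface_field()` stacks interfaces cumulatively and adds a
transverse displacement field per interface,
$u_{i+1} = a\,u_i + \sqrt{1-a^2}\,v_i$, with $a$ the layer-to-layer
carry-over ("bumps and valleys attenuate into subsequent layers") and $v_i$
fresh lateral noise. Two roughness models are available:

* `"smooth"`: Gaussian random field of correlation length
  `roughness_corr_length`;
* `"faceted"`: piecewise-linear facets of that length with i.i.d. Gaussian
  slopes — the flat-tablet picture, orientation changing at tablet
  boundaries.

In both, the common amplitude is calibrated per realization so that the
slope-angle distribution $\arctan(du/dx)$ has exactly the requested
half-width at half maximum (defined throughout as $\sqrt{2\ln 2}$ times the
SD). Displacements are clipped so spacing never falls below the floor.

`render_micrograph()` draws each sheath as a Gaussian intensity dip of full
width `sheath_width` (15 nm default) centered on the interface, on a bright
tablet background (0.8 vs 0.2 intensity), then applies Gaussian blur (2 px)
and additive noise (SD 0.06, i.e. 10% of the contrast). In a noise-free
render the intensity minima sit exactly on the sheath centerlines, which is
what makes detection-oracle tests exact. `render_transect()` is the 1D
equivalent for full-pearl-scale profiles, where a 2D image at 3 nm/px would
be hundreds of megapixels for no benefit.

**Dislocations.** `insert_dislocations()` adds screw-dislocation-like
defects: a partial organic boundary that terminates at a point inside a host
tablet, with the host locally thinned by `thinning_fraction` (default 0.28,
the documented ~28% thickness change at defects) under a Gaussian envelope;
the displaced thickness is absorbed by the layer above so long-range
stacking is preserved. Placement offers an exact-count mode
(`round(density × area)`, deterministic for tests) and a Poisson mode.

## Detection

`detect_sheaths()` smooths the transect (Gaussian, SD
`max(1 px, sheath_width/2/pixel)`), finds local minima, computes each
minimum's topographic prominence, keeps those above `min_prominence`, and
refines positions with a three-point parabola (sub-pixel precision, ~0.5 nm
RMS at 3 nm/px on clean renders). The default threshold is 25% of the
robust tablet–sheath contrast, where the sheath level is the median
intensity of the deepest minima (a first pass at half the maximum
prominence) read off a lightly smoothed profile. On very long transects the
extreme-value tail of smoothed noise can reach a quarter of the contrast,
so the default also enforces a noise floor of 8× the robust noise SD
(MAD of the smoothed profile against its running median). With both rules
the full-pearl layer count (2,615) is reproduced exactly across seeds, and
recall stays ≥ 0.99 up to noise at 15% of contrast.

Thicknesses are first differences of interface positions
(`thickness_from_interfaces()`), indexed 1-based in growth order (pearl
center → edge). `flag_merged_layers()` flags apparent double layers
(missed sheaths) exceeding 1.8× the rolling median (window 11); flagged
layers are excluded from pair-correlation input and break deviation series
into independent segments. On heavy-tailed profiles (mature preset,
CV ≈ 0.35) this threshold also catches ~2% of genuinely thick tablets —
acceptable for its purpose of guarding the pair-correlation function, but
the reason stage statistics are computed on unflagged, raw measured
profiles. `build_thickness_map()` repeats detection across many transects
and aligns layers by nearest-interface matching, masking unmatched cells and
warning when more than 20% fail to match.

## Pair correlation and the paracrystal assessment

`pair_correlation()` histograms all ordered pairwise separations of
interface positions up to `x_max` (default 30 mean spacings) with bin width
`bw` (default d/20), normalized by $1/(k\,bw)$ with $k$ the number of
positions; the sum $\sum g\,bw\,k$ equals the number of pairs in the window
exactly. Pairs are only formed within a transect (and within unflagged
segments), never across.

`fit_peaks()` fits a constant baseline plus one Gaussian per neighbor order
jointly by Levenberg–Marquardt with box constraints. Two details matter for
correctness in the overlapped regime:

* *Guard orders.* The apparently flat plateau of g(x) at large separation
  **is** the overlap of high-order peaks. The fit therefore includes
  Gaussians for every order reaching into the window, even though only
  `n_max` are reported; with only the reported orders plus a constant the
  least-squares problem is mis-specified and widths come out up to 2× low.
* *Mass-consistent initialization.* Every order carries the same integrated
  pair mass as the resolved first peak, so heights are initialized at
  $A_1/(\sqrt{2\pi}\sigma_n^{(0)})$ with $\sigma_n^{(0)} = \sigma_1\sqrt n$.
  Height-from-histogram initialization occasionally stranded the optimizer
  in an under-filled local minimum.

With 10⁵-layer cumulative-paracrystal input the fitted widths reproduce
$\sigma_n = \sigma_1\sqrt n$ to a broadening exponent β = 0.50 ± 0.01.
`broadening_curve()` reports β from a log–log fit (crystal-like below 0.15,
ideal-paracrystal above 0.4, intermediate between; thresholds configurable).

**Correlation length.** The criterion is the neighbor order at which the
pair-correlation envelope falls below 10% of the first peak. For cumulative
disorder the envelope decays as $\exp(-2\pi^2\sigma_1^2 n/d^2)$ — the
amplitude of the fundamental lattice harmonic — while the raw *height* of
the first peak is a tall narrow Gaussian that does not sit on that envelope.
Ratios of raw heights would therefore cross 10% several orders too early.
`correlation_length()` instead measures, fit-free, the magnitude of the
windowed first lattice harmonic of g(x) around each order; for a narrow
peak this equals the harmonic envelope exactly, and in the overlapped
regime it reads off the local oscillation amplitude. At σ₁/d = 0.088 the
estimator reports loss of translational order at 16 ± 1 layers, matching the
closed-form envelope (and, at d = 340 nm, about 5.4–5.5 µm). A literal
`mode = "height"` is provided for comparison. First crossing wins; if the
envelope never crosses within the window, the result is censored
("exceeds window").

## Corrective-growth statistics

Following the thickness-deviation construction, the deviation of tablet N
is its thickness minus the centered rolling mean of width three *including
itself*: $dev_N = (2w_N - w_{N-1} - w_{N+1})/3$. `adjacent_correlation()`
reports the Pearson correlation of $(dev_N, dev_{N+1})$ with slope, R² and a
t-test p-value.

An important caveat that the package surfaces rather than hides: because
the detrend includes the tablet itself, *independent* thicknesses already
give $corr(dev_N, dev_{N+1}) = -2/3 \approx -0.67$ analytically —
numerically indistinguishable from the −0.66 measured on real nacre by the
same construction. The estimator is faithfully implemented (and its −2/3
behavior is an acceptance check), but on its own it cannot distinguish
corrective growth from white noise. `lag1_autocorrelation()` is the
bias-aware companion: a long-wavelength high-pass (rolling mean, 25
tablets) followed by the direct lag-1 autocorrelation, whose bias under
independence is of order −1/25. Under the generator, the deviation
correlation is monotone in $\phi$, so the pair of estimators together does
carry information about the corrective mechanism. No biological claim is
attached to either.

`stage_statistics()` summarizes windows (mean, SD, and first-vs-last mean
and variance ratios); `growth_rate()` is the layers-per-lifetime
arithmetic: 2,615 layers over 548 days gives 4.77 tablets/day, about
1.6 µm/day at 340 nm per tablet.

## Spectral analysis

`psd_profile()` implements Bartlett averaging: the chronological thickness
series is split into `n_segments` (default 10) contiguous equal segments,
each mean-subtracted, and one-sided periodograms are averaged. No taper is
applied by default (a Hann option exists); frequency is in cycles per
tablet and power is a density, so the spectrum integrates to the segment
variance (checked to 1% by a Parseval test). `fit_powerlaw()` fits
log10-power against log10-frequency over 0.0004–0.04 cycles/tablet (25 to
2,500 tablets). The lower bound requires segments of ≥ 2,500 tablets; for
shorter segments it is raised to 4/segment-length (skipping the most
leakage-biased bins) with a message. Exponent recovery is unbiased within
±0.1 for α ∈ {0.5, 1.0, 1.5, 2.0} at n = 25,000. `detect_flattening()`
reports the log–log slope above 0.04 with a sign classification
(|slope| < 0.15 counts as flat): anticorrective AR growth produces the
characteristic high-frequency rise, verified against the closed-form AR(1)
spectrum $\sigma^2/(1+\phi^2-2\phi\cos 2\pi f)$.

## Angular order

`angular_spread()` takes the 2D FFT (Hann-windowed) of one or more fields
of view, integrates power over an annulus at the first-order layering
frequency (radius 1/d, half-width ±30% — wide enough to capture the
broadened first order while excluding the DC cross), bins it by azimuth
(0.5° bins, folded to 180°), and reports a half-width at half maximum.

Two design choices came out of co-calibrating this estimator against the
generator, and both are recorded in every output's `criterion` field:

* *Faceted orientation fields.* For a smoothly curving phase field the
  spectrum only approaches the slope-angle distribution in the
  large-modulation (FM) limit; at realistic amplitudes the measured width
  was roughly half the true spread. Real tablets are flat facets whose
  orientation changes at boundaries, and a faceted field makes the
  measurement exact: each facet is a straight tilted grating diffracting at
  its own tilt. Angular fixtures therefore use
  `roughness_model = "faceted"` with 10 µm facets and near-conformal
  carry-over (a = 0.999), at 24 nm/px — the azimuthal kernel scales with
  spacing/facet-length and is independent of pixel size, and the flat-layer
  reference reads 0.27°.
* *Moment-based HWHM.* With tens of coherent facets the azimuthal profile
  is speckled; a Gaussian + baseline fit underestimated widths by ~35%. The
  reported half-width is instead $\sqrt{2\ln 2}$ × the power-weighted
  azimuthal SD after background subtraction (median power far from the
  peak) and iterative ±3 SD trimming — the HWHM of the matching Gaussian,
  robust to lumpiness.

`simulate_angular_views()` freezes the fixture geometry: by default two
independent fields of 24 tiles × 1024 px each, 150 layers; the realized
slope-angle half-width of the generated field is returned as ground truth.
With these settings the early (15°) and mature (5°) presets are recovered
within about ±1° across seeds, and strictly ordered.

## Defects

`defect_density()` is deliberately exact arithmetic — count divided by
area, with the Poisson standard error $\sqrt{\text{count}}/\text{area}$,
reported per view (plan / cross-section). Automated defect detection from
raw images is out of scope; centers come from synthetic truth
(`defect_centers()`, exact-count or Poisson) or manual annotation CSVs.

## Pipeline, units, determinism

`run_pipeline()` composes the stages (detect → growth statistics → pair
correlation → spectral → angular/defects) over simulated, image, or
profile-CSV input; image-dependent results are marked not-computed for
profile input, the spectral power-law fit is skipped for profiles whose
segments cannot resolve the band, and simulated stacks above 500 layers are
rendered as 1D transects. Units are fixed package-wide: nm for lengths,
degrees for angles, m⁻² for densities, cycles/tablet for frequency.
Every stochastic function takes an explicit seed, restores the caller's RNG
state, and identical (config, seed) gives bit-identical output — including
rendered images.

## Problem sizes and limitations

The validation suite uses: 10⁵-layer sequences for closed-form statistics
(deviation correlation, paracrystal broadening, correlation length);
25,000-tablet profiles for spectral-exponent recovery (ten 2,500-tablet
segments resolve the full fit band); 2,000-layer mature renders at 3 nm/px
for detection statistics; the exact 2,615-layer stack for layer-count
fidelity; and two 24-tile fields per stage for angular order. These sizes
were chosen so each check's Monte-Carlo error is several times smaller than
its tolerance.

Known limitations, stated plainly:

* The generative model is an artifact choice: nacre growth is surely not an
  AR(1) plus spectrally synthesized modulation. The model is validated only
  in that it reproduces the documented summary statistics; conclusions
  about real nacre should come from applying the estimators to real
  micrographs.
* As noted above, stage presets place thickness variance in components that
  destroy positional coherence faster than real nacre does; preset-based
  pair-correlation output is honest but shows short correlation lengths.
* The histogram construction of the pair-correlation function from complete
  transects is equivalent whether one histograms pairwise separations or
  cumulative thickness sums; the pairwise-separation construction is
  implemented, and the equivalence breaks only for gapped (flagged)
  profiles, where pairs never span a gap.
* The angular criterion is one of several possible readings of "±15°"; it
  is co-calibrated with the generator and recorded in outputs, but
  comparisons against other software should compare criteria first.
* No tablet lateral-boundary segmentation, no mineral-bridge detection, no
  3D rendering, and no attribution of spectral features to specific
  biological clocks.
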