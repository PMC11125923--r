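---
title: "Methods: canopy-coverage inversion and swarm-based crop-model assimilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy-coverage inversion and swarm-based crop-model assimilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aquapso` implements a complete desk-scale version of a common
remote-sensing / crop-modelling workflow for perennial row crops such as
tea: estimate canopy coverage (CC, the percentage of ground covered by
canopy) from multispectral imagery, learn a regression from vegetation
indices to coverage, and use the inverted coverage series to recalibrate a
water-driven crop model by particle swarm optimization (PSO). Because raw
field scenes for this kind of study are rarely shareable, the package
treats the synthetic-data generators as first-class components: every
stage can be exercised against known ground truth.

This vignette records the model equations, the tunable parameters and
their defaults, the numerical conventions, and the design decisions made
where the methodology left genuine choices open.

## 1. Coverage extraction from imagery

A scene is a stack of co-registered reflectance rasters (blue, green,
red, red edge, NIR; unitless reflectance in [0, 1]) with a validity mask.
Extraction uses the red band, where chlorophyll absorption makes canopy
pixels dark against bright soil:

1. quantize reflectance to 8-bit gray, `g = round(255 r)`;
2. build the 256-bin gray histogram of valid pixels;
3. find the Otsu threshold `t` maximizing the between-class variance
   `w0 w1 (mu0 - mu1)^2` of the split into levels `<= t` and `> t`;
4. remove the bright (soil) class;
5. report `CC = 100 * canopy pixels / valid pixels`.

Numerical conventions, chosen for determinism:

* **Quantization** is linear with round-half-up; bit depth is not part of
  the procedure's definition, and 8-bit matches standard gray histograms.
* **Otsu ties** are broken toward the smallest optimal threshold. The
  implementation uses cumulative moments in one pass; the test suite
  checks it against an exhaustive 256-candidate scan on randomized
  histograms.
* **Which class is canopy** is a polarity switch. The default
  `canopy_below` reflects red-band physics (vegetation dark). Because the
  Otsu value is the top level *of* the dark class, `extract_coverage()`
  cuts at `t + 1`, so a noiseless two-level scene is segmented exactly.
* **The coverage denominator** is valid (in-plot, non-nodata) pixels, not
  the full frame, since frames are cropped to the study plot.

## 2. Vegetation indices and inversion

Ten standard indices are computed pixelwise from the band stack (NDVI,
NDRE, WDRVI, MSR, GNDVI, RVI, LCI, OSAVI, SAVI, EVI, with WDRVI's
weighting coefficient fixed at 0.1 and OSAVI's soil-adjustment constant
at 0.16). Pixels with a zero or non-finite denominator are marked invalid
rather than being substituted, so plot means are always means of defined
values. Plot-level predictors are arithmetic means over a mask; an
optional brightness-percentile filter (off by default) can drop the
darkest canopy pixels as a crude shadow screen — it is an extension, not
part of the core procedure.

Indices are screened by Pearson correlation with measured coverage
(default threshold |r| >= 0.8, the conventional "highly correlated"
band), then four single-index regression families are fit:

| family | model | estimator |
|---|---|---|
| linear | y = a + b x | OLS |
| logarithmic | y = a + b ln x | OLS on ln x |
| exponential | y = a e^(bx) | OLS of ln y on x |
| power | y = a x^b | OLS of ln y on ln x |

Exponential and power families are fit by **log-linearization** because
it is deterministic and closed-form; an `nls_refine` flag exists for
iterative polishing but is off by default. Domain constraints (positive
x for log/power, positive y for exp/power) are enforced as errors, not
silently patched.

The multi-index model is **PLS1 via NIPALS** on centered/scaled
predictors, with final coefficients back-transformed so prediction is a
plain affine map `CC = intercept + sum(coef * index)`. At full components
PLS1 coincides with ordinary least squares, which the tests exploit as an
independent oracle. The component count is chosen by leave-one-out
cross-validated RMSEP, selecting the **first local minimum** — the
smallest count after which RMSEP stops decreasing. LOO was chosen over
k-fold because sample tables in this workflow are small and LOO removes
the fold-assignment degree of freedom.

Model quality is reported as `RMSE = sqrt(mean((S - M)^2))` and the
standard coefficient of determination `R2 = 1 - SS_res/SS_tot`. A
variance-ratio statistic `sum((M - Mbar)^2)/sum((S - Mbar)^2)` is also
emitted as `r2_ratio` because it circulates in parts of the applied
literature as if it were R squared; it is not bounded by 1 and is never
used for decisions here. Predictions are reported unclipped by default
(regression output as-is), with an optional clip to [0, 100].

## 3. The crop simulator

The simulator is a self-contained daily-step canopy / soil-water /
biomass model in the AquaCrop tradition — written from scratch for this
package, not FAO's code. It is driven by nine crop parameters
(`crop_params()`), reference bounds in `default_param_bounds()`:

| parameter | default | range | meaning |
|---|---|---|---|
| cc_ini | 60 | 57–63 | initial canopy coverage, % |
| den | 5000 | 4750–5250 | plant density, plants/ha |
| mcc | 70 | 66–74 | maximum canopy coverage, % |
| wp | 12 | 11.4–12.6 | water productivity (biomass per unit Tr/ET0) |
| hi | 5 | 4.75–5.25 | harvest index, % |
| kcb | 0.8 | 0.76–0.84 | basal transpiration coefficient |
| tmg | 7 | 6.65–7.35 | minimum growth temperature, deg C |
| tupper | 30 | 28.5–31.5 | upper thermal-time threshold, deg C |
| tbase | 7 | 6.65–7.35 | base temperature, deg C |

**Thermal time.** `GDD = max(0, min(Tmean, tupper) - tbase)` with
`Tmean = (Tmin + Tmax)/2`.

**Canopy development.** Coverage follows the canonical
exponential-growth / exponential-decay form in *gated* thermal time `t`:
exponential growth `CC = CC0 exp(CGC t)` while `CC < mcc/2`, then
`CC = mcc - (mcc - mcc/2) exp(-CGC (t - t*))`, joining continuously at
`t* = ln(mcc/(2 CC0))/CGC`. For an established perennial canopy with
`CC0 >= mcc/2` — the tea case, where default initial coverage (60%)
already exceeds half the maximum (35%) — development starts directly in
the decay branch as `CC = mcc - (mcc - CC0) exp(-CGC t)`, so `CC(0) =
CC0` exactly. This continuity construction is mathematically identical to
the textbook decay expression whenever `CC0 < mcc/2` and avoids a
spurious jump at day one otherwise. The effective initial coverage is
`CC0 = cc_ini * den / 5000`: density enters as a multiplicative scaling
around the reference planting density, the simplest coupling consistent
with the parameter set. Expansion is gated multiplicatively: the thermal
clock does not advance on days with `Tmean < tmg` (interpreting `tmg` as
the minimum air temperature for canopy growth) or when the water-stress
coefficient `Ks < 1`. The canopy growth coefficient `CGC` (default 0.003
per GDD, configuration constant, not assimilated) was set once so that a
60%-cover canopy approaches its 70% maximum within roughly one growing
season of the default climate.

**Soil water.** A tipping-bucket profile (default 4 layers x 0.25 m,
field capacity 0.30, wilting point 0.12, saturation 0.45 m3/m3).
Each day: surface water beyond a daily infiltration cap (50 mm) runs
off; infiltration fills layers to field capacity top-down; the remainder
leaves the bottom layer as deep percolation; soil evaporation
`(1 - CC/100) Ke ET0` (Ke = 1.1) is drawn from the top layer and crop
transpiration `Ks kcb (CC/100) ET0` from all layers proportionally to
available water. Extraction never draws a layer below wilting point —
excess demand is scaled down, never creating negative storage. The daily
ledger closes identically:
`delta storage = precipitation - runoff - percolation - Es - Tr`,
asserted to 1e-9 mm in the tests (observed residuals are at machine
precision, ~1e-13 mm). When stress is enabled, `Ks` falls linearly from 1
to 0 as root-zone depletion grows from 50% of total available water to
100%.

**Biomass and yield.** `B = wp * sum(Tr/ET0)` over days with positive
ET0, `Y = (hi/100) B`. Units of wp/hi are treated as consistent internal
units, so yields are compared *relatively*, never absolutely. The
classical linear yield-response-to-water relation
`1 - Ky (ET_pot - ET_act)/ET_pot` is exposed separately as
`yield_response()`; it equals 1 exactly when actual equals potential
evapotranspiration.

By default the simulator runs **unstressed** (`water_limited = FALSE`,
or `soil = NULL` to skip the ledger entirely): whether the original
workflow used stress functions is unknowable, so stress is optional and
off in the reference scenario.

## 4. PSO assimilation

The swarm searches the nine-dimensional box of `default_param_bounds()`.
Updates follow the standard rules
`v <- omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, `x <- x + v`,
with fresh `r1, r2 ~ U[0,1]` per particle and dimension, and pbest/gbest
maintained as fitness argmins — so the global best fitness is non-increasing
by construction, a property the tests assert for every seed.

Choices the methodology left open, fixed here as:

* **Coefficients** omega = 0.72, c1 = c2 = 1.49 (standard constriction
  values), all configurable; the swarm defaults are 60 particles and a
  fixed 40-iteration budget (no early stop; an optional plateau stop
  exists).
* **Boundary handling**: positions are clipped to the box and the
  velocity zeroed on the clipped coordinate; velocities are clamped to
  the coordinate range width. Both are unglamorous but deterministic and
  stable.
* **Scales**: parameters are optimized on their natural scales; the
  bounds are all roughly +/-5% of the defaults, which keeps coordinates
  comparable without normalization. (The sphere benchmark in the tests
  *is* normalized, because the raw scales span three orders of
  magnitude.)
* **Cost function**: the signed mean relative difference
  `mean((CC_s - CC_r)/CC_s)` is reported as `signed_mre`, but it is not
  the default objective — positive and negative errors cancel, and a
  minimizer can drive it unboundedly negative. The default objective is
  its absolute counterpart `mare = mean(|CC_s - CC_r|/CC_s)`; an RMSE
  variant is also selectable. All three agree that a perfect match scores
  zero.

Each fitness evaluation runs the full simulator at the particle's
parameters and scores the simulated coverage at the observation days; a
simulator failure penalizes that particle with infinite fitness without
stopping the run.

Not all nine parameters are identifiable from coverage alone: `wp`, `hi`
and `kcb` do not influence the canopy trajectory (they act downstream on
biomass and yield), and `cc_ini` and `den` enter only through their
product. The planted-optimum experiments therefore assess recovery of the
*trajectory* (and of identifiable quantities such as `mcc`), not of every
coordinate; assimilated yield inherits the spread of the unidentifiable
parameters across their (narrow) bounds.

## 5. What the synthetic generators emulate — and what they do not

* `make_scene()` renders striped row-crop scenes: two spectral
  populations (healthy canopy: red ~0.04, NIR ~0.50; bare soil: red
  ~0.22, NIR ~0.32) with truncated Gaussian pixel noise (default sd 0.02
  reflectance). Stripes follow the planted-row geometry; the canopy
  column count is chosen so realized coverage is within one column
  quantum of the target, and the truth bundle records the exact mask.
  The two-population construction preserves the gray-histogram
  bimodality that makes Otsu segmentation meaningful. It does **not**
  emulate shadows, mixed border pixels, BRDF or atmospheric effects, or
  georeferencing — so passing tests show algorithmic correctness, not
  field-scale radiometric robustness.
* `make_weather()` produces sinusoidal seasonal temperature and ET0
  cycles with Gaussian noise and summer-concentrated stochastic rain,
  defaults set to a humid subtropical tea-growing climate (summer mean
  ~26 deg C, winter ~3 deg C). It does not model multi-day weather
  persistence or extremes.
* `make_vi_cc_dataset()` draws index/coverage samples from a known truth
  model plus Gaussian noise clipped to [0, 100]; multi-index truths mix a
  shared latent greenness with independent components so predictors are
  realistically correlated. Additive Gaussian observation noise is an
  assumption — no observation-error model was prescribed.
* `make_observations()` samples a simulated trajectory at chosen days
  with Gaussian noise clipped to [0, mcc], standing in for an inverted
  coverage series with known truth.

Sampling designs (how many plots and dates feed a regression) are
generator defaults documented here — twelve monthly acquisitions over one
season in the reference pipeline — and are not inferred from any field
protocol.

## 6. Reference problem sizes

The shipped test-and-acceptance scenario uses 64 x 64-pixel scenes,
365-day weather series, 12 monthly observations, 100–200-row sample
tables, and the full 60-particle x 40-iteration swarm (10 seeds for the
planted-optimum experiment; smaller swarms in unit tests). These sizes
were chosen so the complete synthetic study is reproducible on a laptop
in about a minute while leaving every algorithmic path exercised at its
reference settings.

## 7. Known limitations

* The simulator is a deliberately compact reimplementation: no
  senescence phase, no root growth, no temperature or aeration stress on
  biomass, single crop cycle. It is adequate for studying the
  assimilation machinery, not for agronomic forecasting.
* Yield is in consistent internal units; only relative yield comparisons
  are meaningful.
* The literal signed relative-difference cost and the variance-ratio
  `r2_ratio` are provided for comparability but are statistically fragile;
  the defaults (`mare`, standard R squared) should be used for any real
  decision.
* PSO is a stochastic optimizer; all shipped experiments fix seeds, and
  the parameter-recovery guarantees are medians over seeds, not
  per-run bounds.
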