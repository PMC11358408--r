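---
title: "Ranking optical and fluorescence proxies of leaf water status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking optical and fluorescence proxies of leaf water status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drydown)
```

## The problem

When a detached leaf dries, dozens of non-destructive measurements change
with it: reflectance-derived water indices, vegetation indices, relative
chlorophyll content, chlorophyll-fluorescence parameters, water
potentials. Which of them actually *tracks* leaf water status — and which
merely wiggles? `drydown` answers this with a coefficient framework that
scores every monitored parameter against relative water content (RWC),
the fraction of the fully turgid water content a leaf retains.

The practical currency of the package is the tidy series: one monitored
parameter observed as `(RWC, value)` points across leaf samples, each
point one leaf.

## Water status quantities

RWC is rarely measured directly during monitoring because the direct
route, `RWC = (m_a - m_d) * 100 / (m_t - m_d)`, is destructive (it needs
the dry mass `m_d` and the fully turgid mass `m_t`). Instead the
non-destructive leaf mass decrease, `LMD = (m_f - m_a) * 100 / m_f`, is
recorded and converted to RWC through a species-specific linear
calibration fitted once in a destructive side experiment. The package
ships two such calibrations (tobacco whole leaves:
`RWC = -1.1085 * LMD + 100.37`; barley segments:
`RWC = -1.0986 * LMD + 98.221`) and can fit new ones by ordinary least
squares with a free intercept — the free intercept matters, because a
fresh detached leaf is typically slightly below full turgor, so the
calibrated RWC at zero mass loss need not be 100.

Calibrated RWC is deliberately **not clamped** to [0, 100]: the tobacco
intercept above 100 would otherwise silently distort the top of the
evaluation window. Out-of-range values are kept and flagged with a
warning.

Equivalent water thickness, `EWT = (m_a - m_d) / area`, uses the
*actual* (possibly shrunken) leaf area. In strongly shrinking leaves EWT
therefore falls much more slowly than RWC — the mechanism by which leaf
shrinkage mutes the reflectance water indices.

## The reliability coefficients

Over an RWC window (default 100–50%, both ends inclusive; below ~50%
desiccation damage is usually lethal, so method comparison is most
meaningful above it), each parameter series is fitted with an ordinary
least-squares line `y = a + b * RWC`. With the mean absolute residual

$$\overline{\Delta y} = \frac{1}{n}\sum_i |y_i - (a + b\,x_i)|$$

and the series mean $\bar y$, the three coefficients are

$$CR = \frac{|b|\,\Delta s}{\overline{\Delta y}},\qquad
  CS = \frac{100\,|b|}{|\bar y|},\qquad
  CI = \frac{100\,\overline{\Delta y}}{|\bar y|},$$

so that $CR = \Delta s\, CS / CI$ identically. `CR` asks: over a
meaningful RWC step `delta_s` (default 10 percentage points, i.e. 0.1 of
the fractional scale), how large is the parameter's systematic change in
units of its own scatter? A parameter is flagged *reliable* when
`CR >= 0.4` (the default threshold, chosen from the observed range of CR
values across typical parameter batteries; it is a ranking device, not a
significance test — no α-level is attached).

Conventions worth noting, each of which is asserted by the test suite:

* **Absolute values.** `|b|` and `|ȳ|` are used so parameters that rise
  and parameters that fall with RWC rank on one magnitude scale, and so
  negative-valued series (water potentials) get positive CS/CI.
* **Units of RWC.** CR is invariant to expressing RWC in percent or as a
  fraction, provided `delta_s` uses the same units. CS is defined per
  percent RWC, which puts typical values in the order of units.
* **Degenerate cases.** A perfect linear fit leaves only rounding-level
  residuals; scatter below `1e-12` of the data scale is treated as zero
  and reported as `CR = Inf` with a `perfect_fit` flag (such results
  sort first in rankings and are excluded from coefficient–coefficient
  correlations). A constant series has `SStot = 0` and `r2` defined as
  1 in the line fit; in coefficient–coefficient correlation, a constant
  response instead yields `r2 = 0` — there is no variance to explain.
* **Window R².** The reported `r2` is computed on the windowed points,
  the same points the coefficients use.

Ranking is descending (rank 1 = largest coefficient), ties are broken
lexicographically by parameter name and flagged. Group comparison sums
the within-species ranks per parameter group (lower = better) and
averages coefficient values per group.

```{r worked}
x <- c(50, 60, 70, 80, 90, 100)
y <- c(10, 12, 13, 16, 17, 20)
compute_coefficients(x, y, parameter = "demo")
```

## The synthetic desiccation generator

No instrument data are needed to exercise the pipeline:
`simulate_dataset()` builds per-sample tables with internally consistent
masses and parameter values, plus a ground-truth sidecar. What it
emulates:

* **Drying kinetics**: `RWC(t) = floor + (100 - floor) exp(-t/tau)`. An
  exponential was chosen because any monotone curve would serve and the
  exponential has a single interpretable constant; the built-in profiles
  use tau = 48 h (slowly drying whole tobacco-like leaves) versus
  tau = 6 h (fast-drying barley-like segments). These time constants are
  order-of-magnitude choices, not fitted values.
* **Mass consistency**: target RWC values are spread evenly over
  45–100%, mapped to harvest times through the drying curve; LMD is
  inverted from the profile's ground-truth calibration; the turgid mass
  is constructed so the direct (destructive) RWC route reproduces the
  same value. Applying the package's own water-status operations to the
  emitted table therefore recovers the true RWC, which the tests assert.
* **Shrinkage**: fractional area loss grows linearly with `(100 - RWC)`,
  anchored at the profile's loss at RWC 50% (0.30 tobacco-like, 0.08
  barley-like). Relative EWT follows as `(RWC/100)/(1 - shrinkage)`, so
  the strongly shrinking profile keeps its water *concentration* up
  while losing water *content*.
* **Response shapes vs. RWC**: linear, plateau-then-decline
  (`onset_decline`), Gaussian-bump `biphasic` (rise-then-fall, as
  steady-state NPQ shows), `logistic_decline` and `constant`. Biphasic
  responses are Gaussian bumps rather than piecewise lines because they
  are differentiable and controlled by three parameters.
* **Noise**: an additive per-leaf random intercept (`leaf_effect_sd`)
  plus independent measurement noise (`noise_sd`) — a two-component
  model motivated by the visibly leaf-dominated scatter of chlorophyll
  and NDVI measurements on real leaves.
* **Spectra**: `simulate_spectrum()` composes a sigmoidal VIS–NIR edge,
  a chlorophyll absorption trough at 670 nm that deepens with the
  apparent (shrinkage-concentrated) chlorophyll, and Gaussian water
  troughs at 970 nm (weak) and 1450 nm (strong, putting R1000/R1450
  near 3 on a hydrated leaf) whose depths saturate with relative EWT.
  By construction the water indices decrease monotonically with water
  loss, and the strongly shrinking profile shows the smaller WI change.
* **Fluorescence traces**: `simulate_fluorescence_trace()` is the exact
  inverse of `extract_record()` on noiseless input: dark measuring
  flashes at `F0`, an 800-ms dark pulse at `FM`, actinic onset with a
  transient relaxing toward `Fst` (clamped to `Fst` over the final
  steady-state window, the trace's operational definition of "steady"),
  and a 60-s pulse train whose peaks run from `FM'1` to `FM'st`.

The built-in profiles' response-model parameters are **illustrative**:
they reproduce the qualitative contrast between a shrinking and a
non-shrinking species (water indices unreliable in the former, among the
most reliable in the latter; NDVI/SPAD rising under shrinkage), and they
were fixed before any recovery experiment was run. Passing tests on this
generator show that the pipeline recovers what the generator encodes;
they do not show that real leaves behave like the generator — real
spectra have structure (specular effects, vein heterogeneity,
senescence drift in slowly drying leaves) the generator deliberately
omits.

## Numerical and protocol choices

* Band extraction interpolates linearly at the exact nominal wavelength
  (no nearest-sample snapping, no band averaging, no extrapolation):
  instrument grids differ and interpolation is grid-independent.
* Reflectance is stored as a fraction; files with values above 1.5 are
  auto-detected as percent and divided by 100, with a message.
* "Steady state" in trace extraction is operationalized as the final
  30 s before the last saturating pulse (configurable); the "1 min"
  pulse is the one nearest 60 s after actinic onset, tolerance ±10 s.
* Saturating-pulse levels are extracted as the mean of the top three
  in-pulse samples rather than the raw maximum: on a noiseless plateau
  the two coincide, but under noise the raw maximum inherits the upward
  bias of an extreme order statistic, which would bias every NPQ value
  derived from it.
* `F0` is the mean of all dark measuring-flash samples before the first
  pulse; negative NPQ values are reported with a warning, never clipped.
* SPAD and the water potentials are *inputs* (externally measured
  parameter columns), never derived from spectra: the SPAD instrument's
  internal formula is proprietary, and water-potential physics is out of
  scope.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data at desk scale: 1,000 randomized series for the CR = Δs·CS/CI
identity, n = 10,000 points for the Gaussian mean-absolute-deviation
law (where `dy_bar` converges to σ·√(2/π)), 100 replicates of a
four-parameter battery at n = 40 points per parameter for ranking
recovery (theoretical CR ratio 2 between neighbours, within the
framework's separability regime of ratios ≥ 1.5), and 40 samples per
species for the end-to-end pipeline run. These sizes were chosen as the
smallest at which the asymptotic laws the framework relies on are
visibly in force.

## Known limitations

* The CR threshold is a heuristic ranking device; formal significance
  calibration is explicitly out of scope.
* Repeated-measures series (the same leaf measured over time) are
  accepted but violate the one-leaf-one-point independence the scatter
  statistic assumes; treat their coefficients as descriptive.
* The generator does not model senescence, radiative transfer, or
  per-pixel heterogeneity; conclusions about real instruments require
  real data.
* `CS` and `CI` are undefined for series with zero mean; such results
  are flagged and excluded from correlations.
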