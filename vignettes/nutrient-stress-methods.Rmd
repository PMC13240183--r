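---
title: "Methods: a satellite nutrient-stress index and its space-time decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a satellite nutrient-stress index and its space-time decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The physiological model behind the index

Phytoplankton adjust their cellular carbon-to-chlorophyll ratio (Θ, mgC
mgChl⁻¹) on timescales of days, balancing light harvesting against growth
demand. Two processes dominate: photoacclimation (more chlorophyll per
carbon under low light) and nutrient regulation (less chlorophyll per carbon
when nutrient-limited division slows). Satellite ocean color constrains the
observed ratio directly,

Θ_obs = C_phyto / Chl,

from retrieved phytoplankton carbon and chlorophyll-a. The photoacclimation
component alone is modeled mechanistically from three globally available
quantities — daily integrated surface irradiance (PAR, mol quanta m⁻²
day⁻¹), the diffuse attenuation coefficient for PAR (K_PAR, m⁻¹), and
mixed-layer depth (MLD, m):

- median mixed-layer irradiance: I_ML = PAR · exp(−K_PAR · MLD / 2);
- shallow-mixing correction: ΔΘ_SM = (1 + e^(−0.15·PAR)) / (1 + e^(−3·I_ML));
- photoacclimation ratio: Θ_photo = Θ_DM · ΔΘ_SM,

with Θ_DM = 150 mgC mgChl⁻¹ a fixed deep-mixing baseline (a configuration
constant here, not re-estimated from data). The nutrient-stress index is the
ratio

Θ′ = Θ_photo / Θ_obs,

dimensionless, with low values indicating strong nutrient stress: nutrient
stress raises C:Chl above its photoacclimation expectation, pushing Θ_obs
above Θ_photo.

Note the exact identity ΔΘ_SM = 1 whenever K_PAR·MLD = 2·ln 20 ≈ 6 optical
depths, for every PAR: the correction passes smoothly through the
deep-mixing baseline. We evaluate the correction as printed at *all* mixed-layer
depths rather than clamping it beyond six optical depths; the
`clamp_deep_mixing` flag exposes the alternative reading in which Θ_photo is
held at Θ_DM under deeper mixing. With the default, very deep mixing at
moderate PAR yields ΔΘ_SM below one; both behaviors are available because
the deep-mixing convention is a genuine modeling choice.

### Why the ratio, and not its inverse

The chemostat simulation (`acclimation_model()`, `index_response()`)
compares three candidate formulations. Cellular Chl:C is modeled as a
baseline light curve anchored at a common dark value `chlc_dark` (division
becomes entirely light-limited as irradiance → 0, so nutrient status cannot
matter there), and nutrient availability scales the light-dependent part in
direct proportion to the division-rate multiplier `f`:

Chl:C(f, I) = chlc_dark + f · (chlc_base(I) − chlc_dark).

The baseline `chlc_base` rises steeply from the dark anchor over the first
few tens of µmol photons m⁻² s⁻¹ and then declines with increasing light
(the photoacclimation branch); its parametric form,
`chlc_dark + a·(1 − e^(−I/b_rise))·e^(−I/b_fall)`, is a structural stand-in
for laboratory curves — the conclusions drawn from it are structural
(linearity versus curvature of the indices), not species-specific. Defaults:
`a` = 0.08 mgChl mgC⁻¹, `b_rise` = 15, `b_fall` = 300 µmol photons m⁻² s⁻¹,
light-saturated nutrient-limited division rate 0.75 day⁻¹ with light
saturation down to ~200 µmol photons m⁻² s⁻¹.

Algebra then gives, at a fixed irradiance, the ratio index
Θ_photo/Θ_obs = Chl:C(f)/Chl:C(1), which is *exactly affine in f* and
reduces to f as the dark anchor's contribution vanishes. The inverse
(Θ_obs/Θ_photo) and normalized difference ((Θ_obs − Θ_photo)/Θ_photo) are
convex decreasing in f — they compress differences among strongly stressed
states and stretch weakly stressed ones, which is why the ratio form is
retained.

## Profile-derived quantities

Nutricline depth is the shallowest depth where a nitrate profile crosses
3 µM, by linear interpolation between bottle depths; a surface value at or
above threshold gives 0 m, and a profile that never reaches it returns the
`Inf` sentinel — "absent nutricline" is deliberately distinct from missing
data (`NA`), and downstream regressions drop the sentinel unless told to
treat absent as 0 m. Mixed-layer depth uses the 0.03 kg m⁻³
density-threshold criterion against a 10-m reference depth (a common
hydrographic convention; configurable), with a `bottom_limited` flag when
the threshold is never exceeded. When only the 490-nm attenuation is
available, K_PAR = 0.0864 + 0.884·K490 − 0.00137/K490 (a published monotone
conversion), bypassable when K_PAR is supplied directly.

## The synthetic ocean

`generate_scene()` plants known structure so every downstream stage can be
verified end to end:

- a smooth nutricline map Z(x): two subtropical-gyre lobes near 175 m,
  shallow (~30 m) equatorial/eastern upwelling and poleward edges;
- a monotone map g(Z) from nutricline depth to the mean index level,
  spanning roughly 0.5–3.5 (above 3 over shallow nutriclines, below 1 where
  the nutricline is deeper than 150 m); an optional "dip" at the shallowest
  depths mimics equatorial iron-stress suppression and is off by default to
  keep g monotone;
- hemispherically opposed annual cycles whose amplitude grows linearly with
  |latitude| (35% at 40°), plus a semiannual tropical component (15%);
- one interannual mode: an ENSO-like zonal dipole pattern in the tropics
  driven by a quasi-oscillatory index (default period 10/3 years, random
  phase). A band-limited oscillation rather than a red-noise process was
  chosen deliberately: real climate modes are quasi-periodic, and an
  oscillatory index keeps the planted per-pixel linear trends identified —
  an AR(1) mode with a multi-year decorrelation time would itself alias
  into decade-scale linear trends and make the planted trend map
  ill-defined at this record length;
- a smooth per-pixel relative trend field (peak ±0.4% per year) applied
  multiplicatively and centered mid-record;
- multiplicative lognormal noise on the realized index (ratios are scale
  quantities; the default coefficient of variation is 5%);
- rectangular land masks, sufficient to exercise masking logic.

The noise-free latent index is stored as `s_true` and the realized index
(`s_true` × noise) as `theta_prime_true`; the emitted optical fields are
constructed so that running the index chain on them reproduces
`theta_prime_true` to machine precision. The *planted trend* stored on the
scene is the closed-form least-squares slope of the noise-free latent field,
not the nominal relative rate: over a finite record, seasonal and mode
factors interact with the trend term (and with record truncation), and the
deterministic trend actually present is what a trend estimator should
recover. The planted seasonal/interannual variance budget is likewise
computed from the noise-free field by plain group-mean arithmetic on the
monthly-binned series — a route independent of the ANOVA machinery used for
recovery. With defaults the budget is roughly 70% seasonal and 21%
interannual, a seasonally dominated regime with substantial climate-mode
variance like the observed ocean.

What the generator does *not* emulate: ocean dynamics (advection, eddies),
spatially correlated retrieval errors, irregular sampling gaps and cloud
masks beyond simple rectangles, non-Gaussian climate-mode asymmetries, or
trends in the driver fields' seasonality. Passing recovery tests therefore
demonstrates that the statistical machinery is correct and unbiased under
the planted structure — not that real retrievals are free of the systematic
errors the generator omits.

Biomarker samples (`sample_biomarkers()`) fall along contiguous cruise-track
segments by default — emulating the spatial autocorrelation of ship-based
transect sampling — with a uniform mode for unit tests. The five genomic
stress indices (Ω_NH, Ω_NM, Ω_PH, Ω_FeH, Ω_FeM) are logistic functions of
the *standardized log of the index averaged over ±20 days* around the
sampling date: the community genomic state is modeled as integrating its
nutrient environment over a characteristic window, which is exactly the
structure the matchup-window scan is designed to detect. High-intensity N
and Fe markers load negatively (elevated under strong stress), the
phosphorus marker positively, medium-intensity markers weakly. Gene tables
(`generate_gene_table()`) draw per-sample single-copy core-gene (SCCG) mean
coverages lognormally and set each flexible gene's coverage to
copies-per-genome × SCCG mean × lognormal noise, with copies driven by
planted per-gene coefficients (+0.8 / −0.8 / 0 thirds by default).

## Matchups, timescale, and attribution

`colocate()` averages, unweighted, all unmasked cells whose composite
midpoint falls within ±h days of a sample's date and whose position falls in
the spatial window: pixel blocks (1×1, 3×3, 5×5, centered on the nearest
pixel) or degree boxes (1°, 2°, 5°, centered on the sample's coordinates,
not snapped to pixel boundaries). No distance or area weighting is applied.
Because sampling dates are continuous while composites are discrete, the
contributing set varies smoothly with h, which is what lets a scan over
half-widths (±2 to ±30 days in 2-day steps) localize the planted ±20-day
biological window instead of producing ties.

`timescale_scan()` and `variance_attribution()` grow random forests
(500 trees by default, other hyperparameters at the implementation's
package defaults, pinned by seed) and report out-of-bag variance explained —
the honest generalization estimate the forest provides for free; in-bag R²
is reported alongside for transparency. Complete cases only; no imputation.
Gene-trait correlations are plain Pearson correlations of per-gene z-scored
copies-per-genome against the matched index, reported unadjusted (a
Benjamini–Hochberg flag exists), ranked most negative first.

## Geospatial statistics

- **Detrending/trends**: per-pixel ordinary least squares, vectorized with
  mask-aware sums; slope standard errors from the usual iid formula. A
  documented limitation: with strong seasonal cycles, slight non-integer
  record lengths leak seasonal variance into per-pixel slopes; the planted
  slope map includes this deterministic leakage, so recovery is tested
  against the trend actually present.
- **EOF**: singular value decomposition of the pixels × time matrix of
  centered series. Pixels missing more than 20% of time steps are excluded
  listwise (threshold configurable); remaining gaps enter as zero
  anomalies. Principal components are orthonormal; spatial loadings carry
  amplitude; variance fractions are squared singular values over their sum.
  Sign convention: each mode is flipped so its largest-magnitude spatial
  loading is positive. No cos-latitude area weighting by default (a flag
  enables it). The decomposition operates on 8-day fields by default;
  monthly binning first is possible but not required.
- **Mode selection**: mode numbering is dataset-dependent, so interannual
  modes are selected by criterion — dominant raw-periodogram period of the
  PC longer than 1.5 years — never by fixed index.
- **Variance partition**: 8-day composites are binned to calendar months
  (twelve equal 30.44-day slices of a 365.25-day year, keeping the
  month × year design balanced), then a two-factor fixed-effects model per
  pixel; fractions are factor sums of squares over the total, with type-II
  sums of squares (each factor adjusted for the other) for pixels with
  missing months. Balanced designs reduce exactly to the textbook
  orthogonal decomposition.
- **Anomalies**: monthly anomalies subtract the pixel's month-of-year
  climatology (their climatology is identically zero afterwards — a test
  invariant); annual anomalies are year means minus the record mean; phase
  composites average annual anomalies over analyst-supplied year sets (the
  warm/cool phase years are inputs, not detected).
- **Regional summaries**: pixels are labelled hemisphere × nutrient regime
  (nutricline shallower/deeper than 50 m); regional mean trends carry 95%
  percentile-bootstrap intervals (10⁴ resamples by default) over pixels
  resampled independently. Ignoring spatial autocorrelation makes these
  intervals anti-conservative on strongly correlated fields — a documented
  limitation of the naive pixel bootstrap.
- **Smoothing**: visualization uses local first-degree tricube-weighted
  regression over a 20-point window without robustness iterations.

## Numerical choices and degenerate inputs

Masked cells are `NA` throughout; arithmetic with a mask yields a mask and
nothing is infilled. `theta_obs()` masks non-positive inputs (warning only
when everything masks out). Zero-variance EOF modes are dropped at a
relative singular-value tolerance of 1e-12. Constant gene profiles yield
missing correlations rather than errors. Cross-mission harmonization
(`apply_sensor_bias()`, chlorophyll −0.012 mg m⁻³, backscattering
+1.71 × 10⁻⁵ m⁻¹ on the companion mission) is guarded by a provenance flag
so it cannot be applied twice. Scenes serialize to a plain-text JSON format
at full double precision, so a write/read cycle is value-identical.

## Problem sizes

The desk-scale study conditions used by the tests and the acceptance script:
a 40 × 80 pixel, 10-year scene of 8-day composites (457 steps, ~3000 ocean
pixels) for the round-trip recovery of variance shares, the interannual
mode, and trend maps; ten independent 10 × 20 × 4-year scenes with 250
samples each for the timescale scan; 200 samples × 30 genes × 10 seeds for
gene-trait statistics; 200 replications of 100-pixel Gaussian slope fields
for bootstrap coverage. Each was chosen as the smallest configuration at
which the planted signals are comfortably identified by the statistics
involved.
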