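---
title: "Methods: upscaling soil respiration and measuring above-belowground stability coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upscaling soil respiration and measuring above-belowground stability coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabcouple)
```

## The model and its assumptions

The package treats belowground ecosystem stability as the temporal
stability of annual soil respiration (Rs, g C m⁻² yr⁻¹) and aboveground
stability as that of vegetation productivity metrics (NPP, LAI). Stability
of an annual series is μ/σ with the sample (n−1) standard deviation; a
zero-variance series has undefined stability and is masked rather than set
to infinity, so that downstream correlations skip such cells explicitly.

Gridded annual Rs is not observed; it is upscaled from site-year records
by a quadratic regression on six composite environmental indices, fit
separately per ecosystem type:

Rs = β₀ + β₁·Cli + β₂·Cli² + β₃·Plant + β₄·Plant² + β₅·Gra + β₆·Gra² +
β₇·Mic + β₈·Mic² + β₉·Phy + β₁₀·Phy² + β₁₁·Chem + β₁₂·Chem² + ε

Each index is the first principal component of a standardized (z-scored)
variable category; PCA on the correlation scale is assumed throughout.
The time-varying categories (climate: MAT, Tmax, Tmin, MAP, radiation,
AET, PET; vegetation: NPP, LAI, FVC, CUE = NPP/GPP, WUE = NPP/AET) enter
the PCA together with their 3-year trailing moving averages, which proxy
cumulative effects of past conditions on the flux; the static categories
(topography, soil microbial, physical, chemical) use plain PCA. The
trailing (not centered) window shortens at the series start so the output
keeps the input length. Because a principal component's sign is
arbitrary, each index is oriented so a designated reference variable
loads positively (MAT, NPP, elevation, MBC, clay, SOC respectively);
without this convention the β would not be reproducible. The PCA is fit
once globally (by default on all cell-years) so indices are comparable
across space; a subsample fraction is available for very large grids.

Key modelling assumptions: Rs is modelled on the raw flux scale (no log
transform); quadratic candidate terms enter selection independently of
their linear partners (no heredity constraint); negative predictions are
floored at zero and counted; and ecosystem classes are fit independently,
so any class with too few records is skipped with a warning rather than
borrowed across.

## Term selection

"Stepwise" selection leaves the penalty open, and the choice matters. The
default here is the extended BIC (penalty log n + 2·log p with p = 12
candidates), searched bidirectionally from the intercept-only model. With
AIC, each null term enters with probability ≈ 0.16, so on a candidate set
with several inactive terms the probability of recovering exactly the true
support is well under one half; plain BIC improves this but a
bidirectional search over twelve correlated candidates still admits null
terms several times more often than the single-test rate suggests. The
extended BIC was introduced precisely for selection over larger candidate
sets; at the sample sizes per class this package targets (several hundred
records), true effects of the size a usable upscaling model requires carry
t-statistics of 10 or more, so the stricter penalty costs essentially no
power while making the selected term set stable across replicates.
`fit_rs_model(selection = list(criterion = "aic"))` or `"bic"` restore the
alternatives.

## Validation

Records from one site are strongly dependent (same cell, same soil, often
a shared measurement campaign), so a record-level random split leaks
information from training to test. Validation therefore blocks folds by
Site ID: within each ecosystem class, ~80% of *sites* (not records) go to
training, and metrics (Pearson R, MAE, RMSE) are computed on the held-out
records. The package also exposes the record-level random split — not as
a recommendation but so the leakage can be demonstrated: with site-level
noise, the random split reports systematically higher R than the blocked
split, which is the reason for blocking.

## Stability, windows, coupling

Full-period stability maps use all years; the time-resolved analysis uses
10-year moving windows (34 annual steps give 25 windows, labelled
1985–1994 through 2009–2018 for a 1985 start). Coupling between
belowground and aboveground stability is the per-cell Pearson correlation
between the two 25-value window series, flagged significant when |r|
exceeds the two-sided t critical value at the analysis's actual window
count (0.396 at 25 windows, α = 0.05) — the threshold is always computed
from first principles, never hard-coded, because published per-figure
constants depend on an unstated n.

A caveat stated here deliberately: consecutive 10-year windows share nine
years of data, so the 25 window values are strongly autocorrelated, and
the t-based test — which assumes independent pairs — is anticonservative
under the null. Monte Carlo on independent white series shows a rejection
rate near 40% rather than 5% at α = 0.05. The significance flag is
therefore a *descriptive* device for comparing maps (exactly as used in
the literature this package follows), not a calibrated test; the
decoupled-world generator makes this visible, and calibrated inference
across overlapping windows would need an effective-sample-size or
block-resampling correction, which is out of scope.

Aridity classes use AI = MAP/PET averaged over years with the standard
UNEP breakpoints 0.05, 0.20, 0.50, 0.65; boundary values fall to the
drier class. Bivariate low/high overlap maps classify cells against each
map's own 10th/90th percentiles; if a map is degenerate (all values
equal) all its cells are classed intermediate. In the dominant-predictor
map, a predictor's "contribution" to interannual Rs variation is its
absolute per-cell Pearson correlation with the annual Rs series (a
standardized-regression-coefficient variant is available behind
`method = "std_beta"`); ties break by predictor order.

## Driver attribution

Attribution runs at a coarsened sampling scale: fine cells are grouped
into square blocks (five 0.2° cells per 1°-analogue block), averaging
each stability map over valid fine cells, taking the modal ecosystem
class, and dropping blocks with fewer than 25% valid cells (configurable).
Productivity stability is summarized as the first principal component of
z-scored NPP and LAI stability, oriented positive on NPP. Analyses:

- **Random-forest importance** (ranger, permutation importance) with a
  permutation p-value from refitting on shuffled responses (default 999
  shuffles; the pipeline demo uses fewer). Star-style significance for
  forest importances has no analytic distribution, hence permutation.
- **Partial correlations** per ecosystem: the correlation of the response
  and one predictor after regressing both on all other predictors. The
  residual-regression form is used directly because it remains defined
  when inputs are exactly collinear, where the precision-matrix identity
  fails; p-values use the t approximation with n − k − 2 df and are
  Benjamini–Hochberg adjusted jointly across the whole
  ecosystem × predictor table.
- **Variance partitioning** on adjusted R²: unique₁ = R²f − R²₂,
  unique₂ = R²f − R²₁, shared = R²₁ + R²₂ − R²f, unexplained = 1 − R²f.
  These close to 1 exactly before flooring; small negative components
  (possible with adjusted R²) are floored at zero with a flag.
- **Structural equation model**: a recursive path model — climate
  stabilities (temperature, precipitation, aridity) → productivity
  stability → Rs stability, plus direct climate paths — estimated on
  standardized complete cases. For recursive models with uncorrelated
  disturbances, per-equation least squares is the maximum-likelihood
  estimate; global fit uses the ML discrepancy between the implied and
  sample covariance (χ² with its df, RMSEA, CFI against the independence
  baseline). The default topology is saturated (df = 0): it fits
  trivially and is flagged as such, which matters when reading its fit
  statistics. User topologies with omitted paths get honest positive df.
  The conventional pass rule is χ²/df ≤ 2, P > 0.05, RMSEA ≤ 0.05.

## The synthetic world

The generator emulates the study conditions end to end: 34 annual steps on
an abstract row/col grid (0.2° per cell for the coarsening stage), a
mean-aridity gradient across columns (MAP/PET 0.05–1.5), an interannual
temperature-SD gradient across rows (0.3–2.0 °C), vegetation driven by a
saturating water response times a Gaussian temperature response with
lognormal noise, and true Rs generated from the quadratic index model
with known per-ecosystem coefficients plus additive Gaussian noise
truncated at zero (default SD: 10% of the deterministic signal's SD).
In decoupled mode the vegetation index is replaced by an independent
series before Rs generation, severing the above-belowground link while
leaving everything else intact — the calibration twin for the coupling
analysis.

Design choices made deliberately, and why:

- **Generative β sized to the index scales.** PC1 indices span roughly
  ±8 (climate) to ±3 (chemical); coefficients are chosen (positive
  quadratics, moderate linear terms, β₀ 700–1300 by ecosystem) so the
  deterministic flux stays positive over the whole realized index range.
  A generator whose truth is heavily zero-truncated censors the very
  regression it is supposed to validate.
- **Ecosystem classes are a seeded mosaic**, not regions carved out of
  climate space. Real biome types overlap broadly along climate
  gradients, and per-class regressions are only identifiable if each
  class samples the full index range; with climate-carved classes the
  within-class index variance collapses to a tenth of the global one.
  Realistic biome geography is an explicit non-goal.
- **Within-class soil heterogeneity is comparable to the between-class
  mean spread** (soil maps show enormous within-biome variance). Static
  fields still draw from ecosystem-specific means, but if the means
  dominate, a class's static index and its square become collinear
  (r ≈ 0.97) and no selector can separate linear from quadratic terms.
- **Site records**: each site is pinned to one cell with a unique Site
  ID; per-site year counts are uniform on 1..max (the within-site
  sampling pattern of real compilations is not standardized, so it is
  configuration, default max 10; the recovery analyses use 20 to hold
  several hundred records per class — a pre-hoc power choice). Optional
  injections: a fraction of records with a blanked coordinate or year, a
  fraction pushed beyond ±3 SD, observation noise, and a per-site random
  intercept for leakage studies.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatial autocorrelation beyond smooth gradients,
sub-annual structure, measurement-method heterogeneity between studies,
non-Gaussian flux errors, land-cover change over time, and any dependence
of coupling strength on aridity (in this generator the arid columns have
*weaker* apparent coupling, because vegetation noise is multiplicative
while flux noise is additive, so dry low-flux cells have the worst
signal-to-noise). Conclusions about those features require real rasters
and records.

## Numerical and reproducibility choices

Problem sizes used by the shipped analyses: 30×30 grids with 34 years for
recovery and coupling runs (25 seeded worlds for coefficient recovery;
500 sites each), a 50×50 decoupled world for the null summary, 500 trees
for the vegetation-free forest, n = 2000 for the SEM recovery check.
These sizes give stable statistics while keeping any single analysis in
the tens of seconds.

Every stochastic step takes an explicit seed; a single top-level seed
expands deterministically into per-stage seeds (`stage_seed()`), recorded
in the run manifest together with an MD5 checksum per output file, so a
rerun with the same config is byte-identical. Ties in nearest-cell
assignment go to the lower index; fractional record midyears floor to the
integer year; outlier bounds are computed on the pooled records surviving
the earlier filter steps (a per-ecosystem variant is a flag); the outlier
pass runs once, not iteratively. Stacks and tables persist as long-format
CSV plus JSON/YAML sidecars — plain-text formats keep runs diffable and
portable.

## Known limitations

- The significance flag on windowed coupling is descriptive, not
  calibrated (see above).
- The upscaler extrapolates with a quadratic: cells whose indices lie far
  outside the fitted range can take unphysical values (floored at zero
  and counted, but still extrapolations).
- The SEM default topology being saturated means its fit statistics carry
  no information; use restricted topologies to actually test structure.
- Variance partitioning with adjusted R² can return small negative
  components; flooring is reported but the raw values should be read
  alongside.
- The vegetation-free forest shares the regression's training records;
  it is an independent *model*, not independent *data*.
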