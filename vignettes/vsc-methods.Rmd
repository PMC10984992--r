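---
title: "Vertical structural complexity: metrics, driver attribution and upscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertical structural complexity: metrics, driver attribution and upscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertsc)
```

## The problem

Plant communities occupy above-ground space vertically as well as
horizontally. How completely they fill that vertical niche — their
*vertical structural complexity* (VSC) — responds both to how much
resource the environment supplies (water, heat, soil nutrients) and to
how much physiological stress it imposes without supplying anything
(extreme cold, wide diurnal temperature swings, wind, low oxygen partial
pressure, ultraviolet load). `vertsc` implements a complete plot-to-map
analysis of this question: per-plot VSC metrics from survey tables,
attribution of their spatial variation to resource versus non-resource
drivers, and machine-learning upscaling to gridded maps. A
synthetic-data generator emulating a high-plateau survey across five
vegetation types makes every stage testable without field data.

## The three metrics

For a plot with measured plant heights $h_1, \dots, h_n$:

* **Height-max** — $\max_i h_i$, the canopy top.
* **Height-var** — the coefficient of variation $\mathrm{SD}(h)/\bar h$.
  The sample ($n-1$) standard deviation is the default because survey
  plots are samples of a community; `sd_mode = "population"` switches
  to the $n$ denominator.
* **Height-even** — Shannon evenness across fixed-width height classes,
  $\left[-\sum_k P_k \ln P_k\right]/\ln N_h$, where $P_k$ is the weight
  share of the $k$-th occupied class and $N_h$ the number of occupied
  classes.

Class widths follow the survey convention: 1 m for forests, 0.10 m for
shrublands, 0.01 m for grasslands (`class_widths()`), so each
vegetation type is resolved at a scale commensurate with its stature
(0.1 m alpine cushions to 30 m trees). Classes are half-open intervals
$[kw, (k+1)w)$ anchored at zero — anchoring is a convention, and a
fixed one keeps the binning reproducible.

The class weights differ by vegetation type, mirroring what the field
protocol records:

* **Woody plots** (forest, shrubland): each stem is weighted by its
  basal area $\pi (d/2)^2$ from the DBH (forests) or basal diameter
  (shrublands).
* **Grassland plots**: records are aggregated to species; each species
  is weighted by its importance value
  $\mathrm{IV} = (\text{relative height} + \text{relative coverage})/2$
  and assigned to the class of its mean height. Relative height is the
  species' mean height divided by the sum of species mean heights, so
  the weights sum to one by construction. The same IVs feed the
  Shannon–Wiener diversity index used in the sampling-bias check below.

Two degenerate-input conventions matter. A single occupied class gives
$N_h = 1$ and an indeterminate $0/0$; we define Height-even as 1 there,
because a one-class profile is maximally uniform — consistent with
Height-var being 0 for equal heights. And $N_h$ counts *occupied*
classes by default (`nh_mode = "occupied"`), which makes uniform
occupancy score exactly 1; `nh_mode = "span"` instead counts every
class between the lowest and highest occupied one, so canopy gaps
depress the score. The occupied convention is the default because it
keeps the $[0, 1]$ bounds tight.

## Driver attribution

Thirteen candidate drivers are classified once in `vsc_variables()`:
six resource variables (MAT, MAP, aridity index AI = MAP/PET, pH, SOC,
TN) and seven non-resource limiting variables (T_coldest, T_diurnal,
T_annual, PO2, PCO2, UR, Wind). The inferential chain is:

1. **Pearson screening** (`screen_variables()`). Three ordered rules
   remove structural redundancy before any model is fit: PCO2 is
   dropped when it is collinear with PO2 (both are barometric functions
   of elevation, so their correlation is 1); among the three
   low-temperature variables only the one least correlated with MAT is
   kept, and only when the trio is mutually redundant (|r| ≥ 0.5, below
   the observed trio correlations but high enough that orthogonal
   tables pass untouched); MAP is dropped when AI is present and the
   two correlate at |r| ≥ 0.9 (AI is MAP/PET, so this is near-certain
   wherever PET varies less than MAP). Thresholds are arguments, 0.9 by
   default for the hard collinearity rules.
2. **Stepwise selection** (`fit_drivers()`): a bidirectional AIC search
   from the full OLS model, via `MASS::stepAIC`. Starting full and
   searching both directions matches that function's default behaviour
   when handed a full formula. The 0.05 significance level affects
   reporting only; selection is AIC-driven.
3. **LMG relative importance** (`lmg_importance()`): each selected
   predictor's share of the model $R^2$, averaged over all orders of
   predictor entry. We compute it by the subset-weighted identity
   (weights $|S|!\,(p-|S|-1)!/p!$ over the $2^p$ subsets), which is
   exact and feasible up to 12 predictors; beyond that the function
   refuses rather than silently sampling orderings. Shares are
   non-negative and sum to the model $R^2$ to machine precision — this
   is asserted in the tests on every fitted model. A sequential
   (entry-order) decomposition is available behind
   `importance = "sequential"` for comparison; LMG is the default
   because it is order-invariant.
4. **Resource split** (`resource_split()`): the LMG shares summed
   within each registry class, expressed as percentages of the model
   $R^2$.
5. **Diagnostics**: VIFs from the inverse correlation matrix of the
   selected design (undefined for a single predictor, infinite under
   exact collinearity), and Moran's I of the model residuals with
   row-standardized inverse-distance weights over great-circle
   distances (`morans_i()`; k-nearest-neighbour weights are available).
   The weight scheme is a genuinely open choice — inverse distance with
   row standardization is the common default for irregular survey
   points. Residual I near the null expectation $-1/(n-1)$ indicates
   the drivers absorb the spatial structure, so ordinary (non-spatial)
   regression is defensible.

Because the vegetation types differ greatly in plot count,
`bootstrap_match()` equalises sample sizes: each replicate draws the
same number of plots (237, the smallest type's count) without
replacement from every type and re-runs the full chain. Types with
fewer plots than the target — the 30 shrubland plots — cannot be
size-matched and are excluded from this comparison.

`partial_correlation()` supports the grassland sampling-bias check:
since only a subsample of individuals per species is measured, species
richness and evenness could leak into Height-var and Height-even. The
check compares the zero-order correlation between a metric and its
dominant driver with the first-order partial correlation controlling
the Shannon–Wiener index; agreement indicates negligible leakage.

## Spatial upscaling

`fit_rf()` trains one regression forest per metric on all 13 drivers,
using 75% of the plots and reporting hold-out accuracy on the other
25% as the squared Pearson correlation between observed and predicted
values (the observed-vs-predicted, 1:1-line convention;
`r2_mode = "ss"` gives $1-\mathrm{SSE}/\mathrm{SST}$ instead).
Height-max spans more than two orders of magnitude across vegetation
types, so it is log10-transformed before training and back-transformed
in `predict_map()`. Forest hyperparameters are the standard regression
defaults — 500 trees, `mtry = ceiling(p/3)`, unlimited depth — all
exposed as arguments. Variable importance is the accumulated
node-purity (variance-reduction) increase. Rows are ordered canonically
by plot ID before the seeded split, so results do not depend on the
incidental order of the input table.

Soil and atmospheric predictors are only measured at plots, so their
gridded layers are rebuilt by **ordinary kriging**
(`krige_layer()`, `krige_to_raster()`): a spherical variogram with
nugget is fitted to the empirical semivariogram by weighted least
squares (pair-count weights; a linear model is also available), and the
kriging system is solved in semivariogram form with a Lagrange
multiplier. Because $\gamma(0) = 0$, predictions at sample locations
reproduce the sample values exactly — the property ordinary kriging is
chosen for — and the tests assert agreement within $10^{-6}$. A
constant field short-circuits to a constant layer with zero kriging
variance, since a variogram cannot be fitted to zero dispersion.
Duplicate sample locations make the system singular and are refused
with the offending rows named.

Masked raster cells (water/ice in the emulated domain) carry NA and
propagate through every predicted map.

## What the synthetic generator emulates

`synthetic_config()` defaults define the emulated survey: 456 forest,
30 shrubland, 669 meadow, 621 steppe and 237 desert plots (2013 in
all); per-type environmental regimes in which aridity declines and
stress (diurnal range, wind, elevation) rises from forest to desert;
and per-type linear models that tie the log of each plot's Height-max,
and of its within-plot height CV, to standardized drivers. The
scenario's per-type Height-max and Height-var means and SDs span the
realistic range for such a campaign (forests 23.5 ± 8.1 m down to
alpine deserts 0.17 ± 0.10 m). The default variance decompositions
realise the
favorable-to-extreme scenario: the aridity index dominates the woody
regimes, while the non-resource share rises monotonically from forest
through meadow and steppe to desert. The meadow and steppe
decompositions are spaced widely enough (roughly 26 and 10 resource
percentage points from their neighbours) for the stepwise-plus-LMG
chain to resolve the ordering at the bootstrap sample size; a
post-selection analysis inflates small shares by several points, so
decompositions closer than that are indistinguishable to it.

Mechanically, each plot draws its environment from the type's regime
(AI always derived as MAP/PET, PO2 and PCO2 always barometric functions
of elevation with scale height 8000 m and mixing ratios 0.20946 and
4.0×10⁻⁴ — an isothermal approximation; the true profile is
temperature-dependent, which we do not model), then its true metrics
from the configured linear models, then individual plants: log-normal
heights rescaled so the tallest plant realises Height-max exactly and
power-adjusted so the sample CV equals the plot's target (the
adjustment preserves order, positivity and the maximum). Grassland
plots draw a Poisson(8) species count (minimum 1, three measured
individuals per species) with Dirichlet coverages; woody plots draw
Poisson stem counts (38 forests, 11 shrublands) with allometric
DBH/basal diameters. Height-even is *emergent* — no model drives it —
so its per-type means are not calibrated to the survey and its
random-forest hold-out accuracy is low; tests treat it through its
mathematical invariants rather than its driver structure.

The generator does **not** mimic real geography, species identities,
phenology, survey-gap masking, or the real data's full covariance
structure; passing tests demonstrate that the pipeline's statistics
behave correctly under a known truth, not that the ecological
conclusions transfer to any particular landscape.

## Numerical choices and problem sizes

* Evenness is clamped to $[0, 1]$ against $10^{-16}$-scale rounding.
* Rank-deficient predictor subsets inside the LMG enumeration fall back
  to a maximal independent subset, so duplicated predictors split their
  share symmetrically instead of crashing.
* Partial correlations with vanishing residual variance (denominator
  below $\sqrt{\varepsilon}$) are reported as NA with a warning.
* Coincident points in inverse-distance weight matrices would give
  infinite weight; they are capped at the largest finite weight with a
  warning.
* The test suite exercises the full 2013-plot survey in the
  deeper end-to-end checks (bootstrap at 100 replicates of 237 plots)
  and scaled-down surveys of 200–400 plots elsewhere; these sizes keep
  every statistic well identified while the whole suite runs in about
  a minute.

## Known limitations

* The barometric PO2/PCO2 profile is isothermal; a temperature-coupled
  profile would shift high-elevation values by a few percent.
* LMG is exact-enumeration only (≤ 12 predictors); sampling of
  orderings is deliberately not implemented.
* No spatial regression models: Moran's I is a diagnostic, and the
  pipeline assumes it stays near its null expectation.
* Kriging treats lon/lat as planar coordinates at regional extent;
  project first if the domain is large enough for that to matter.
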