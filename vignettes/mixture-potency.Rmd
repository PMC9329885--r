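---
title: "Dose-response methods for binary-mixture potency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response methods for binary-mixture potency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasmix)
```

## Scope and model

`pfasmix` analyses embryo toxicity studies with the classic layout: a
control group plus an ascending series of treatment groups, several
replicate dishes per group, a fixed number of embryos per dish, continuous
morphometric endpoints (swim bladder area in mm², body length in mm, yolk
sac area in mm²) measured on surviving fish, and per-dish mortality and
hatch counts. The motivating case is the binary mixture of PFOS (the index
chemical) and 6:2 FTS, studied both as single-chemical "component"
experiments and as a whole mixture at a nominal 1:10 concentration ratio.

The workhorse dose-response model for a continuous endpoint is linear in
dose,

$$R_i = a + b\,D_i,$$

with $a$ in endpoint units (mm²), $b$ in endpoint units per µg/L, and $D_i$
the measured concentration in µg/L. Fits use individual fish pooled across
replicate dishes under a constant-variance Gaussian likelihood, so the OLS
solution is the maximum-likelihood fit. Concentrations are carried in µg/L
throughout; the molar scale is display-only (`convert_units()`), and all
analysis uses *measured* rather than nominal concentrations.

## Percent response and its baseline

Responses are expressed as fractional change from the **observed
control-group mean** $R_0$, not from the fitted intercept:

$$\text{\% response}(D) = \frac{R_0 - (a + b\,D)}{R_0}, \qquad
  D(p) = \frac{R_0\,(1-p) - a}{b}.$$

This choice matters. For the PFOS component fit the intercept sits about
28% below the control mean, so the fitted line "starts" at a nonzero
response and levels shallower than that are unreachable: the inversion
returns a typed `below_intercept` status, never a negative dose. An
intercept-relative baseline would change every number in the relative
potency and balance tables; the control-mean convention is the one that
reproduces the published tables, and it is applied uniformly — including in
the response-additivity classifier, where a mixed convention could silently
flip an interaction call from antagonistic to synergistic.

`dose_at_response()` is the exact algebraic inverse of the percent-response
map; the tests verify the round trip to 1e-9 and agreement with an
independent bisection root-finder.

## Points of departure

**NOAEL/LOAEL.** `anova_pairwise()` runs a one-way ANOVA on *replicate
means* (typically n = 3 dishes per group) with Tukey-adjusted
control-vs-treatment contrasts at α = 0.05 (configurable). The dish is the
independent experimental unit, so this is deliberately low-powered; treating
360 fish as independent would badly overstate significance.
`derive_noael_loael()` applies the standard reading — LOAEL = lowest
significant dose, NOAEL = highest non-significant dose below it — with two
qualified boundary cases: significance at the lowest tested dose yields an
*unbounded-low* LOAEL (printed `<`), and no significance anywhere yields an
*unbounded-high* NOAEL at the top dose (printed `>`). Non-monotonic
significance patterns (significant at T4 but not T5, as seen for body
length and yolk sac area under PFOS) warn rather than fail.

`pod_ratio()` propagates these qualifiers through POD ratios: an
unbounded-low numerator or unbounded-high denominator makes the ratio an
upper bound, the opposite directions a lower bound, and same-direction
unbounded inputs are honestly `indeterminate`. Ratios are kept at full
precision internally and conventionally reported at 2 significant figures.

**Benchmark doses.** `compute_bmd()` defines the benchmark response as a
shift of `bmr_sd` control standard deviations (default 1) from the model's
dose-0 prediction, in an explicit adverse direction per endpoint (decrease
for SBA and BL, increase for YSA). For the linear model the BMD has the
closed form `bmr_sd · SD / |b|`; for other models it is solved numerically
on a geometric dose grid up to 10× the maximum tested dose, beyond which a
`no_solution` status is returned. The BMDL is the one-sided 95%
profile-likelihood lower bound (χ², 1 df, 90% two-sided cutoff — the
convention of benchmark-dose practice). Profiling eliminates one mean
parameter per model in closed form from the benchmark constraint and
re-optimises the rest; if profiling fails for the linear model a
delta-method bound is substituted and flagged in `bmdl_method`. Residual
variance is modelled as constant across dose groups — stated here because
dedicated benchmark-dose software sometimes models dose-dependent variance,
and the choice affects BMDLs.

Candidate mean models (`fit_candidates()`) are linear, power (exponent
≥ 1), second-order polynomial, three-parameter exponential, and Hill with
power ≥ 1. The power restrictions avoid the unbounded low-dose steepness
that lets a Hill fit place the BMD orders of magnitude below the lowest
tested dose; when that happens anyway, the 3× extrapolation rule flags the
result `questionable_extrapolation` (BMD more than three-fold below the
lowest nonzero dose). Non-converged models are reported with a failure
status, never dropped silently. Because doses are internally rescaled to
[0, 1] before optimisation, AIC values and rankings are invariant to dose
units.

`exclude_nonmonotonic_top()` implements the pre-fitting screen for the
pattern that precludes dose-response modelling: the top group is dropped
if and only if its mean reverses the direction of the preceding trend by
more than one control SD, and the decision is logged.

## Mixture analysis

**Five-step dose balance** (`equivalent_dose_balance()`): at each response
level, (1) invert the component-study index fit, (2) invert the
mixture-study index fit, (3) subtract — the *balance* is the
index-equivalent dose attributable to the co-chemical, (4) invert the
mixture-study co-chemical fit, (5) ratio balance to co-chemical dose. A
negative balance means the mixture needed more index chemical than the
component study at the same response — flagged `antagonistic`, with ratios
suppressed (a zero balance is treated the same way; it is not a positive
potency). Levels unreachable by the component fit are `below_intercept`.
The decomposition `dose_index_mix + balance = dose_index_alone` is exact.

**Isoboles** (`isobole()`): the dose-addition line at one response level
joins the two single-chemical iso-effective doses; the endpoints reuse the
same inversion as `rp_curve()`, so they agree identically. **Response
additivity** (`classify_point()`, `response_additivity_table()`): the
additive prediction is the *sum of component percent responses* (each
floored at 0, the sum capped at 100%) — response addition, distinct from
the dose addition of the isoboles; both conventions appear in mixture
practice and the package names them explicitly. A point whose observed
response exceeds the additive prediction by more than the tolerance is
synergistic, short of it antagonistic, within it additive. The default
tolerance of ±0.05 absolute response fraction reflects that differences of
this order in group-mean responses are within the noise of a 3-dish design.

**Limiting relative potency** (`rp_limit()`): as the response level
approaches 100% the co/index dose ratio converges to the ratio of
x-intercepts $(a_{co}/|b_{co}|)/(a_{idx}/|b_{idx}|)$ — about 13.9 (≈ 14)
for the shipped component fits, matching the slope of the published
isoboles.

## The synthetic-data generator

`generate_study()` emulates the study design: 6 groups × 3 dishes × 20
embryos (360 records), survival and hatching as group-level binomial draws,
and each continuous endpoint as
$\mathcal{N}(a + b \sum_k w_k C_k,\ \sigma)$ truncated at zero, where
$w_k$ are potency weights (index = 1) so one generator serves component and
mixture designs. Dead fish keep missing morphometrics, as in the real
protocol where dead embryos are removed before imaging. Draws follow a
fixed order under R's Mersenne-Twister with inversion normals, so a
`(design, truth, seed)` triple is exactly reproducible; the seed and
generator are recorded as attributes.

Defaults (`default_truth_model()`): the SBA truth is the published PFOS
component fit (a = 0.04563 mm², b = −6.45×10⁻⁶ mm² per µg/L) with noise SD
0.013 mm², the scatter scale those fits imply; BL declines shallowly
(−2×10⁻⁵ mm per µg/L around 3.7 mm, SD 0.15 mm) and YSA increases
(+1×10⁻⁶ mm² per µg/L around 0.25 mm², SD 0.03 mm²), reflecting that these
endpoints respond weakly in this design; the 6:2 FTS potency weight is
1/13.88 (the component-fit limiting relative potency); mortality is 5% and
hatch 90% per group, dose-independent, because those endpoints showed no
dose response. The measured 1.9 µg/L 6:2 FTS trace in one control group
(attributed to analytical carryover) is configurable and defaults to 0 in
simulation.

What the generator does **not** emulate: chemical mass loss over the
exposure (the measured-vs-nominal discrepancies of the real study),
hatching kinetics, dose-dependent mortality, between-dish random effects,
or non-Gaussian endpoint distributions. Passing tests therefore validate
the *statistical machinery* under a known truth, not the biology of any
particular dataset.

One regime deserves a caveat: when `a + b·D` approaches zero the truncated
generator's mean rises above the linear truth, so the linear fit is then a
misspecified model of its own generator. The generator-validation tests
use the component dose range with the top group removed (5 groups × 60
fish, n = 300, doses 0–2066 µg/L) — mirroring the analysis choice of
excluding the non-monotonic top group — where truncation is negligible.

## Validation summary

The test suite establishes, among others (problem sizes chosen to keep the
whole suite under a minute):

* exact reproduction of the published relative-potency and dose-balance
  tables (50–90% rows within 2% of print, ratio cells additionally allowed
  half a unit in the last printed digit, since 2-significant-figure cells
  can round by more than 2%);
* the linear BMD equals its closed form to 1e-9; BMDL ≤ BMD always, with
  the gap collapsing as residual noise vanishes;
* the profile BMDL agrees with a 2000-resample stratified bootstrap
  percentile oracle within 10% on a seeded synthetic study;
* 95% OLS intervals cover the generator truth at nominal rate over 500
  simulations, and the replicate-mean ANOVA pipeline holds its family-wise
  type-I error within [0.01, 0.10] over 1000 null simulations;
* qualifier algebra is closed and reciprocal; interaction calls respond to
  dose scaling with the correct sign.

## Known limitations

* Only linear fits feed the inversion/balance machinery; nonlinear curves
  participate in BMD analysis but full-curve relative potency would need
  monotone numerical inversion (out of scope).
* No confidence bands on relative-potency curves or balance tables — point
  estimates only, as in the source tables.
* The NOAEL/LOAEL stage inherits the low power of n = 3 replicate means;
  an unbounded LOAEL at the lowest dose is common and the qualifier
  algebra exists precisely to keep that honest.
* Dichotomous-endpoint benchmark modelling and model averaging are not
  implemented.
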