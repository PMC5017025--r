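---
title: "Predicting combined toxicant and environmental stress with samtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting combined toxicant and environmental stress with samtox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samtox)
```

## The problem

Acute toxicity tests estimate the concentration of a toxicant that kills a
given fraction of a population — the LC50, or more generally the LCx. In
the field, however, organisms are rarely exposed to a toxicant alone: food
limitation, competition, predator cues, UV, oxygen deficits and similar
environmental stressors act at the same time. Experiments that run the same
concentration series with and without such a stressor consistently find
that the environmental stressor *sensitises* the population: the lethal
concentration with stress, LCx\*, can sit one to two orders of magnitude
below the LCx without stress, even when the environmental stressor alone
causes little or no measurable mortality. Classical mixture-toxicity
baselines do not capture this: effect addition (Bliss independence)
predicts no change of toxicant sensitivity at all, and concentration
addition predicts only a modest change.

`samtox` implements a stress-addition model (SAM) of this synergy, the two
classical baselines it is compared against, the dose-response machinery the
comparison needs, a meta-analysis layer that calibrates the model against a
collection of paired studies, and a synthetic-data generator that produces
such collections with known ground truth.

## The model

**Stress capacity.** Every individual is assumed to have a *general stress
capacity* — a tolerance towards all kinds of stress — distributed across
the population as a Beta(p, q) random variable on [0, 1]. An individual
dies when the total general stress it experiences exceeds its capacity, so
the population survival under total stress $S$ is

$$N(S) = 1 - F_{p,q}(S),$$

with $F_{p,q}$ the beta distribution function, $N(0) = 1$ and $N(S) = 0$
for $S \ge 1$. Symmetry of the capacity distribution is postulated
($p = q$); the shape is a free parameter calibrated from data (see below),
with the calibrated default $p = q = 3.2$.

**Common currency.** Each stressor is converted to a general stress level
through the mortality it causes on its own: a stressor that alone kills a
fraction $m$ of the population exerts the general stress
$S = F_{p,q}^{-1}(m)$, the $m$-quantile of the capacity distribution. This
is the only link between the physical dose scale (µg/L, °C, ...) and the
stress scale, which is what makes stressors of entirely different kinds
commensurable.

**Additivity.** General stress levels of independently acting stressors
add: $S = \sum_i S_i$. The combined mortality is then
$F_{p,q}(\sum_i F_{p,q}^{-1}(m_i))$. Because the quantile function is
steep near 0, small mortalities convert to disproportionally large stress
levels — this is the mechanism behind the predicted synergy: 10% and 15%
mortality convert to stresses of roughly 0.25 and 0.30, which together
yield about 60% combined mortality rather than the ~24% of Bliss
independence.

```{r}
dist <- stress_capacity(3.2)
sam_combined_mortality(dist, c(0.10, 0.15))
ea_combined_mortality(c(0.10, 0.15))
```

**Reporting resolution.** The worked example published with the model
quotes the two stress levels as 0.26 and 0.30. Those values correspond to
tabulating the capacity distribution on a 0.01 stress grid and reporting
the smallest grid level whose cumulative mortality reaches the observed
one — the convention of the original spreadsheet calculator. The package's
core transfer is the exact continuous quantile (0.254 and 0.296 here); the
grid convention is available as
`mortality_to_stress(dist, m, resolution = 0.01)` and is used when
reproducing the published example. With it, the combined mortality of the
example evaluates to 61.5% (the published text rounds to 61.6%).

```{r}
mortality_to_stress(dist, c(0.10, 0.15), resolution = 0.01)
100 * sam_combined_mortality(dist, c(0.10, 0.15), resolution = 0.01)
```

## Dose-response machinery

Concentration-response curves are modelled with the five-parameter
log-logistic function

$$N(C) = c + \frac{d - c}{\bigl(1 + e^{b(\ln C - \ln e)}\bigr)^{f}},$$

with shape $b > 0$, limits $0 \le c < d \le 1$, scale $e > 0$ and
asymmetry $f > 0$. Following standard acute-bioassay practice the lower
limit is fixed to 0 and the upper limit to the control response, so
mortality is always control-normalised (Abbott-corrected):
`effect_mortality()` returns $1 - N(C)/d$, and `lc()` inverts it in closed
form.

Two pre-processing steps precede fitting, in this order:

1. **Williams transformation** (`williams_transform()`): apparent hormesis
   — survival increasing again at low concentrations — is averaged out by
   pooling adjacent violators of the expected non-increasing trend into
   their weighted means (isotonic regression in the downhill direction,
   weighted by organism counts when available).
2. **Log-scale interpolation** (`interpolate_log()`): 10 points equidistant
   in log-concentration, linearly interpolated, stabilise the fit when only
   a few concentrations show a partial response (the typical situation in
   the literature data the model was built for). The control is excluded
   from the interpolation — its log-concentration is undefined — and enters
   only through the fixed upper limit.

Fitting (`fit_ll5()`) is multi-start Levenberg–Marquardt least squares:
the scale parameter starts at the concentration nearest half-maximal
effect, the shape and asymmetry parameters on the coarse grid
$b \in \{0.5, 1, 2, 4\}$, $f \in \{0.5, 1, 2\}$; parameters are bounded
below at $10^{-6}$ and convergence tolerances are $10^{-10}$ on objective
and parameters. The returned solution is never worse than any grid start.
Flat responses raise a degenerate-data error rather than returning an
arbitrary curve.

## Shifts, baselines and conventions

The sensitivity shift of a study is LCx/LCx\*: the factor by which the
environmental stressor lowers the concentration needed for an x%
mortality. Three models predict it:

* **SAM** (`sam_lcx_shift()`): LCx\* solves
  $F(F^{-1}(m_{env}) + F^{-1}(\text{eff}(C))) = x/100$. The inversion has
  a closed form through the quantile difference
  $\text{eff}(LCx^*) = F(F^{-1}(x/100) - F^{-1}(m_{env}))$, which the
  package uses directly (a bracketed root-finder would add nothing but
  iteration error; the test suite checks the closed form against
  brute-force grid inversion).
* **CA** (`ca_lcx_shift()`): the environmental mortality is mapped to its
  equivalent concentration on the common curve and subtracted,
  $LCx^* = \text{lc}(x) - C_{eq}$.
* **EA**: the toxicant curve is unchanged by definition; the shift is
  identically 1.

Effect levels are taken on the *unstressed-control* mortality scale
throughout: an effect level x is reachable only when $x/100 > m_{env}$
(the environmental stress alone must not already exceed it), and
unreachable study/level combinations are flagged and excluded rather than
extrapolated. An alternative convention renormalises the combined arm to
its own control, which keeps every level reachable; it is not used here
because it breaks the correspondence with `sam_lcx_shift()` and the
self-consistency of the calibration below.

## Meta-analysis layer

**Normalisation and averaging.** To compare curves across studies with
different toxicants and units, each fitted toxicant-alone curve is
restricted to its LC1–LC99 range and that concentration interval is mapped
linearly onto [0, 1] (`normalize_curve()`). The linear (not logarithmic)
map is deliberate: it produces the strongly right-skewed normalised curve —
most of the mortality increase happens at small normalised concentrations —
that (i) matches the published worked example, in which a 10% mortality
corresponds to a normalised concentration near 0.1, and (ii) is the shape
under which the stress-addition prediction dominates the concentration-
addition one; under a logarithmic map the normalised curves become near-
symmetric and the model ordering inverts, contradicting the headline
comparison. `average_curves()` takes the median and standard error of
survival across studies at 10 equidistant levels (endpoints included) and
refits the LL.5 model to the median and to median ± SE; the two band fits
propagate between-study spread into the overall predictions
(`overall_prediction()`).

**Calibration.** `calibrate_shape()` finds the symmetric shape $p = q$
minimising the sum of squared differences between observed and predicted
shifts on the log10 scale (shifts span orders of magnitude, so a raw-scale
objective would be dominated by the largest shifts; goodness of fit
`model_r2()` is reported on the log10 scale for the same reason, with the
raw-scale value available for comparison). Studies with zero environmental
mortality carry no information about the shape and are excluded, as are
study/level combinations whose effect level is unreachable.

Predicted shifts inside the calibration are computed *through the same
fitting pipeline as the observed ones* (`predicted_shift()`): the
SAM-predicted combined response is sampled at the study's own design
concentrations, refitted with the LL.5 model and the same pre-processing,
and LCx\* is extracted identically. This matters because the SAM-combined
curve is not itself a log-logistic function: refitting it with LL.5
misplaces LCx\* by up to tens of percent depending on the stress level, a
systematic distortion that affects observed and predicted arms alike and
therefore cancels when both go through it. With closed-form predictions
instead, that distortion becomes bias: on noise-free synthetic data the
calibrated shape lands 10–25% below the generating value, while the
pipeline-matched comparison recovers it essentially exactly. The
closed-form route remains available (`method = "closed_form"`).

The optimiser is a deterministic coarse grid (step 0.1 on [1, 20]) with
Brent refinement around the best grid point — the objective is cheap,
one-dimensional, and not guaranteed unimodal, so a grid is the robust
choice.

## Synthetic data

`sim_config()` / `generate_meta_dataset()` emulate the structure of the
paired-study literature behind the model: by default 23 study pairs,
heterogeneous true LL.5 curves (shape $b \in [0.8, 3]$, control response
$d \in [0.85, 1]$, scale $\log_{10} e \in [-1, 2]$, asymmetry
$f \in [0.5, 2]$), environmental mortalities uniform on [0.01, 0.45],
1000 organisms per treatment with binomial sampling noise, and combined
arms generated from the stress-addition ground truth with shape 3.2
(options `truth_model = "ca"`/`"ea"` generate from the baselines instead,
so tests can confirm the calibration distinguishes generating models).

Design choices worth stating explicitly:

* Each arm receives its own log-spaced concentration grid spanning that
  arm's 2%–99.5% effect range, mirroring the original inclusion criteria
  (every curve must show a control, a partial response and a near-complete
  kill). A shared grid spanning only the toxicant arm leaves the combined
  arm's transition unresolved and makes LCx\* an extrapolation.
* The default of 10 concentrations per arm coincides with the 10-point
  interpolation grid, so the smoothing step is value-preserving on
  generated designs and fits of noise-free data recover the generating
  parameters exactly.
* Every generator call threads an explicit seed and restores the caller's
  RNG state; a fixed seed makes the CSV serialisation byte-identical.

What the generator does **not** emulate: digitisation error of
figure-extracted data, hormesis (deliberately out of scope — the Williams
step removes it from real data), sublethal endpoints, time-resolved
mortality, and correlation between stressor tolerances. Passing tests on
synthetic data therefore demonstrate internal consistency of the pipeline
under the model's own assumptions, not the model's adequacy for any
particular real dataset.

## Numerical choices and degenerate inputs

* Beta distribution function and quantile come from R's `pbeta`/`qbeta`
  (regularised incomplete beta); the round trip is exact to well below
  $10^{-9}$.
* Total stress is stored uncapped; capping happens only in
  `survival_at_stress()` through the $S \ge 1$ convention.
* Quantiles at $m = 0$ and $m = 1$ return the support endpoints 0 and 1.
* `m_env = 1` (environmental stress alone kills everything) returns an
  all-zero prediction with a warning; $x/100 \le m_{env}$ raises an
  unreachable-effect-level error in shift functions and yields flagged
  rows in `overall_prediction()`.
* When the CA equivalent concentration reaches LCx the CA shift is
  reported unattainable rather than infinite.
* Fits of flat responses (no concentration effect) raise degenerate-data
  errors; fit failures carry the optimiser diagnostics.

## Problem sizes used in the checks

The packaged checks run the full pipeline at the default study conditions
(23 pairs, 10 concentrations per arm, 1000 organisms per treatment), use
$10^6$ agents for the individual-based cross-check of the survival
formula, and 200 replicates per setting for the sampling-noise scaling
check. A full shape calibration of a 23-pair dataset takes on the order of
tens of seconds on a single core; all other operations are effectively
instantaneous.

## Known limitations

* The LL.5 refit of a SAM-combined response is an approximation; absolute
  closed-form shifts and pipeline shifts can differ by tens of percent at
  extreme effect levels. Comparisons should stay within one route (the
  calibration does).
* The calibration assumes the symmetric capacity postulate $p = q$; the
  distribution object accepts $p \ne q$, but nothing in the package
  estimates asymmetric capacity.
* One environmental stressor per prediction is assumed in the high-level
  interfaces; the core combination functions accept any number of
  stressors.
* The published per-study goodness-of-fit values and the empirical
  regression lines of the original meta-analysis depend on digitised
  literature tables that are not redistributable; supplying such tables in
  the documented CSV schema reproduces the corresponding outputs.
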