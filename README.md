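# samtox — stress addition modelling of combined toxicant and environmental stress

Environmental stressors — food limitation, competition, predator cues, UV,
oxygen deficiency — can raise the sensitivity of aquatic organisms to
toxicants by up to two orders of magnitude, even when the stressor alone
causes little measurable mortality. The classical mixture-toxicity
baselines miss this synergy: effect addition (Bliss independence) predicts
no sensitivity change at all, and concentration addition only a modest one.
`samtox` is for ecotoxicologists and risk assessors who need a quantitative
prediction of such combined effects from standard acute-test data.

## The model

Each individual carries a *general stress capacity*, Beta(p, q)-distributed
on [0, 1]; it dies when the total general stress exceeds its capacity, so
population survival under total stress *S* is

    N(S) = 1 − F(S),        F = Beta(p, q) distribution function

A stressor that alone causes mortality *m* exerts the general stress
F⁻¹(m) (the *m*-quantile); stress levels of independent stressors add, and
the combined mortality is

    m_combined = F( Σᵢ F⁻¹(mᵢ) )

Because the quantile function is steep near zero, small mortalities convert
into disproportionally large stress levels — the source of the predicted
synergy. The symmetric shape p = q is calibrated against observed shifts of
the lethal concentrations LC10/LC50 between paired experiments run with
and without the environmental stressor (calibrated default p = q = 3.2).

Around this core the package provides five-parameter log-logistic
(LL.5) dose-response fitting with Williams-type monotonisation and
log-scale interpolation smoothing, closed-form LCx estimation, the effect-
addition and adapted concentration-addition baselines, the meta-analysis
layer (curve normalisation to LC1–LC99, median/SE averaging, shape
calibration, goodness of fit, overall shift-prediction tables), a
synthetic study-pair generator with known ground truth, and a command-line
tool (`exec/samtool`).

## Worked example

```r
library(samtox)
dist <- stress_capacity(3.2)

# 10% and 15% single-stressor mortality -> general stress levels
mortality_to_stress(dist, c(0.10, 0.15))
#> [1] 0.2541156 0.2964507

# stress adds; the beta CDF of the sum gives the combined mortality
sam_combined_mortality(dist, c(0.10, 0.15))
#> [1] 0.5974396

# Bliss effect addition predicts far less
ea_combined_mortality(c(0.10, 0.15))
#> [1] 0.235
```

About 60% combined mortality from two stressors that alone kill 10% and
15% — versus 23.5% under independence. (The published worked example
quotes the stress levels as 0.26/0.30 and the combined mortality as
~62%; that is the same computation at the 0.01-grid reporting resolution
of the original spreadsheet calculator, available via
`mortality_to_stress(..., resolution = 0.01)`.)

Sensitivity shifts on a toxicant curve (LL.5 with b = 1.5, e = 20,
f = 1.3) under an environmental stressor causing 10% mortality:

```r
curve <- ll5_params(b = 1.5, e = 20, f = 1.3)
sam_lcx_shift(dist, curve, m_env = 0.10, x = 50)   # SAM: LC50 drops 4.4-fold
#> [1] 4.388329
ca_lcx_shift(curve, m_env = 0.10, x = 50)          # CA: only 1.3-fold
#> [1] 1.321165
```

A synthetic meta-analysis with known ground truth, calibrated end to end:

```r
ds  <- generate_meta_dataset(sim_config(seed = 1, n_studies = 6))
cal <- calibrate_shape(ds$pairs)
cal
#> SAM shape calibration: p = q = 3.307
#>   residual sum of squares (log10 shifts): 0.03869 over 9 study-level terms
#>   variance explained (log10 shifts): LC10: 0.994, LC50: 0.957
#>   3 study/level terms excluded
```

The generator's true shape was 3.2; the calibration recovers 3.31 from six
noisy pairs (1000 organisms per treatment), and the excluded terms are
study/level combinations whose environmental mortality exceeds the effect
level (logged with reasons in `cal$excluded`).

The command-line tool mirrors this workflow:

```sh
samtool simulate --n-studies 23 --seed 1 --out data/
samtool fit       --input data/studies.csv --out results/
samtool calibrate --input data/studies.csv --out results/
samtool meta      --input data/studies.csv --out results/
```

See the vignette (`vignettes/stress-addition-model.Rmd`) for the model's
assumptions, the fitting and calibration conventions, and known
limitations.

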