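# Independent brute-force oracles used to cross-check closed-form and
# fitted results. These deliberately avoid the code paths they verify.

# Invert a monotone increasing function fn(C) on a log-concentration grid by
# iterative grid refinement (no algebraic inversion involved).
grid_invert <- function(fn, target, lower, upper, iters = 6L, n = 400L) {
  j <- NA_integer_
  g <- NULL
  for (i in seq_len(iters)) {
    g <- exp(seq(log(lower), log(upper), length.out = n))
    v <- vapply(g, fn, numeric(1))
    j <- which.min(abs(v - target))
    lower <- g[max(1L, j - 1L)]
    upper <- g[min(n, j + 1L)]
  }
  g[j]
}

# Brute-force LCx* of the SAM-combined response: scans concentrations for the
# point where the combined (control-normalised) mortality crosses x/100.
brute_force_sam_lcx_star <- function(dist, curve, m_env, x) {
  grid_invert(function(C)
    sam_combined_mortality(dist, c(m_env, effect_mortality(curve, C))),
    x / 100, lower = curve$e * 1e-8, upper = curve$e * 1e8)
}

# Reference monotonisation for unit weights: base-R isotonic regression run
# on the reversed sequence (isoreg fits non-decreasing).
isoreg_decreasing <- function(y) rev(stats::isoreg(rev(y))$yf)

# A small noise-free study pair from explicit ground truth, bypassing the
# random generator.
make_sam_pair <- function(curve, m_env, shape = 3.2, n_conc = 10L,
                          span = c(2, 99.5), id = "toy") {
  dist <- stress_capacity(shape)
  conc_tox <- exp(seq(log(lc(curve, span[1])), log(lc(curve, span[2])),
                      length.out = n_conc))
  comb_mort <- function(C)
    sam_combined_mortality(dist, c(m_env, effect_mortality(curve, C)))
  norm_target <- function(t) m_env + t * (1 - m_env)
  lo <- grid_invert(comb_mort, norm_target(span[1] / 100),
                    curve$e * 1e-10, curve$e * 1e6)
  hi <- grid_invert(comb_mort, norm_target(span[2] / 100),
                    curve$e * 1e-10, curve$e * 1e6)
  conc_comb <- exp(seq(log(lo), log(hi), length.out = n_conc))
  surv_comb <- vapply(conc_comb, function(C) curve$d * (1 - comb_mort(C)),
                      numeric(1))
  study_pair(id,
             dose_response_data(conc_tox, ll5_survival(curve, conc_tox),
                                control_survival = curve$d),
             dose_response_data(conc_comb, surv_comb,
                                control_survival = curve$d * (1 - m_env)))
}
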