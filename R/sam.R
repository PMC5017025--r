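#' Beta-distributed general stress capacity
#'
#' The SAM postulates that every individual has a general stress capacity —
#' a tolerance towards all types of stress — distributed over `[0, 1]`
#' following a beta distribution with shape parameters `p`, `q`. An
#' individual survives a total general stress `S` exactly when its capacity
#' exceeds `S`. The symmetry postulate sets `p = q`; the calibrated default
#' is `p = q = 3.2`.
#'
#' @param p First shape parameter, `> 0`.
#' @param q Second shape parameter, `> 0`; defaults to `p` (symmetric
#'   capacity distribution).
#'
#' @return An object of class `"stress_capacity"` with elements `p` and `q`.
#' @export
#' @examples
#' d <- stress_capacity(3.2)
#' survival_at_stress(d, 0.45)
stress_capacity <- function(p = 3.2, q = p) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 1L, length(q) == 1L)
  if (!is.finite(p) || p <= 0 || !is.finite(q) || q <= 0)
    stop("shape parameters p and q must be positive and finite", call. = FALSE)
  structure(list(p = p, q = q), class = "stress_capacity")
}

#' @export
print.stress_capacity <- function(x, ...) {
  cat(sprintf("General stress capacity ~ Beta(p = %.4g, q = %.4g)\n", x$p, x$q))
  invisible(x)
}

#' Population survival under a given total general stress
#'
#' The surviving fraction is the proportion of individuals whose stress
#' capacity exceeds the total stress: `1 - F(S)` with `F` the Beta(p, q)
#' distribution function. Boundary conventions: survival is 1 at `S = 0`
#' and 0 for `S >= 1` (total stress at or beyond the capacity support kills
#' the whole population).
#'
#' @param dist A [stress_capacity()] distribution.
#' @param S Numeric vector of general stress levels, `>= 0` (an uncapped
#'   sum of per-stressor stress levels is allowed).
#'
#' @return Survival fractions in `[0, 1]`, strictly decreasing on `(0, 1)`.
#' @export
survival_at_stress <- function(dist, S) {
  stopifnot(inherits(dist, "stress_capacity"))
  if (any(!is.finite(S) | S < 0)) stop("general stress must be finite and >= 0", call. = FALSE)
  1 - stats::pbeta(S, dist$p, dist$q)
}

#' Transfer an observed mortality into a general stress level
#'
#' The SAM's common currency: a stressor that alone causes mortality `m`
#' exerts the general stress given by the `m`-quantile of the capacity
#' distribution (the stress level at which exactly a fraction `m` of
#' individuals has a smaller capacity). This is the inverse of
#' `1 - survival_at_stress()` on `(0, 1)`; the endpoints map to the support
#' endpoints 0 and 1.
#'
#' `resolution` reproduces the discretised transfer of the original
#' spreadsheet implementation of the model, which tabulated the distribution
#' on a fixed stress grid: the reported stress is the smallest multiple of
#' `resolution` at which the cumulative mortality reaches `m` (so e.g. with
#' `resolution = 0.01`, a 10% mortality maps to 0.26 rather than the
#' continuous quantile 0.254). The continuous quantile (`resolution = NULL`)
#' is the default and is used throughout fitting and calibration.
#'
#' @param dist A [stress_capacity()] distribution.
#' @param m Mortality fraction(s) in `[0, 1]`.
#' @param resolution Optional stress-grid step for the discretised reporting
#'   convention; `NULL` (default) for the exact quantile.
#'
#' @return General stress level(s) in `[0, 1]`, monotone increasing in `m`.
#' @export
#' @examples
#' mortality_to_stress(stress_capacity(3.2), c(0.10, 0.15))
#' mortality_to_stress(stress_capacity(3.2), c(0.10, 0.15), resolution = 0.01)
mortality_to_stress <- function(dist, m, resolution = NULL) {
  stopifnot(inherits(dist, "stress_capacity"))
  if (any(!is.finite(m) | m < 0 | m > 1))
    stop("mortality must lie in [0, 1]", call. = FALSE)
  s <- stats::qbeta(m, dist$p, dist$q)
  if (!is.null(resolution)) {
    stopifnot(is.numeric(resolution), length(resolution) == 1L,
              resolution > 0, resolution < 1)
    s <- ceiling(s / resolution - 1e-9) * resolution
  }
  s
}

#' Total general stress of independent stressors
#'
#' General stress levels of independently acting stressors are additive;
#' the arithmetic sum determines the total stress exerted on the
#' population. The sum is returned uncapped — values `>= 1` simply mean
#' total mortality once passed to [survival_at_stress()].
#'
#' @param stresses Numeric vector of general stress levels, each `>= 0`.
#' @return The sum (0 for an empty vector).
#' @export
#' @examples
#' add_stress(c(0.2, 0.25))  # 0.45
add_stress <- function(stresses) {
  if (length(stresses) == 0L) return(0)
  if (any(!is.finite(stresses) | stresses < 0))
    stop("general stress levels must be finite and >= 0", call. = FALSE)
  sum(stresses)
}

#' SAM-combined mortality of independent stressors
#'
#' Converts each single-stressor mortality to a general stress level via
#' the beta quantile, adds the stress levels, and evaluates the beta
#' distribution function at the total:
#' `F(sum_i F^{-1}(m_i))`. The result is symmetric in its arguments, equals
#' `m` when combined with a zero mortality, and reaches 1 once the total
#' stress is `>= 1`.
#'
#' @param dist A [stress_capacity()] distribution.
#' @param mortalities Vector of single-stressor mortality fractions in
#'   `[0, 1]` (control-normalised).
#' @inheritParams mortality_to_stress
#'
#' @return Combined mortality fraction in `[0, 1]`, `>= max(mortalities)`.
#' @export
#' @examples
#' sam_combined_mortality(stress_capacity(3.2), c(0.10, 0.15))
sam_combined_mortality <- function(dist, mortalities, resolution = NULL) {
  S <- add_stress(mortality_to_stress(dist, mortalities, resolution = resolution))
  1 - survival_at_stress(dist, S)
}

#' SAM prediction of a concentration-response curve under environmental stress
#'
#' Predicts the absolute survival of a population exposed to a toxicant
#' (described by its LL.5 curve fitted without environmental stress) plus an
#' environmental stressor that alone causes mortality `m_env`. Per
#' concentration the control-normalised toxicant mortality is transferred to
#' general stress, added to the environmental stress level, and the
#' resulting survival is scaled back to the absolute scale by the control
#' response `d` of the toxicant curve.
#'
#' @param dist A [stress_capacity()] distribution.
#' @param tox_curve LL.5 parameters of the toxicant-alone curve.
#' @param m_env Environmental-stress-only mortality fraction in `[0, 1)`
#'   (control-normalised). `m_env = 1` returns zeros with a warning.
#' @param concentrations Concentrations at which to predict.
#'
#' @return Numeric vector of predicted absolute survival fractions,
#'   non-increasing in concentration; at `C = 0` it equals the
#'   environmental-stress-only survival `d * (1 - m_env)`.
#' @export
predict_combined_curve <- function(dist, tox_curve, m_env, concentrations) {
  tox_curve <- as_ll5(tox_curve)
  stopifnot(is.numeric(m_env), length(m_env) == 1L, m_env >= 0, m_env <= 1)
  if (m_env == 1) {
    warning("m_env = 1: environmental stress alone kills the whole population")
    return(rep(0, length(concentrations)))
  }
  s_env <- mortality_to_stress(dist, m_env)
  s_tox <- mortality_to_stress(dist, effect_mortality(tox_curve, concentrations))
  tox_curve$d * survival_at_stress(dist, s_env + s_tox)
}

#' SAM-predicted shift of the lethal concentration LCx
#'
#' The sensitivity shift `LCx / LCx*`: the factor by which the additional
#' environmental stressor lowers the toxicant concentration needed for an
#' `x`% control-normalised mortality. `LCx*` solves
#' `sam_combined_mortality(m_env, effect_mortality(C)) = x/100`, which
#' inverts in closed form through the quantile difference
#' `effect_mortality(LCx*) = F(F^{-1}(x/100) - F^{-1}(m_env))`.
#'
#' @inheritParams predict_combined_curve
#' @param x Effect level in percent; must exceed `100 * m_env`, otherwise
#'   the environmental stress alone already exceeds the effect level and
#'   `LCx*` is undefined.
#'
#' @return The shift factor `LCx / LCx*`, `>= 1`, equal to 1 at
#'   `m_env = 0` and strictly increasing in `m_env`.
#' @export
sam_lcx_shift <- function(dist, tox_curve, m_env, x) {
  tox_curve <- as_ll5(tox_curve)
  stopifnot(is.numeric(m_env), length(m_env) == 1L, m_env >= 0, m_env < 1,
            is.numeric(x), length(x) == 1L, x > 0, x < 100)
  if (x / 100 <= m_env)
    stop(sprintf(paste0("effect level unreachable: x/100 = %.3g does not exceed ",
                        "the environmental mortality m_env = %.3g"), x / 100, m_env),
         call. = FALSE)
  lcx <- lc(tox_curve, x)
  m_star <- 1 - survival_at_stress(
    dist, mortality_to_stress(dist, x / 100) - mortality_to_stress(dist, m_env))
  if (m_star <= 0) return(Inf)
  lcx_star <- lc(tox_curve, 100 * m_star)
  lcx / lcx_star
}
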