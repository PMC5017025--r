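#' Effect addition (Bliss independence) combined mortality
#'
#' The classical independent-action baseline: the combined effect of
#' stressors with single effects `E_i` is `1 - prod(1 - E_i)`. Under effect
#' addition the toxicant's concentration-response curve is unchanged by the
#' environmental stressor, so EA predicts no shift of population
#' sensitivity.
#'
#' @param mortalities Vector of mortality fractions in `[0, 1]`.
#' @return Combined mortality in `[0, 1]`, symmetric, `>= max(mortalities)`.
#' @export
#' @examples
#' ea_combined_mortality(c(0.10, 0.15))  # 0.235
ea_combined_mortality <- function(mortalities) {
  if (length(mortalities) == 0L) return(0)
  if (any(!is.finite(mortalities) | mortalities < 0 | mortalities > 1))
    stop("mortalities must lie in [0, 1]", call. = FALSE)
  1 - prod(1 - mortalities)
}

#' Concentration equivalent of an environmental-stress mortality
#'
#' The adapted concentration-addition baseline treats the environmental
#' stressor as if it acted through the same stress-response relationship as
#' the toxicant: a stress causing mortality `m` is assigned the
#' concentration at which the common curve yields mortality `m`
#' (`lc(curve, 100 m)`); `m = 0` maps to concentration 0 by convention.
#'
#' @param curve LL.5 parameters of the designated common curve (for the
#'   meta-analysis, the averaged normalised curve).
#' @param m Mortality fraction, attainable on the curve.
#' @return The equivalent concentration, monotone in `m`.
#' @export
ca_equivalent_concentration <- function(curve, m) {
  curve <- as_ll5(curve)
  stopifnot(is.numeric(m), length(m) == 1L)
  if (!is.finite(m) || m < 0 || m >= 1)
    stop("mortality must lie in [0, 1)", call. = FALSE)
  if (m == 0) return(0)
  lc(curve, 100 * m)
}

#' Adapted concentration-addition combined mortality
#'
#' Converts the environmental-stress mortality to its equivalent
#' concentration on the common curve, adds the toxicant concentration, and
#' reads the mortality of the summed dose off the same curve. Two doses of
#' the same toxicant combined this way reproduce the curve at the summed
#' dose (sham-combination consistency).
#'
#' @inheritParams ca_equivalent_concentration
#' @param m_env Environmental-stress-only mortality fraction.
#' @param C_tox Toxicant concentration (same axis as the common curve).
#' @return Combined mortality fraction; at `m_env = 0` the curve's own
#'   mortality at `C_tox`.
#' @export
ca_combined_mortality <- function(curve, m_env, C_tox) {
  curve <- as_ll5(curve)
  effect_mortality(curve, ca_equivalent_concentration(curve, m_env) + C_tox)
}

#' Concentration-addition predicted shift of the lethal concentration LCx
#'
#' Under the adapted CA baseline the combined response at toxicant
#' concentration `C` equals the common curve at `C_env_eq + C`, so the
#' concentration reaching an `x`% effect is `LCx* = lc(x) - C_env_eq` and
#' the sensitivity shift is `LCx / (LCx - C_env_eq)`.
#'
#' @inheritParams ca_combined_mortality
#' @param x Effect level in percent; the equivalent concentration must stay
#'   below `lc(curve, x)`, otherwise the environmental stress alone already
#'   exceeds the effect level and the shift is unattainable.
#' @return Shift factor `>= 1`; exactly 1 at `m_env = 0`.
#' @export
ca_lcx_shift <- function(curve, m_env, x) {
  curve <- as_ll5(curve)
  stopifnot(is.numeric(x), length(x) == 1L, x > 0, x < 100)
  c_eq <- ca_equivalent_concentration(curve, m_env)
  lcx <- lc(curve, x)
  if (c_eq >= lcx)
    stop(sprintf(paste0("effect level unreachable: the environmental-stress ",
                        "equivalent concentration %.6g is not below LC%g = %.6g"),
                 c_eq, x, lcx), call. = FALSE)
  lcx / max(lcx - c_eq, .Machine$double.eps * lcx)
}
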