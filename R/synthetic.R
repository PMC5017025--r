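# Seed handling: every generator call threads an explicit seed and restores
# the caller's RNG state on exit, so the package never leaks global state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic study-pair generator
#'
#' Defines the study conditions under which synthetic meta-datasets are
#' generated. The defaults emulate the structure of the 23 literature study
#' pairs behind the model's calibration: binomially sampled survival around
#' a true LL.5 toxicant curve, a combined arm that follows the stress-
#' addition ground truth with shape `p = q = 3.2`, heterogeneous curve
#' parameters across studies, and environmental-stress mortalities spread
#' over the observed range.
#'
#' @param seed Integer seed; a fixed seed makes the generated dataset (and
#'   its CSV serialisation) byte-identical across calls.
#' @param n_studies Number of study pairs (default 23).
#' @param organisms_per_concentration Binomial denominator per treatment
#'   (default 1000).
#' @param n_concentrations Concentrations per arm (default 10, log-spaced; this
#'   matches the 10-point log-interpolation grid of the fitting pipeline, so
#'   pre-processing is value-preserving on generated designs).
#' @param lc_span Effect-percent span of the log-spaced concentration grid
#'   (default `c(2, 99.5)`), guaranteeing partial-response and
#'   near-complete-kill concentrations as the original inclusion criteria
#'   require.
#' @param true_shape Shape `p = q` of the generating stress-capacity
#'   distribution (default 3.2).
#' @param env_mortality_range Environmental-stress mortalities are drawn
#'   uniformly from this interval (default `c(0.01, 0.45)`), mirroring the
#'   spread of environmental stress levels across the literature studies.
#' @param curve_prior Ranges of the generating LL.5 parameters: a list with
#'   `b`, `d`, `log10_e`, `f`, each a length-2 interval.
#' @param noise `"binomial"` (default) or `"none"` (exact curve values).
#' @param truth_model Generating model for the combined arm: `"sam"`
#'   (default), `"ca"`, or `"ea"` — the latter two let tests confirm the
#'   calibration distinguishes generating models.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_studies = 23L,
                       organisms_per_concentration = 1000L,
                       n_concentrations = 10L, lc_span = c(2, 99.5),
                       true_shape = 3.2, env_mortality_range = c(0.01, 0.45),
                       curve_prior = list(b = c(0.8, 3), d = c(0.85, 1),
                                          log10_e = c(-1, 2), f = c(0.5, 2)),
                       noise = c("binomial", "none"),
                       truth_model = c("sam", "ca", "ea")) {
  noise <- match.arg(noise)
  truth_model <- match.arg(truth_model)
  stopifnot(n_studies >= 0, organisms_per_concentration >= 1,
            n_concentrations >= 3, length(lc_span) == 2L,
            lc_span[1] > 0, lc_span[2] < 100, lc_span[1] < lc_span[2],
            true_shape > 0,
            length(env_mortality_range) == 2L,
            env_mortality_range[1] >= 0, env_mortality_range[2] <= 0.5,
            all(c("b", "d", "log10_e", "f") %in% names(curve_prior)))
  structure(list(seed = as.integer(seed), n_studies = as.integer(n_studies),
                 organisms_per_concentration = as.integer(organisms_per_concentration),
                 n_concentrations = as.integer(n_concentrations),
                 lc_span = lc_span, true_shape = true_shape,
                 env_mortality_range = env_mortality_range,
                 curve_prior = curve_prior, noise = noise,
                 truth_model = truth_model),
            class = "sim_config")
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

# Combined-arm absolute survival under the generating model.
truth_combined_survival <- function(model, dist, params, m_env, conc) {
  m_tox <- effect_mortality(params, conc)
  m_comb <- switch(model,
    sam = vapply(m_tox, function(m)
      sam_combined_mortality(dist, c(m_env, m)), numeric(1)),
    ea = vapply(m_tox, function(m)
      ea_combined_mortality(c(m_env, m)), numeric(1)),
    ca = vapply(conc, function(C)
      min(1, max(0, ca_combined_mortality(params, m_env, C))), numeric(1)))
  params$d * (1 - m_comb)
}

# Concentration at which the combined arm reaches a given mortality relative
# to its own (environment-only) control. Used to lay out a design that gives
# the combined arm a partial response too, as the original study-inclusion
# criteria require of both arms.
combined_arm_lc <- function(model, dist, params, m_env, x) {
  target <- x / 100
  norm_mort <- function(C) {
    s_abs <- truth_combined_survival(model, dist, params, m_env, C)
    (1 - s_abs / (params$d * (1 - m_env)) - target)
  }
  hi <- lc(params, 99.9)
  lo <- hi * 1e-8
  if (norm_mort(lo) >= 0) return(lo)
  stats::uniroot(norm_mort, c(lo, hi), tol = 1e-12)$root
}

#' Generate one synthetic study pair with known ground truth
#'
#' Draws a true LL.5 toxicant curve and environmental-stress mortality from
#' the configured priors, lays a log-spaced concentration grid across the
#' configured LCx span of the true curve, and samples survived counts
#' binomially (or takes exact probabilities with `noise = "none"`) for the
#' toxicant-alone arm, the combined arm (following the configured
#' ground-truth model), and both controls.
#'
#' @param config A [sim_config()].
#' @param study_id Label for the pair.
#' @param seed Optional seed overriding `config$seed` for this pair.
#'
#' @return A [study_pair()] with an attribute `"truth"`: a list with the
#'   generating `params`, `m_env`, `shape`, and `truth_model`.
#' @export
generate_study_pair <- function(config, study_id = "S1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed, generate_study_pair_impl(config, study_id))
}

generate_study_pair_impl <- function(config, study_id) {
  pr <- config$curve_prior
  n <- config$organisms_per_concentration
  dist <- stress_capacity(config$true_shape)
  for (attempt in 1:10) {
    params <- ll5_params(b = runif_range(pr$b), c = 0, d = runif_range(pr$d),
                         e = 10^runif_range(pr$log10_e), f = runif_range(pr$f))
    m_env <- runif_range(config$env_mortality_range)
    # each arm gets a log-spaced grid spanning its OWN partial-response
    # range (the original inclusion criteria require a partial response and
    # a near-complete kill in each of the two curves)
    grids <- try({
      conc_tox <- exp(seq(log(lc(params, config$lc_span[1])),
                          log(lc(params, config$lc_span[2])),
                          length.out = config$n_concentrations))
      lo <- combined_arm_lc(config$truth_model, dist, params, m_env,
                            config$lc_span[1])
      hi <- combined_arm_lc(config$truth_model, dist, params, m_env,
                            config$lc_span[2])
      conc_comb <- exp(seq(log(lo), log(hi),
                           length.out = config$n_concentrations))
      list(tox = conc_tox, comb = conc_comb)
    }, silent = TRUE)
    if (inherits(grids, "try-error") ||
        any(!is.finite(c(grids$tox, grids$comb)))) next
    conc <- grids$tox
    conc_comb <- grids$comb

    p_tox <- ll5_survival(params, conc)
    p_comb <- truth_combined_survival(config$truth_model, dist, params,
                                      m_env, conc_comb)
    p_ctrl <- params$d
    p_env <- params$d * (1 - m_env)
    if (config$noise == "binomial") {
      draw <- function(p) stats::rbinom(length(p), n, p)
      tox_arm <- dose_response_data(conc, n_total = rep(n, length(conc)),
                                    n_survived = draw(p_tox),
                                    control_survival = draw(p_ctrl) / n,
                                    control_n = n)
      combined_arm <- dose_response_data(conc_comb,
                                         n_total = rep(n, length(conc_comb)),
                                         n_survived = draw(p_comb),
                                         control_survival = draw(p_env) / n,
                                         control_n = n)
    } else {
      tox_arm <- dose_response_data(conc, p_tox, control_survival = p_ctrl)
      combined_arm <- dose_response_data(conc_comb, p_comb,
                                         control_survival = p_env)
    }
    pair <- study_pair(study_id, tox_arm, combined_arm)
    attr(pair, "truth") <- list(params = params, m_env = m_env,
                                shape = config$true_shape,
                                truth_model = config$truth_model)
    return(pair)
  }
  stop("could not generate a feasible study design in 10 attempts", call. = FALSE)
}

#' Generate a synthetic meta-dataset with a ground-truth manifest
#'
#' @param config A [sim_config()].
#' @return A list of class `"sam_meta_dataset"` with elements `pairs` (list
#'   of [study_pair()]s), `manifest` (a `data.frame` recording every
#'   generating parameter for recovery tests), and `config`.
#' @export
generate_meta_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  empty_manifest <- data.frame(study_id = character(), b = numeric(),
                               c = numeric(), d = numeric(), e = numeric(),
                               f = numeric(), m_env = numeric(),
                               shape = numeric(), truth_model = character())
  if (config$n_studies == 0L)
    return(structure(list(pairs = list(), manifest = empty_manifest,
                          config = config), class = "sam_meta_dataset"))
  pairs <- with_local_seed(config$seed, lapply(seq_len(config$n_studies),
    function(i) generate_study_pair_impl(config, sprintf("S%02d", i))))
  manifest <- do.call(rbind, lapply(pairs, function(p) {
    tr <- attr(p, "truth")
    data.frame(study_id = p$study_id, b = tr$params$b, c = tr$params$c,
               d = tr$params$d, e = tr$params$e, f = tr$params$f,
               m_env = tr$m_env, shape = tr$shape,
               truth_model = tr$truth_model)
  }))
  structure(list(pairs = pairs, manifest = manifest, config = config),
            class = "sam_meta_dataset")
}

#' @export
print.sam_meta_dataset <- function(x, ...) {
  cat(sprintf("Synthetic meta-dataset: %d study pairs (truth: %s, shape %.3g, noise %s)\n",
              length(x$pairs), x$config$truth_model, x$config$true_shape,
              x$config$noise))
  invisible(x)
}
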