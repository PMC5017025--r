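#' Fit a five-parameter log-logistic concentration-response curve
#'
#' Least-squares fit of the LL.5 model to observed survival, with the lower
#' limit `c` fixed to 0 and the upper limit `d` fixed to the control
#' response (both by default, as in standard acute-bioassay practice).
#' Optional pre-processing applies the Williams transformation and log-scale
#' interpolation smoothing before fitting, in that order.
#'
#' The optimisation is multi-start Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]): the scale parameter is initialised at the
#' observed concentration nearest 50% effect and the shape and asymmetry
#' parameters on a coarse grid (`b` in 0.5/1/2/4, `f` in 0.5/1/2); the best
#' local solution is returned and is never worse than any grid start.
#' Parameters are bounded below at `1e-6`; convergence tolerances are
#' `1e-10` on the objective and the parameters.
#'
#' @param data A [dose_response_data()] object.
#' @param fix_c,fix_d Fix the lower limit to 0 and the upper limit to the
#'   control survival (defaults `TRUE`). When freed, the limits are
#'   box-constrained to `[0, 1]`.
#' @param williams Apply [williams_transform()] first (default `FALSE`; the
#'   meta-analysis pipeline turns it on).
#' @param interpolate `NULL` for no smoothing, or the number of points for
#'   [interpolate_log()].
#' @param start Optional named vector of free parameters (`b`, `e`, `f`,
#'   plus `c`/`d` when freed) used as an additional warm start.
#' @param multistart When `FALSE` (and `start` is given) only the warm
#'   start is used — the fast path for refitting predicted curves that are
#'   close to an already-fitted one.
#'
#' @return An object of classes `"ll5_fit"` and `"ll5"`: the fitted
#'   parameters with attributes `rss` (residual sum of squares), `n_points`,
#'   and `convergence` diagnostics.
#' @export
fit_ll5 <- function(data, fix_c = TRUE, fix_d = TRUE,
                    williams = FALSE, interpolate = NULL,
                    start = NULL, multistart = TRUE) {
  stopifnot(inherits(data, "dose_response_data"))
  if (williams) data$survival <- williams_transform(data$survival, data$weights)
  if (!is.null(interpolate)) data <- interpolate_log(data, interpolate)
  conc <- data$concentrations
  surv <- data$survival
  if (length(conc) < 3L) stop("need at least 3 usable points to fit LL.5", call. = FALSE)
  d0 <- data$control_survival
  if (d0 <= 0) stop("degenerate data: control survival must be > 0", call. = FALSE)
  if (diff(range(c(surv, d0))) < 1e-8)
    stop("degenerate data: no concentration effect (flat response)", call. = FALSE)

  free <- c(b = TRUE, c = !fix_c, d = !fix_d, e = TRUE, f = TRUE)
  fixed <- c(b = NA_real_, c = 0, d = d0, e = NA_real_, f = NA_real_)
  assemble <- function(par) {
    full <- fixed
    full[names(par)] <- par
    full
  }
  resid_fun <- function(par) {
    p <- assemble(par)
    if (p[["c"]] >= p[["d"]]) return(rep(1e6, length(surv)))
    z <- exp(p[["b"]] * (log(conc) - log(p[["e"]])))
    surv - (p[["c"]] + (p[["d"]] - p[["c"]]) / (1 + z)^p[["f"]])
  }

  # initial scale: concentration nearest half-maximal observed effect
  eff <- pmax(0, 1 - surv / d0)
  target <- if (max(eff) >= 0.5) 0.5 else max(eff) / 2
  e0 <- conc[which.min(abs(eff - target))]
  starts <- expand.grid(b = c(0.5, 1, 2, 4), f = c(0.5, 1, 2))

  lower <- c(b = 1e-6, c = 0, d = 1e-6, e = 1e-6, f = 1e-6)[free]
  upper <- c(b = Inf, c = 1, d = 1, e = Inf, f = Inf)[free]
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)

  start_list <- list()
  if (!is.null(start)) {
    par0 <- c(b = 1, c = 0, d = d0, e = e0, f = 1)[names(free)[free]]
    par0[names(start)[names(start) %in% names(par0)]] <-
      start[names(start) %in% names(par0)]
    start_list[[1L]] <- pmax(par0, 1e-6)
  }
  if (multistart || length(start_list) == 0L)
    for (i in seq_len(nrow(starts))) {
      par0 <- c(b = starts$b[i], c = if (!fix_c) 0 else NULL,
                d = if (!fix_d) d0 else NULL, e = e0, f = starts$f[i])
      start_list[[length(start_list) + 1L]] <- par0[names(free)[free]]
    }

  best <- NULL
  diagnostics <- character()
  for (par0 in start_list) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                         fn = resid_fun, control = ctrl),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info,
                   message = fit$message)
  }
  if (is.null(best))
    stop("LL.5 fit failed to converge from every start; diagnostics: ",
         paste(unique(diagnostics), collapse = "; "), call. = FALSE)

  p <- assemble(best$par)
  params <- ll5_params(p[["b"]], p[["c"]], p[["d"]], p[["e"]], p[["f"]])
  structure(params,
            class = c("ll5_fit", "ll5"),
            rss = best$rss, n_points = length(conc),
            convergence = list(info = best$info, message = best$message))
}
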