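#' Observed concentration-response data for one experimental arm
#'
#' Bundles the observed survival of one experimental arm (toxicant alone, or
#' toxicant plus environmental stress) together with its control. Survival
#' can be given as fractions or as survived/total counts, in which case the
#' counts also serve as weights for the Williams transformation.
#'
#' @param concentrations Strictly increasing vector of non-negative toxicant
#'   concentrations (arbitrary but consistent units), excluding the control.
#'   A concentration of 0, if present, is split off as the control.
#' @param survival Survival fractions in `[0, 1]`, one per concentration.
#'   Omit when counts are given.
#' @param n_total,n_survived Integer counts per concentration; `survival` is
#'   derived as `n_survived / n_total`.
#' @param control_survival Survival fraction of the untreated (concentration
#'   0) control of this arm.
#' @param control_n Optional number of organisms in the control.
#'
#' @return An object of class `"dose_response_data"`: a list with elements
#'   `concentrations`, `survival`, `weights` (counts, or 1), and
#'   `control_survival`.
#' @export
dose_response_data <- function(concentrations, survival = NULL,
                               n_total = NULL, n_survived = NULL,
                               control_survival, control_n = NULL) {
  stopifnot(is.numeric(concentrations))
  if (is.null(survival)) {
    if (is.null(n_total) || is.null(n_survived))
      stop("provide either 'survival' or both 'n_total' and 'n_survived'", call. = FALSE)
    if (any(n_total <= 0) || any(n_survived < 0) || any(n_survived > n_total))
      stop("counts must satisfy 0 <= n_survived <= n_total, n_total > 0", call. = FALSE)
    survival <- n_survived / n_total
    weights <- as.numeric(n_total)
  } else {
    weights <- if (is.null(n_total)) rep(1, length(survival)) else as.numeric(n_total)
  }
  if (length(survival) != length(concentrations))
    stop("'survival' and 'concentrations' must have equal length", call. = FALSE)
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  survival <- survival[ord]
  weights <- weights[ord]
  if (concentrations[1L] == 0) {
    if (missing(control_survival)) control_survival <- survival[1L]
    concentrations <- concentrations[-1L]
    survival <- survival[-1L]
    weights <- weights[-1L]
  }
  if (any(concentrations <= 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (anyDuplicated(concentrations)) stop("concentrations must be unique", call. = FALSE)
  if (length(concentrations) < 2L)
    stop("need at least 2 distinct non-zero concentrations plus a control", call. = FALSE)
  if (any(survival < 0 | survival > 1) || control_survival < 0 || control_survival > 1)
    stop("survival values must lie in [0, 1]", call. = FALSE)
  structure(list(concentrations = concentrations, survival = survival,
                 weights = weights, control_survival = control_survival,
                 control_n = control_n),
            class = "dose_response_data")
}

#' @export
print.dose_response_data <- function(x, ...) {
  cat(sprintf("Concentration-response data: %d concentrations, control survival %.3f\n",
              length(x$concentrations), x$control_survival))
  print(data.frame(concentration = x$concentrations, survival = x$survival,
                   weight = x$weights), row.names = FALSE)
  invisible(x)
}

#' Williams transformation (monotonising pool-adjacent-violators)
#'
#' Enforces the expected non-increasing trend of survival with concentration
#' by pooling adjacent violating values into their (weighted) mean. This is
#' the classical isotonic-regression smoother applied in the non-increasing
#' direction, used to average out apparent hormesis before curve fitting.
#'
#' @param survival Survival fractions ordered by increasing concentration.
#' @param weights Optional positive weights (e.g. organism counts).
#'
#' @return Non-increasing numeric vector of the same length; the weighted
#'   mean of the input is preserved, and an already monotone input is
#'   returned unchanged.
#' @export
#' @examples
#' williams_transform(c(1, 0.8, 0.9, 0.5))  # pools (0.8, 0.9) into 0.85
williams_transform <- function(survival, weights = NULL) {
  n <- length(survival)
  if (n == 0L) stop("empty survival sequence", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("'weights' must be positive and match 'survival' in length", call. = FALSE)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- survival[i]; wt[k] <- weights[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] < val[k]) {
      tot <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / tot
      wt[k - 1L] <- tot
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], times = len[seq_len(k)])
}

#' Smooth a response by linear interpolation on a log-concentration scale
#'
#' Replaces the observed points by `k` points whose log-concentrations are
#' equidistant between the smallest and largest non-zero observed
#' concentrations, with survival linearly interpolated between neighbouring
#' observations in log-concentration space (via [stats::approx()]). This is
#' the smoothing step that stabilises the LL.5 fit when only a few
#' concentrations show a partial response. The control is passed through
#' unchanged; it does not take part in the interpolation because its
#' log-concentration is undefined.
#'
#' @param data A [dose_response_data()] object with at least 2 non-zero
#'   concentrations.
#' @param k Number of interpolation points, `>= 2` (default 10).
#'
#' @return A new [dose_response_data()] object on the interpolated grid
#'   (unit weights).
#' @export
interpolate_log <- function(data, k = 10L) {
  stopifnot(inherits(data, "dose_response_data"))
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (length(data$concentrations) < 2L)
    stop("need at least 2 non-zero concentrations to interpolate", call. = FALSE)
  lx <- log(data$concentrations)
  xout <- seq(lx[1L], lx[length(lx)], length.out = k)
  yout <- stats::approx(lx, data$survival, xout = xout, ties = "ordered")$y
  conc <- exp(xout)
  # guard against floating round-off collapsing the endpoints
  conc[1L] <- data$concentrations[1L]
  conc[k] <- data$concentrations[length(data$concentrations)]
  dose_response_data(conc, yout, control_survival = data$control_survival)
}
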