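#' Five-parameter log-logistic concentration-response parameters
#'
#' Constructs and validates the parameter set of the five-parameter
#' log-logistic (LL.5) concentration-response model
#' \deqn{N(C) = c + \frac{d - c}{\left(1 + \exp\{b(\ln C - \ln e)\}\right)^f}}
#' where `N` is the surviving fraction at toxicant concentration `C`.
#'
#' @param b Shape (slope) parameter, `> 0`. Larger values give a steeper curve.
#' @param c Lower survival limit, a fraction with `0 <= c < d`.
#' @param d Upper survival limit (the control response), a fraction `<= 1`.
#' @param e Scale parameter in concentration units, `> 0`. For a symmetric
#'   curve (`f = 1`) it is the concentration of half-maximal effect.
#' @param f Asymmetry parameter, `> 0`; `f = 1` gives the symmetric
#'   four-parameter log-logistic.
#'
#' @return An object of class `"ll5"`: a list with elements `b`, `c`, `d`,
#'   `e`, `f`.
#' @seealso [ll5_survival()], [effect_mortality()], [lc()], [fit_ll5()]
#' @export
#' @examples
#' p <- ll5_params(b = 1, e = 10)
#' ll5_survival(p, c(0, 10, 100))
ll5_params <- function(b, c = 0, d = 1, e, f = 1) {
  stopifnot(is.numeric(b), is.numeric(c), is.numeric(d), is.numeric(e),
            is.numeric(f), lengths(list(b, c, d, e, f)) == 1L)
  if (!is.finite(b) || b <= 0) stop("'b' must be a positive finite shape parameter", call. = FALSE)
  if (!is.finite(e) || e <= 0) stop("'e' must be a positive finite scale parameter", call. = FALSE)
  if (!is.finite(f) || f <= 0) stop("'f' must be a positive finite asymmetry parameter", call. = FALSE)
  if (c < 0 || d > 1 || c >= d)
    stop("limits must satisfy 0 <= c < d <= 1", call. = FALSE)
  structure(list(b = b, c = c, d = d, e = e, f = f), class = "ll5")
}

#' @export
print.ll5 <- function(x, ...) {
  cat("Five-parameter log-logistic curve\n")
  cat(sprintf("  b = %.6g, c = %.6g, d = %.6g, e = %.6g, f = %.6g\n",
              x$b, x$c, x$d, x$e, x$f))
  if (!is.null(attr(x, "rss")))
    cat(sprintf("  fit: RSS = %.6g on %d points\n",
                attr(x, "rss"), attr(x, "n_points")))
  invisible(x)
}

as_ll5 <- function(x) {
  if (inherits(x, "ll5")) return(x)
  if (is.list(x) && all(c("b", "c", "d", "e", "f") %in% names(x)))
    return(ll5_params(x$b, x$c, x$d, x$e, x$f))
  stop("cannot interpret object as LL.5 parameters", call. = FALSE)
}

#' Survival predicted by an LL.5 curve
#'
#' Evaluates the five-parameter log-logistic survival fraction at the given
#' concentrations. At `C = 0` the limit convention applies and the upper
#' limit `d` (the control response) is returned.
#'
#' @param params An [ll5_params()] object.
#' @param C Numeric vector of non-negative concentrations.
#'
#' @return Numeric vector of survival fractions in `[c, d]`, non-increasing
#'   in `C`.
#' @export
ll5_survival <- function(params, C) {
  params <- as_ll5(params)
  if (any(!is.finite(C) | C < 0)) stop("concentrations must be finite and >= 0", call. = FALSE)
  # log(0) = -Inf and exp(b * -Inf) = 0 give the C -> 0 limit d exactly
  z <- exp(params$b * (log(C) - log(params$e)))
  params$c + (params$d - params$c) / (1 + z)^params$f
}

#' Control-normalised mortality of an LL.5 curve
#'
#' Mortality relative to the control response (Abbott-style):
#' `1 - N(C) / d`. This is the effect scale on which stress levels are
#' compared and on which SAM's mortality-to-stress transfer operates.
#'
#' @inheritParams ll5_survival
#' @return Numeric vector of mortality fractions in `[0, 1]`, non-decreasing
#'   in `C`; 0 at `C = 0`.
#' @export
effect_mortality <- function(params, C) {
  params <- as_ll5(params)
  if (params$d <= 0) stop("degenerate curve: upper limit d must be > 0", call. = FALSE)
  1 - ll5_survival(params, C) / params$d
}

#' Lethal concentration LCx of an LL.5 curve
#'
#' Closed-form inversion of the LL.5 model: the concentration at which the
#' control-normalised mortality equals `x`/100.
#'
#' @inheritParams ll5_survival
#' @param x Effect level(s) in percent, in `(0, 100)`. Must be attainable,
#'   i.e. `x/100 < 1 - c/d`.
#'
#' @return Concentration(s) `C` with `effect_mortality(params, C) == x/100`,
#'   strictly increasing in `x`.
#' @export
#' @examples
#' lc(ll5_params(b = 1, e = 10), 50)  # 10
lc <- function(params, x) {
  params <- as_ll5(params)
  if (any(!is.finite(x) | x <= 0 | x >= 100))
    stop("effect level x must lie strictly between 0 and 100 percent", call. = FALSE)
  m <- x / 100
  ceiling_m <- 1 - params$c / params$d
  if (any(m >= ceiling_m))
    stop(sprintf("effect level unattainable: x/100 must be < 1 - c/d = %.6g", ceiling_m),
         call. = FALSE)
  ratio <- (params$d - params$c) / (params$d * (1 - m) - params$c)
  params$e * (ratio^(1 / params$f) - 1)^(1 / params$b)
}
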