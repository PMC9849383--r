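#' Moore-type double-exponential age-performance curve parameters
#'
#' Constructs a parameter quadruplet for the Moore family of
#' age-performance curves. Two orientations are supported:
#'
#' * `"minimize"` — the sign-adjusted form for lower-is-better scores
#'   (race points): \deqn{p(t) = a e^{-bt} + c e^{dt},}
#'   a U-shaped curve whose interior minimum is the performance peak.
#' * `"maximize"` — the classical form for higher-is-better scores:
#'   \deqn{p(t) = a (1 - e^{-bt}) + c (1 - e^{dt}),}
#'   an inverted-U whose interior maximum is the peak.
#'
#' In both orientations `a` governs the early (progression) phase, `c`
#' the late (decline) phase, and `b`, `d` are the corresponding rates.
#' Both curves share the same closed-form peak location
#' \eqn{t^* = \log(ab/(cd)) / (b + d)}.
#'
#' @param a,b,c,d Curve parameters. Rates `b` and `d` must be strictly
#'   positive; amplitudes `a` and `c` must be strictly positive for a
#'   well-defined interior peak.
#' @param orientation `"minimize"` (default, points-like scores) or
#'   `"maximize"`.
#' @return An object of class `"moore"`: a named list with elements
#'   `a`, `b`, `c`, `d`, `orientation`.
#' @seealso [moore_eval()], [moore_deriv()], [moore_peak()]
#' @examples
#' m <- moore(0.52, 2.32, 0.87, 0.18)
#' moore_peak(m)
#' @export
moore <- function(a, b, c, d, orientation = c("minimize", "maximize")) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1L, length(b) == 1L, length(c) == 1L, length(d) == 1L)
  if (!is.finite(a) || !is.finite(b) || !is.finite(c) || !is.finite(d))
    stop("Moore parameters must be finite")
  if (b <= 0 || d <= 0)
    stop("rates 'b' and 'd' must be strictly positive")
  structure(list(a = a, b = b, c = c, d = d, orientation = orientation),
            class = "moore")
}

#' @export
print.moore <- function(x, ...) {
  cat(sprintf("Moore curve (%s): a = %.6g, b = %.6g, c = %.6g, d = %.6g\n",
              x$orientation, x$a, x$b, x$c, x$d))
  pk <- tryCatch(moore_peak(x), error = function(e) NULL)
  if (!is.null(pk))
    cat(sprintf("  interior peak at t* = %.6g, p* = %.6g\n", pk[["t"]], pk[["p"]]))
  invisible(x)
}

as_moore <- function(x, orientation = "minimize") {
  if (inherits(x, "moore")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) == 4L)
  moore(x[1L], x[2L], x[3L], x[4L], orientation = orientation)
}

#' Evaluate a Moore curve on an age grid
#'
#' @param params A [moore()] object (or numeric quadruplet `c(a, b, c, d)`,
#'   taken in the minimizing orientation).
#' @param t Numeric vector of (standardized) ages.
#' @return Numeric vector of curve values, one per element of `t`.
#' @export
moore_eval <- function(params, t) {
  p <- as_moore(params)
  if (p$orientation == "minimize") {
    p$a * exp(-p$b * t) + p$c * exp(p$d * t)
  } else {
    p$a * (1 - exp(-p$b * t)) + p$c * (1 - exp(p$d * t))
  }
}

#' First derivative of a Moore curve
#'
#' The slope of the age-performance curve with respect to (standardized)
#' age; negative slopes mean improvement on a minimized score.
#'
#' @inheritParams moore_eval
#' @return Numeric vector of slopes, one per element of `t`.
#' @export
moore_deriv <- function(params, t) {
  p <- as_moore(params)
  if (p$orientation == "minimize") {
    -p$a * p$b * exp(-p$b * t) + p$c * p$d * exp(p$d * t)
  } else {
    p$a * p$b * exp(-p$b * t) - p$c * p$d * exp(p$d * t)
  }
}

#' Closed-form peak of a Moore curve
#'
#' Location and value of the interior extremum: the minimum of the
#' minimizing form, the maximum of the maximizing form. Both orientations
#' share \eqn{t^* = \log(ab/(cd)) / (b + d)} from the first-order
#' condition.
#'
#' @inheritParams moore_eval
#' @return Named numeric vector `c(t = ..., p = ...)`: peak age and peak
#'   value on the scale `params` is expressed in.
#' @export
moore_peak <- function(params) {
  p <- as_moore(params)
  if (p$a * p$b <= 0 || p$c * p$d <= 0)
    stop("no interior peak: a*b and c*d must both be strictly positive")
  tstar <- log((p$a * p$b) / (p$c * p$d)) / (p$b + p$d)
  c(t = tstar, p = moore_eval(p, tstar))
}
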