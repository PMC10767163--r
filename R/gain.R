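#' Deterministic reserve gain between breeding events
#'
#' Builds a gain model in which the reserves gained between breeding events
#' are a known function of time.  The default functional form is
#' \eqn{g(t) = a + b e^{-c t}} with \eqn{(a, b, c) = (0.32, 4, 0.5)}; any
#' other single-argument function of the period index can be supplied via
#' `fn`.  Negative values are clipped to 0 with a warning: gains are
#' resources.
#'
#' @param a,b,c Coefficients of the default exponential form.
#' @param fn Optional function `t -> g(t)` overriding the default form.
#' @return An object of class `"gain_model"` with `mode = "deterministic"`.
#' @examples
#' g <- gain_deterministic()
#' gain_at(g, 1)   # 0.32 + 4 * exp(-0.5)
#' @export
gain_deterministic <- function(a = 0.32, b = 4, c = 0.5, fn = NULL) {
  if (is.null(fn)) {
    force(a); force(b); force(c)
    fn <- function(t) a + b * exp(-c * t)
  } else if (!is.function(fn)) {
    stop("`fn` must be a function of t", call. = FALSE)
  }
  structure(list(mode = "deterministic", fn = fn),
            class = "gain_model")
}

#' Constant deterministic gain
#'
#' @param g The fixed per-period gain, `>= 0`.
#' @return A `"gain_model"` with `mode = "deterministic"`.
#' @export
gain_constant <- function(g) {
  if (g < 0) stop("`g` must be >= 0", call. = FALSE)
  gain_deterministic(a = g, b = 0, c = 0)
}

#' Stochastic reserve gain: discrete Gaussian on a bounded support
#'
#' The gain obtained at a breeding site is a random variable on the evenly
#' spaced support \eqn{g_n = g_{min} + (n/N)(g_{max} - g_{min})},
#' \eqn{n = 0, \ldots, N}, with a discrete Gaussian distribution
#' \deqn{p(g_n) = \frac{e^{-(g_n-\bar g)^2 / 2\sigma^2}}
#'                     {\sum_{m=0}^{N} e^{-(g_m-\bar g)^2 / 2\sigma^2}}.}
#' Because of the truncation and discretization, \eqn{\bar g} and
#' \eqn{\sigma} are only approximately the mean and standard deviation of
#' the resulting distribution.
#'
#' @param g_min,g_max Support bounds, `g_min < g_max`.
#' @param N Number of intervals (the support has `N + 1` points), `>= 1`.
#' @param g_bar Approximate mean gain.
#' @param sigma Approximate standard deviation, `> 0`.
#' @return A `"gain_model"` with `mode = "stochastic"` carrying `support`
#'   and `probs` (summing to 1).
#' @examples
#' g <- gain_stochastic(0, 1, N = 20, g_bar = 0.5, sigma = 0.4)
#' sum(g$probs)  # 1
#' @export
gain_stochastic <- function(g_min = 0, g_max = 1, N = 20, g_bar = 0.5,
                            sigma = 0.4) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("`N` must be an integer >= 1", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (g_min >= g_max) stop("need `g_min` < `g_max`", call. = FALSE)
  if (g_min < 0) stop("gains must be >= 0", call. = FALSE)
  support <- g_min + (0:N) / N * (g_max - g_min)
  w <- exp(-(support - g_bar)^2 / (2 * sigma^2))
  structure(list(mode = "stochastic", support = support, probs = w / sum(w),
                 g_min = g_min, g_max = g_max, N = as.integer(N),
                 g_bar = g_bar, sigma = sigma),
            class = "gain_model")
}

#' Degenerate (single-point) stochastic gain
#'
#' A stochastic gain model whose support is a single value received with
#' probability 1 -- the \eqn{\sigma \to 0} limit.  Useful for checking that
#' the stochastic solver collapses to the deterministic one.
#'
#' @param g The certain gain, `>= 0`.
#' @return A `"gain_model"` with `mode = "stochastic"` and one support
#'   point.
#' @export
gain_point <- function(g) {
  if (g < 0) stop("`g` must be >= 0", call. = FALSE)
  structure(list(mode = "stochastic", support = g, probs = 1,
                 g_min = g, g_max = g, N = 0L, g_bar = g, sigma = 0),
            class = "gain_model")
}

#' Evaluate a deterministic gain model at given times
#'
#' @param gain A `"gain_model"` with `mode = "deterministic"`.
#' @param t Period index(es), `>= 1`.
#' @return Gain value(s), clipped below at 0 (with a warning if clipping
#'   occurred).
#' @export
gain_at <- function(gain, t) {
  stopifnot(inherits(gain, "gain_model"))
  if (gain$mode != "deterministic")
    stop("`gain_at()` applies to deterministic gain models", call. = FALSE)
  if (any(t < 1)) stop("`t` must be >= 1", call. = FALSE)
  g <- gain$fn(t)
  if (any(g < 0)) {
    warning("negative gain clipped to 0")
    g <- pmax(g, 0)
  }
  g
}

#' @export
print.gain_model <- function(x, ...) {
  if (x$mode == "deterministic") {
    cat("Deterministic gain model; g(1) =", format(gain_at(x, 1)),
        " g(10) =", format(gain_at(x, 10)), "\n")
  } else {
    cat(sprintf(
      "Stochastic gain model: %d support point(s) on [%g, %g], g_bar = %g, sigma = %g\n",
      length(x$support), x$g_min, x$g_max, x$g_bar, x$sigma))
  }
  invisible(x)
}

#' Reserve transition between breeding periods
#'
#' Next-period reserves are the unspent reserves plus the gain, capped at
#' the reserve ceiling: \eqn{r' = \min(r - r_o - r_i + g,\, r_{max})},
#' floored at 0.  Excess gain above the ceiling is wasted.
#'
#' @param r Current reserves.
#' @param r_o,r_i Allocations to offspring and immunity; must satisfy
#'   `r_o + r_i <= r`.
#' @param gain Gain in reserves this period, `>= 0`.
#' @param r_max Reserve ceiling (default 1).
#' @return Next-period reserves in `[0, r_max]`.
#' @export
transition <- function(r, r_o, r_i, gain, r_max = 1) {
  if (any(r_o + r_i > r + 1e-12))
    stop("infeasible allocation: r_o + r_i exceeds r", call. = FALSE)
  if (any(gain < 0)) stop("`gain` must be >= 0", call. = FALSE)
  pmin(pmax(r - r_o - r_i + gain, 0), r_max)
}
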