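#' Model parameters for the immunity--reproduction allocation model
#'
#' Bundles and validates the biological constants of the allocation model:
#' background mortality, immune-investment efficacy, the brooding fraction,
#' the concavity of offspring production and the offspring ceiling.
#' Validation happens here, once; the primitive functions assume a validated
#' object so that the dynamic-programming solvers can call them in tight
#' loops without per-call checks.
#'
#' @param M Background mortality rate per breeding period (\eqn{\ge 0}).
#'   Without immune investment, per-period survival is \eqn{e^{-M}} and life
#'   expectancy is roughly \eqn{1/M} breeding periods.
#' @param gamma Scaling factor \eqn{\gamma \ge 0} for the effect of immune
#'   investment on survival: investing \eqn{r_i} divides the mortality
#'   exponent by \eqn{1 + \gamma r_i}.  High \eqn{\gamma} means a small
#'   investment buys a large survival gain.
#' @param f Fraction of the breeding period spent in pregnancy or brooding,
#'   in \eqn{[0, 1]}.  Offspring survive only if the parent survives this
#'   fraction of the period.
#' @param alpha Concavity shape parameter of offspring production, in the
#'   open interval \eqn{(0, 1)}.
#' @param phi_max Maximum number of offspring, produced when the full
#'   reserve is allocated to reproduction (\eqn{> 0}).
#' @param r_max Maximum reserve level; fixed at 1 by convention.
#'
#' @return An object of class `"alloc_params"`: a named list with the
#'   validated fields.
#'
#' @examples
#' p <- alloc_params(M = 1, gamma = 2, f = 0.5)
#' offspring_count(0.25, p)
#' survival_current(0.5, p)
#' @export
alloc_params <- function(M, gamma, f, alpha = 0.5, phi_max = 100,
                         r_max = 1) {
  stop_unless <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x, nm) {
    stop_unless(is.numeric(x) && length(x) == 1L && is.finite(x),
                sprintf("`%s` must be a single finite number", nm))
    as.numeric(x)
  }
  M <- num1(M, "M"); gamma <- num1(gamma, "gamma"); f <- num1(f, "f")
  alpha <- num1(alpha, "alpha"); phi_max <- num1(phi_max, "phi_max")
  r_max <- num1(r_max, "r_max")
  stop_unless(M >= 0, "`M` must be >= 0")
  stop_unless(gamma >= 0, "`gamma` must be >= 0")
  stop_unless(f >= 0 && f <= 1, "`f` must lie in [0, 1]")
  stop_unless(alpha > 0 && alpha < 1,
              "`alpha` must lie in the open interval (0, 1)")
  stop_unless(phi_max > 0, "`phi_max` must be > 0")
  stop_unless(r_max == 1, "`r_max` is fixed at 1 by convention")
  structure(list(M = M, gamma = gamma, f = f, alpha = alpha,
                 phi_max = phi_max, r_max = r_max),
            class = "alloc_params")
}

#' @export
print.alloc_params <- function(x, ...) {
  cat("Allocation model parameters\n")
  cat(sprintf("  M = %g (background mortality), gamma = %g (immune efficacy)\n",
              x$M, x$gamma))
  cat(sprintf("  f = %g (brooding fraction), alpha = %g, phi_max = %g\n",
              x$f, x$alpha, x$phi_max))
  invisible(x)
}

check_reserve <- function(x, r_max, nm) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be finite numeric", nm), call. = FALSE)
  if (any(x < 0) || any(x > r_max))
    stop(sprintf("`%s` must lie in [0, %g]", nm, r_max), call. = FALSE)
  invisible(x)
}

#' Expected offspring production
#'
#' Offspring number is a concave power function of the reserves allocated to
#' reproduction, \eqn{\Phi(r_o) = \Phi_{max} r_o^{\alpha}}: the first units
#' of investment buy more offspring than the last.
#'
#' @param r_o Reserves allocated to offspring production, in `[0, r_max]`.
#'   Vectorized.
#' @param params An [alloc_params()] object.
#' @return Expected offspring count(s), \eqn{\ge 0}.
#' @examples
#' p <- alloc_params(M = 1, gamma = 2, f = 0.5, alpha = 0.5, phi_max = 100)
#' offspring_count(c(0, 0.25, 1), p)  # 0, 50, 100
#' @export
offspring_count <- function(r_o, params) {
  check_reserve(r_o, params$r_max, "r_o")
  # 0^alpha with 0 < alpha < 1 is 0 in R already (continuous limit)
  params$phi_max * r_o^params$alpha
}

#' Survival through the current breeding period
#'
#' Probability that the parent survives the brooding fraction `f` of the
#' current period, \eqn{S_{current}(r_i) = e^{-Mf/(1 + \gamma r_i)}}.
#' Immune investment \eqn{r_i} shields against background mortality by
#' dividing the exponent by \eqn{1 + \gamma r_i}.
#'
#' @param r_i Reserves allocated to the parent's immunity, `>= 0`.
#'   Vectorized.
#' @inheritParams offspring_count
#' @return Survival probability in `(0, 1]`.
#' @export
survival_current <- function(r_i, params) {
  check_reserve(r_i, params$r_max, "r_i")
  exp(-params$M * params$f / (1 + params$gamma * r_i))
}

#' Survival to the next breeding season
#'
#' Probability that the parent survives the whole inter-breeding interval,
#' \eqn{S_{future}(r_i) = e^{-M/(1 + \gamma r_i)}}.  Equals
#' [survival_current()] when `f = 1`.
#'
#' @inheritParams survival_current
#' @return Survival probability in `(0, 1]`.
#' @export
survival_future <- function(r_i, params) {
  check_reserve(r_i, params$r_max, "r_i")
  exp(-params$M / (1 + params$gamma * r_i))
}

#' Current reproductive success
#'
#' Because the offspring depend on the caring parent for the brooding
#' fraction of the period, the expected number of surviving offspring is the
#' product of offspring produced and the parent's within-period survival:
#' \eqn{\Phi(r_o)\, S_{current}(r_i)}.
#'
#' @inheritParams offspring_count
#' @inheritParams survival_current
#' @return Expected surviving offspring, \eqn{\ge 0}.  Vectorized over
#'   `r_o` and `r_i` jointly.
#' @export
reproductive_success <- function(r_o, r_i, params) {
  offspring_count(r_o, params) * survival_current(r_i, params)
}
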