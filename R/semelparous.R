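#' Single-season (semelparous) fitness
#'
#' For an organism with a single reproductive season, lifetime fitness is
#' the current reproductive success with all remaining reserves spent on
#' offspring: \eqn{W(r_i) = \Phi_{max}(r - r_i)^{\alpha}
#' e^{-Mf/(1+\gamma r_i)}}.
#'
#' @param r_i Immune allocation(s), in `[0, r]`.  Vectorized.
#' @param r Total reserves available, in `(0, r_max]`.
#' @param params An [alloc_params()] object.
#' @return Fitness value(s), \eqn{\ge 0}.
#' @seealso [semelparous_optimum()] for the maximizer.
#' @export
semelparous_fitness <- function(r_i, r, params) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) ||
      r <= 0 || r > params$r_max)
    stop("`r` must be a single value in (0, r_max]", call. = FALSE)
  if (any(r_i < 0) || any(r_i > r))
    stop("`r_i` must lie in [0, r]", call. = FALSE)
  params$phi_max * (r - r_i)^params$alpha *
    exp(-params$M * params$f / (1 + params$gamma * r_i))
}

#' Optimal semelparous immune allocation
#'
#' Maximizes [semelparous_fitness()] over \eqn{r_i \in [0, r]}.  The
#' closed form solves the stationarity condition, a quadratic in
#' \eqn{r_i}: with \eqn{k = Mf/\alpha},
#' \deqn{r_i^* = \frac{-(2+k) + \sqrt{(2+k)^2 - 4(1 - r k \gamma)}}{2\gamma}.}
#' An interior (non-negative) root exists iff the feasibility condition
#' \eqn{r M f \gamma / \alpha \ge 1} holds; otherwise fitness is decreasing
#' in \eqn{r_i} at 0 and the constrained maximizer is the boundary
#' \eqn{r_i^* = 0}.  The `+` branch of the quadratic is taken: under the
#' feasibility condition the `-` branch is always negative.  The root is
#' clipped to `[0, r]` (flagged via `clipped`) since the unconstrained
#' stationary point can exceed `r` for extreme parameters.
#'
#' With `gamma = 0` immune investment has no effect and the boundary answer
#' `r_i_star = 0` is returned, flagged non-interior.
#'
#' @param r Total reserves, in `(0, r_max]`.
#' @param params An [alloc_params()] object.
#' @param method `"closed_form"` (default) or `"grid"`, a brute-force
#'   grid-search maximization used as an independent cross-check.
#' @param n_grid Number of evenly spaced grid points for `method = "grid"`
#'   (at least 100).
#' @return An object of class `"semelparous_optimum"`: a list with
#'   `r_i_star`, `interior` (logical: is the optimum the interior root?),
#'   `k` (the composite ratio \eqn{Mf/\alpha}), `feasible` (does the
#'   interior-root condition hold?), `clipped`, `fitness` (fitness at the
#'   optimum), `r`, `method` and the `params` used.
#' @examples
#' p <- alloc_params(M = 1, gamma = 2, f = 0.5, alpha = 0.5)
#' semelparous_optimum(1, p)                      # interior: (-3 + sqrt(13))/4
#' semelparous_optimum(1, p, method = "grid", n_grid = 1e4)
#' @export
semelparous_optimum <- function(r, params,
                                method = c("closed_form", "grid"),
                                n_grid = 1e4) {
  method <- match.arg(method)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > params$r_max)
    stop("`r` must be a single value in (0, r_max]", call. = FALSE)
  k <- params$M * params$f / params$alpha
  if (method == "grid") {
    if (n_grid < 100) stop("`n_grid` must be at least 100", call. = FALSE)
    ri <- seq(0, r, length.out = n_grid)
    w <- semelparous_fitness(ri, r, params)
    best <- which.max(w)
    out <- list(r_i_star = ri[best], interior = best > 1L, k = k,
                feasible = r * k * params$gamma >= 1, clipped = FALSE,
                fitness = w[best], r = r, method = method, params = params)
    return(structure(out, class = "semelparous_optimum"))
  }
  feasible <- params$gamma > 0 && r * k * params$gamma >= 1
  if (!feasible) {
    ri_star <- 0
    clipped <- FALSE
  } else {
    disc <- (2 + k)^2 - 4 * (1 - r * k * params$gamma)
    root <- (-(2 + k) + sqrt(disc)) / (2 * params$gamma)
    clipped <- root > r
    ri_star <- min(max(root, 0), r)
  }
  structure(list(r_i_star = ri_star, interior = feasible && ri_star > 0,
                 k = k, feasible = feasible, clipped = clipped,
                 fitness = semelparous_fitness(ri_star, r, params),
                 r = r, method = method, params = params),
            class = "semelparous_optimum")
}

#' @export
print.semelparous_optimum <- function(x, ...) {
  cat("Semelparous optimum (", x$method, ")\n", sep = "")
  cat(sprintf("  r_i* = %.6g of r = %g reserves (k = Mf/alpha = %.4g)\n",
              x$r_i_star, x$r, x$k))
  cat(sprintf("  interior: %s; feasibility r*k*gamma >= 1: %s%s\n",
              x$interior, x$feasible,
              if (x$clipped) "; root clipped to [0, r]" else ""))
  cat(sprintf("  fitness at optimum: %.6g\n", x$fitness))
  invisible(x)
}

#' Feasibility threshold for immune efficacy
#'
#' Minimal value of \eqn{\gamma} for which the semelparous interior optimum
#' is non-negative: the condition \eqn{r M f \gamma / \alpha \ge 1} solved
#' for \eqn{\gamma} gives \eqn{\gamma_{min} = \alpha / (r M f)}.  Below this
#' efficacy, investing in immunity never pays within a single season and
#' the optimum sits at \eqn{r_i^* = 0}.
#'
#' @param r Total reserves, `> 0`.
#' @param M Background mortality, `> 0`.
#' @param f Brooding fraction, `> 0`.
#' @param alpha Concavity of offspring production, in `(0, 1)`.
#' @return The threshold \eqn{\gamma_{min}}; `Inf` when any of `r`, `M`,
#'   `f` is zero (no finite efficacy suffices).
#' @examples
#' feasibility_threshold_gamma(1, M = 0.1, f = 0.5, alpha = 0.5)  # 10
#' feasibility_threshold_gamma(1, M = 0.5, f = 0.5, alpha = 0.5)  # 2
#' @export
feasibility_threshold_gamma <- function(r, M, f, alpha) {
  if (any(c(r, M, f) < 0) || alpha <= 0 || alpha >= 1)
    stop("need r, M, f >= 0 and alpha in (0, 1)", call. = FALSE)
  if (r * M * f == 0) return(Inf)
  alpha / (r * M * f)
}

#' Semelparous optimum over a parameter grid
#'
#' Evaluates the closed-form optimum on the Cartesian product of brooding
#' fractions, mortalities and immune efficacies, one row per combination.
#' Rows where the interior-root feasibility condition fails carry
#' `interior = FALSE` and `r_i_star = 0` (the constrained boundary
#' maximizer).
#'
#' @param f_values,M_values,gamma_values Numeric vectors of parameter
#'   values to sweep (all nonempty).
#' @param r Total reserves (default 1).
#' @param alpha Concavity parameter (default 0.5).
#' @param phi_max Offspring ceiling (default 100; does not affect the
#'   optimizer, only fitness values).
#' @return A data frame with columns `f`, `M`, `gamma`, `r`, `alpha`,
#'   `r_i_star`, `interior`.
#' @export
semelparous_surface <- function(f_values, M_values, gamma_values,
                                r = 1, alpha = 0.5, phi_max = 100) {
  if (!length(f_values) || !length(M_values) || !length(gamma_values))
    stop("all parameter grids must be nonempty", call. = FALSE)
  grid <- expand.grid(gamma = gamma_values, M = M_values, f = f_values,
                      KEEP.OUT.ATTRS = FALSE)
  sol <- lapply(seq_len(nrow(grid)), function(i) {
    p <- alloc_params(M = grid$M[i], gamma = grid$gamma[i], f = grid$f[i],
                      alpha = alpha, phi_max = phi_max)
    semelparous_optimum(r, p)
  })
  data.frame(f = grid$f, M = grid$M, gamma = grid$gamma,
             r = r, alpha = alpha,
             r_i_star = vapply(sol, `[[`, numeric(1), "r_i_star"),
             interior = vapply(sol, `[[`, logical(1), "interior"))
}
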