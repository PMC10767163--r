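#' Forward Monte Carlo simulation of a population following a policy
#'
#' Follows `K` individuals forward through the breeding periods
#' `t = 1, ..., T`, each obeying the tabulated allocation policy.  Within
#' each period an individual (in this order) observes its gain, allocates
#' according to the policy looked up at its nearest-grid reserve level,
#' accrues reproductive success \eqn{\Phi(r_o^*) S_{current}(r_i^*)}, and
#' then survives to the next period with probability
#' \eqn{S_{future}(r_i^*)}.  Two uniform draws per individual per period
#' drive the gain category (through the inverse cumulative distribution of
#' \eqn{p(g_n)}) and the survival outcome.  Reserves update as
#' \eqn{r' = \min(r - r_o^* - r_i^* + g_n,\; r_{max})}.
#'
#' Within-season brood loss enters the reproductive-success credit, not
#' the parent's death: forward survival uses only the between-season
#' survival probability.
#'
#' Under a stochastic gain model, initial reserves are drawn from the gain
#' distribution \eqn{p(g_n)} and snapped to the reserve grid; under a
#' deterministic gain model they are set to `r0` (default `r_max`).
#' For reproducibility, uniform draws are consumed for every individual
#' every period, dead or alive, so a given seed yields an identical run
#' regardless of when deaths occur.
#'
#' @param object An `"alloc_policy"` from [solve_policy()] or
#'   [fixed_policy()].
#' @param nsim Number of independent runs (default 1).
#' @param seed RNG seed; set before the first run.
#' @param K Initial population size, `>= 1` (default 200).
#' @param r0 Initial reserve level for deterministic-gain policies.
#' @param ... Unused.
#' @return For `nsim = 1`, an object of class `"population_run"`: a list
#'   with `survivors` (alive count at the start of each period),
#'   `reserves`, `alive`, `alloc_i`, `alloc_o` (per-individual matrices;
#'   allocations are `NA` for dead individuals), accumulated `fitness`
#'   per individual, and the simulation settings.  For `nsim > 1`, a list
#'   of such objects.
#' @examples
#' p <- alloc_params(M = 1.5, gamma = 5, f = 0.5)
#' pol <- solve_policy(p, gain_stochastic(), T = 10, n_grid = 51)
#' run <- simulate(pol, seed = 1, K = 100)
#' run$survivors
#' @export
simulate.alloc_policy <- function(object, nsim = 1, seed = NULL, K = 200,
                                  r0 = NULL, ...) {
  if (K < 1 || K != round(K)) stop("`K` must be an integer >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (nsim > 1) {
    runs <- lapply(seq_len(nsim), function(i)
      simulate.alloc_policy(object, nsim = 1, seed = NULL, K = K, r0 = r0))
    return(runs)
  }
  p <- object$params; grid <- object$grid; T <- object$T
  stochastic <- object$mode == "stochastic"
  if (stochastic) {
    cum <- cumsum(object$gain$probs)
    ng <- length(cum)
  }

  reserves <- matrix(NA_real_, K, T)
  alive <- matrix(FALSE, K, T)
  alloc_i <- alloc_o <- matrix(NA_real_, K, T - 1L)
  fitness <- numeric(K)
  alive[, 1L] <- TRUE
  if (stochastic) {
    g0 <- pmin(findInterval(stats::runif(K), cum) + 1L, ng)
    reserves[, 1L] <- grid[nearest_grid_index(grid, object$gain$support[g0])]
  } else {
    if (is.null(r0)) r0 <- p$r_max
    reserves[, 1L] <- grid[nearest_grid_index(grid, rep(r0, K))]
  }

  for (t in seq_len(T - 1L)) {
    rho <- stats::runif(K)
    chi <- stats::runif(K)
    a <- alive[, t]
    ki <- nearest_grid_index(grid, ifelse(a, reserves[, t], 0))
    if (stochastic) {
      gi <- pmin(findInterval(rho, cum) + 1L, ng)
      gval <- object$gain$support[gi]
      ri <- object$ri_star[cbind(ki, t, gi)]
      ro <- object$ro_star[cbind(ki, t, gi)]
    } else {
      gval <- rep(gain_at(object$gain, t), K)
      ri <- object$ri_star[cbind(ki, t)]
      ro <- object$ro_star[cbind(ki, t)]
    }
    ri[!a] <- NA_real_; ro[!a] <- NA_real_
    alloc_i[, t] <- ri; alloc_o[, t] <- ro
    fitness[a] <- fitness[a] + p$phi_max * ro[a]^p$alpha *
      exp(-p$M * p$f / (1 + p$gamma * ri[a]))
    sf <- exp(-p$M / (1 + p$gamma * ri))
    surv <- a & (chi < sf)
    alive[, t + 1L] <- surv
    reserves[surv, t + 1L] <- pmin(pmax(
      grid[ki[surv]] - ro[surv] - ri[surv] + gval[surv], 0), p$r_max)
  }

  structure(list(K = as.integer(K), seed = seed, T = T,
                 reserves = reserves, alive = alive,
                 alloc_i = alloc_i, alloc_o = alloc_o,
                 survivors = colSums(alive), fitness = fitness,
                 mode = object$mode, params = p, grid = grid),
            class = "population_run")
}

#' @export
print.population_run <- function(x, ...) {
  cat(sprintf("Population run: K = %d individuals, T = %d periods (%s gain)\n",
              x$K, x$T, x$mode))
  cat(sprintf("  survivors at T: %d (%.1f%%); mean lifetime offspring: %.2f\n",
              x$survivors[x$T], 100 * x$survivors[x$T] / x$K,
              mean(x$fitness)))
  invisible(x)
}

#' Plot survivor counts from a population run
#'
#' @param x A `"population_run"`.
#' @param log Axis specification passed to [graphics::plot()]; default
#'   `"y"` so an exponential decay appears linear.
#' @param ... Further plot arguments.
#' @export
plot.population_run <- function(x, log = "y", ...) {
  keep <- x$survivors > 0
  graphics::plot(which(keep), x$survivors[keep], log = log, type = "b",
                 xlab = "breeding period t", ylab = "survivors",
                 main = "Survivor counts", ...)
  invisible(x)
}

#' Population-average allocations over time
#'
#' Means of the realized immune and offspring allocations over the
#' individuals alive in each period, plus the alive fraction.
#'
#' @param run A `"population_run"` from [simulate.alloc_policy()].
#' @return A data frame with columns `t` (1 to `T - 1`), `mean_r_i`,
#'   `mean_r_o`, `alive_frac`.
#' @export
allocation_series <- function(run) {
  stopifnot(inherits(run, "population_run"))
  tt <- seq_len(run$T - 1L)
  data.frame(
    t = tt,
    mean_r_i = colMeans(run$alloc_i, na.rm = TRUE),
    mean_r_o = colMeans(run$alloc_o, na.rm = TRUE),
    alive_frac = run$survivors[tt] / run$K)
}

#' Emergent mortality rate from simulated survivor counts
#'
#' Fits the exponential decay \eqn{S_{forward}(t) = e^{-M_{emergent} t}}
#' to the survivor counts of a forward simulation by least squares on the
#' log scale: the emergent (realized) mortality is the absolute value of
#' the slope of \eqn{\log S_{forward}(t)} versus \eqn{t}.  Because
#' individuals invest in immunity, the emergent mortality is below the
#' background rate `M`.  Periods with zero survivors are dropped (their
#' log is undefined); at least 3 usable periods are required.  The
#' regression weights each period by its survivor count, the delta-method
#' variance weighting for log counts (\eqn{Var[\log S] \approx 1/S}), so
#' the near-extinct tail does not dominate the fit.
#'
#' @param run A `"population_run"`.
#' @return An object of class `"emergent_mortality"`: a list with
#'   `m_emergent` (`>= 0`), `se` (standard error of the slope),
#'   `r_squared`, `fit_points`, and the underlying `lm` fit.
#' @export
emergent_mortality <- function(run) {
  stopifnot(inherits(run, "population_run"))
  tt <- seq_len(run$T)
  keep <- run$survivors > 0
  if (sum(keep) < 3)
    stop("population went extinct too fast: fewer than 3 periods with ",
         "survivors", call. = FALSE)
  fit <- stats::lm(log(s) ~ t, weights = s,
                   data = data.frame(t = tt[keep], s = run$survivors[keep]))
  sm <- summary(fit)
  structure(list(m_emergent = abs(stats::coef(fit)[["t"]]),
                 se = sm$coefficients["t", "Std. Error"],
                 r_squared = sm$r.squared,
                 fit_points = sum(keep), fit = fit),
            class = "emergent_mortality")
}

#' @export
print.emergent_mortality <- function(x, ...) {
  cat(sprintf(
    "Emergent mortality: %.4f per period (se %.4f, R^2 %.3f, %d periods)\n",
    x$m_emergent, x$se, x$r_squared, x$fit_points))
  invisible(x)
}

#' Emergent mortality across brooding fractions
#'
#' Solves the stochastic allocation model for each brooding fraction,
#' simulates populations forward under the optimal policy for each seed,
#' and fits the emergent mortality rate, reporting its ratio to the
#' background mortality `M`.  Longer brooding fractions favor immune
#' investment, so the ratio is expected to fall with `f`.
#'
#' @param params An [alloc_params()] object; its `f` is overridden by
#'   each value of `f_values`.
#' @param f_values Brooding fractions to compare.
#' @param gain A stochastic [gain_stochastic()] model.
#' @param T Horizon (default 20).
#' @param K Individuals per run (default 2000; large enough to keep the
#'   log-linear fit stable over the surviving tail).
#' @param seeds One RNG seed per replicate run.
#' @param n_grid Reserve grid resolution for the solver.
#' @return A data frame with one row per `(f, seed)`: `f`, `seed`,
#'   `m_emergent`, `ratio` (= `m_emergent / M`), `r_squared`,
#'   `fit_points`.
#' @export
emergent_mortality_experiment <- function(params,
                                          f_values = c(0.1, 0.5, 0.9),
                                          gain = gain_stochastic(),
                                          T = 20, K = 2000, seeds = 1:5,
                                          n_grid = 101) {
  stopifnot(inherits(params, "alloc_params"))
  rows <- lapply(f_values, function(f) {
    pf <- alloc_params(M = params$M, gamma = params$gamma, f = f,
                       alpha = params$alpha, phi_max = params$phi_max)
    pol <- solve_policy(pf, gain, T = T, n_grid = n_grid)
    do.call(rbind, lapply(seeds, function(s) {
      em <- emergent_mortality(simulate(pol, seed = s, K = K))
      data.frame(f = f, seed = s, m_emergent = em$m_emergent,
                 ratio = em$m_emergent / params$M,
                 r_squared = em$r_squared, fit_points = em$fit_points)
    }))
  })
  do.call(rbind, rows)
}
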