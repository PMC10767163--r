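# Backward-induction solver for the iteroparous allocation model.
#
# State is (reserves r, period t); the decision is an allocation pair
# (r_i, r_o) with r_i + r_o <= r, both restricted to reserve-grid
# multiples; unspent reserves are banked into the next period.  The
# enumeration below indexes allocations in integer grid steps so that
# feasibility (i0 + o0 <= k0) and leftovers (l0 = k0 - i0 - o0) are exact.

build_alloc_triples <- function(n) {
  per_k <- (seq_len(n) * (seq_len(n) + 1L)) %/% 2L  # triangle sizes per r index
  i0 <- o0 <- k0 <- integer(sum(per_k))
  pos <- 1L
  for (k in 0:(n - 1L)) {
    len <- ((k + 1L) * (k + 2L)) %/% 2L
    idx <- pos:(pos + len - 1L)
    # i0 ascending, then o0 ascending: which.max() then breaks exact ties
    # toward the smallest immune allocation, then smallest offspring one
    i0[idx] <- rep.int(0:k, k:0 + 1L)
    o0[idx] <- sequence(k:0 + 1L) - 1L
    k0[idx] <- k
    pos <- pos + len
  }
  ends <- cumsum(per_k)
  list(i0 = i0, o0 = o0, l0 = k0 - i0 - o0,
       starts = c(1L, ends[-n] + 1L), ends = ends)
}

# argmax of obj within each reserve-index group
group_argmax <- function(obj, starts, ends) {
  n <- length(starts)
  j <- integer(n)
  for (k in seq_len(n)) {
    idx <- starts[k]:ends[k]
    j[k] <- idx[which.max(obj[idx])]
  }
  j
}

#' Solve the iteroparous allocation model by backward induction
#'
#' Computes the maximum accumulated lifetime reproductive success
#' \eqn{W(r, t)} and the optimal allocation policy
#' \eqn{(r_i^*, r_o^*)} for every reserve level on a grid and every
#' breeding period \eqn{t = 1, \ldots, T-1}, working backwards from the
#' reproductive-senescence boundary \eqn{W(r, T) = 0}.
#'
#' At each state the solver maximizes current reproductive success plus
#' survival-discounted continuation value,
#' \deqn{W(r,t) = \max_{r_i + r_o \le r}\;
#'   \Phi(r_o) S_{current}(r_i) + S_{future}(r_i)\, W(r', t+1),}
#' where \eqn{r' = \min(r - r_o - r_i + g, r_{max})} carries unspent
#' reserves plus the period's gain forward.  With a deterministic gain
#' model, \eqn{g = g(t)}.  With a stochastic gain model the individual
#' observes the period's gain \eqn{g_n} before allocating, so the policy
#' is indexed by \eqn{(r, t, g_n)} and
#' \eqn{W(r,t) = \sum_n p(g_n) \max_{r_i+r_o \le r}[\cdot]}.
#'
#' Allocations are restricted to multiples of the reserve-grid step; the
#' full triangle \eqn{r_i + r_o \le r} is searched (reserves may be
#' banked).  The continuation value is evaluated by linear interpolation
#' on the reserve grid, which preserves its monotonicity in reserves.
#' Exact ties in the maximization are broken toward the smallest
#' \eqn{r_i}, then the smallest \eqn{r_o}.
#'
#' @param params An [alloc_params()] object.
#' @param gain A [gain_deterministic()], [gain_constant()],
#'   [gain_stochastic()] or [gain_point()] model.
#' @param T Reproductive senescence time (number of breeding periods),
#'   `>= 2`.  Allocation decisions exist for `t = 1, ..., T - 1`.
#' @param n_grid Number of evenly spaced reserve grid points on
#'   `[0, r_max]` (default 101, i.e. step 0.01).
#' @return An object of class `"alloc_policy"`: a list with the reserve
#'   `grid`, value matrix `W` (`n_grid` x `T`), policy arrays `ri_star`
#'   and `ro_star` (`n_grid` x `T-1`, with a third gain dimension in the
#'   stochastic case), `mode`, and the `params`, `gain`, `T`, `n_grid`
#'   used.
#' @seealso [predict.alloc_policy()], [simulate.alloc_policy()],
#'   [fixed_policy()].
#' @examples
#' p <- alloc_params(M = 1, gamma = 5, f = 0.5)
#' pol <- solve_policy(p, gain_deterministic(), T = 5, n_grid = 51)
#' pol
#' predict(pol, r = 1, t = 1)
#' @export
solve_policy <- function(params, gain, T = 20, n_grid = 101) {
  stopifnot(inherits(params, "alloc_params"), inherits(gain, "gain_model"))
  if (!is.numeric(T) || length(T) != 1L || T < 2 || T != round(T))
    stop("`T` must be an integer >= 2", call. = FALSE)
  if (n_grid < 2) stop("`n_grid` must be >= 2", call. = FALSE)
  T <- as.integer(T); n <- as.integer(n_grid)
  grid <- seq(0, params$r_max, length.out = n)
  tri <- build_alloc_triples(n)
  # state-independent pieces of the objective, one entry per (r_i, r_o, bank)
  crs <- params$phi_max * grid[tri$o0 + 1L]^params$alpha *
    exp(-params$M * params$f / (1 + params$gamma * grid[tri$i0 + 1L]))
  sf <- exp(-params$M / (1 + params$gamma * grid[tri$i0 + 1L]))
  bank1 <- tri$l0 + 1L

  W <- matrix(0, n, T)
  if (gain$mode == "deterministic") {
    ri <- ro <- matrix(0, n, T - 1L)
    for (t in (T - 1L):1L) {
      g <- gain_at(gain, t)
      vcont <- stats::approx(grid, W[, t + 1L],
                             xout = pmin(grid + g, params$r_max),
                             rule = 2)$y
      obj <- crs + sf * vcont[bank1]
      j <- group_argmax(obj, tri$starts, tri$ends)
      W[, t] <- obj[j]
      ri[, t] <- grid[tri$i0[j] + 1L]
      ro[, t] <- grid[tri$o0[j] + 1L]
    }
  } else {
    ng <- length(gain$support)
    ri <- ro <- array(0, dim = c(n, T - 1L, ng))
    wg <- matrix(0, n, ng)
    for (t in (T - 1L):1L) {
      for (gi in seq_len(ng)) {
        vcont <- stats::approx(grid, W[, t + 1L],
                               xout = pmin(grid + gain$support[gi],
                                           params$r_max),
                               rule = 2)$y
        obj <- crs + sf * vcont[bank1]
        j <- group_argmax(obj, tri$starts, tri$ends)
        wg[, gi] <- obj[j]
        ri[, t, gi] <- grid[tri$i0[j] + 1L]
        ro[, t, gi] <- grid[tri$o0[j] + 1L]
      }
      W[, t] <- as.vector(wg %*% gain$probs)
    }
  }
  structure(list(grid = grid, W = W, ri_star = ri, ro_star = ro,
                 mode = gain$mode, params = params, gain = gain,
                 T = T, n_grid = n),
            class = "alloc_policy")
}

#' Policy with allocations pinned to fixed values
#'
#' Builds an `"alloc_policy"` object whose allocations are constant rather
#' than optimized: at every state the individual allocates
#' `min(r_i, r)` to immunity and the remaining reserves (or `r_o`, if
#' given) to offspring.  Used as a control in simulation experiments,
#' e.g. pinning `r_i = 0` to recover the background survival curve
#' \eqn{e^{-Mt}}.
#'
#' @inheritParams solve_policy
#' @param r_i Fixed immune allocation.
#' @param r_o Fixed offspring allocation, or `NULL` (default) to spend
#'   all remaining reserves on offspring.
#' @return An `"alloc_policy"` object (its `W` table is left at zero:
#'   a pinned policy carries no optimal-value interpretation).
#' @export
fixed_policy <- function(params, gain, T = 20, n_grid = 101,
                         r_i = 0, r_o = NULL) {
  stopifnot(inherits(params, "alloc_params"), inherits(gain, "gain_model"))
  T <- as.integer(T); n <- as.integer(n_grid)
  grid <- seq(0, params$r_max, length.out = n)
  ri_r <- pmin(r_i, grid)
  ro_r <- if (is.null(r_o)) grid - ri_r else pmin(r_o, grid - ri_r)
  ng <- if (gain$mode == "stochastic") length(gain$support) else 1L
  if (gain$mode == "deterministic") {
    ri <- matrix(ri_r, n, T - 1L)
    ro <- matrix(ro_r, n, T - 1L)
  } else {
    ri <- array(ri_r, dim = c(n, T - 1L, ng))
    ro <- array(ro_r, dim = c(n, T - 1L, ng))
  }
  structure(list(grid = grid, W = matrix(0, n, T), ri_star = ri,
                 ro_star = ro, mode = gain$mode, params = params,
                 gain = gain, T = T, n_grid = n, pinned = TRUE),
            class = "alloc_policy")
}
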