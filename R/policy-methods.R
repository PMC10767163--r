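nearest_grid_index <- function(grid, x) {
  n <- length(grid)
  pmin(pmax(round(x * (n - 1) / grid[n]) + 1L, 1L), n)
}

#' @export
print.alloc_policy <- function(x, ...) {
  cat(sprintf("Allocation policy (%s gain)%s\n", x$mode,
              if (isTRUE(x$pinned)) " [pinned, not optimized]" else ""))
  cat(sprintf("  horizon T = %d, reserve grid: %d points on [0, %g]\n",
              x$T, x$n_grid, x$params$r_max))
  cat(sprintf("  M = %g, gamma = %g, f = %g, alpha = %g, phi_max = %g\n",
              x$params$M, x$params$gamma, x$params$f, x$params$alpha,
              x$params$phi_max))
  if (!isTRUE(x$pinned))
    cat(sprintf("  W(r_max, 1) = %.4f expected lifetime offspring\n",
                x$W[x$n_grid, 1L]))
  invisible(x)
}

#' Summarize an allocation policy
#'
#' @param object An `"alloc_policy"` from [solve_policy()].
#' @param ... Unused.
#' @return Invisibly, a data frame of per-period policy summaries at full
#'   reserves: expected optimal allocations (gain-probability-weighted in
#'   the stochastic case) and the value `W(r_max, t)`.
#' @export
summary.alloc_policy <- function(object, ...) {
  n <- object$n_grid
  tt <- seq_len(object$T - 1L)
  if (object$mode == "deterministic") {
    ri <- object$ri_star[n, tt]
    ro <- object$ro_star[n, tt]
  } else {
    p <- object$gain$probs
    ri <- apply(object$ri_star[n, tt, , drop = FALSE], 2, function(v) sum(v * p))
    ro <- apply(object$ro_star[n, tt, , drop = FALSE], 2, function(v) sum(v * p))
  }
  out <- data.frame(t = tt, r_i_star = ri, r_o_star = ro,
                    W = object$W[n, tt])
  print(object)
  cat("\nPolicy at full reserves (r = r_max):\n")
  print(utils::head(out, 10), row.names = FALSE)
  if (nrow(out) > 10) cat("  ...", nrow(out) - 10, "more period(s)\n")
  invisible(out)
}

#' Look up the optimal allocation for given states
#'
#' Retrieves the tabulated policy at the grid point nearest to each
#' requested reserve level.
#'
#' @param object An `"alloc_policy"`.
#' @param r Reserve level(s) in `[0, r_max]`.
#' @param t Breeding period(s) in `1, ..., T - 1` (recycled against `r`).
#' @param gn Observed gain value(s), required for stochastic policies
#'   (matched to the nearest support point); ignored otherwise.
#' @param ... Unused.
#' @return A data frame with the grid-snapped state and the optimal
#'   `r_i`, `r_o`.
#' @export
predict.alloc_policy <- function(object, r, t = 1L, gn = NULL, ...) {
  if (any(r < 0 | r > object$params$r_max))
    stop("`r` must lie in [0, r_max]", call. = FALSE)
  if (any(t < 1 | t > object$T - 1L))
    stop("`t` must lie in 1, ..., T - 1", call. = FALSE)
  m <- max(length(r), length(t), length(gn))
  r <- rep_len(r, m); t <- rep_len(as.integer(t), m)
  ki <- nearest_grid_index(object$grid, r)
  if (object$mode == "stochastic") {
    if (is.null(gn))
      stop("stochastic policies need the observed gain `gn`", call. = FALSE)
    gn <- rep_len(gn, m)
    gi <- vapply(gn, function(g) which.min(abs(object$gain$support - g)),
                 integer(1))
    data.frame(r = object$grid[ki], t = t, gn = object$gain$support[gi],
               r_i = object$ri_star[cbind(ki, t, gi)],
               r_o = object$ro_star[cbind(ki, t, gi)])
  } else {
    data.frame(r = object$grid[ki], t = t,
               r_i = object$ri_star[cbind(ki, t)],
               r_o = object$ro_star[cbind(ki, t)])
  }
}

#' Export a policy as a long-format table
#'
#' One row per `(t, r)` cell (per `(t, r, gn)` for stochastic policies)
#' with the value `W` and optimal allocations; suitable for writing to
#' CSV.
#'
#' @param x An `"alloc_policy"`.
#' @param ... Unused.
#' @return A data frame with columns `t`, `r`, (`gn`,) `W`, `r_i_star`,
#'   `r_o_star`.
#' @export
as.data.frame.alloc_policy <- function(x, ...) {
  n <- x$n_grid; tt <- seq_len(x$T - 1L)
  if (x$mode == "deterministic") {
    data.frame(t = rep(tt, each = n), r = rep(x$grid, length(tt)),
               W = as.vector(x$W[, tt]),
               r_i_star = as.vector(x$ri_star),
               r_o_star = as.vector(x$ro_star))
  } else {
    ng <- length(x$gain$support)
    data.frame(t = rep(rep(tt, each = n), ng),
               r = rep(x$grid, length(tt) * ng),
               gn = rep(x$gain$support, each = n * length(tt)),
               W = rep(as.vector(x$W[, tt]), ng),
               r_i_star = as.vector(x$ri_star),
               r_o_star = as.vector(x$ro_star))
  }
}

#' Plot an allocation policy
#'
#' Draws the optimal immune and offspring allocations as functions of the
#' reserve level at one breeding period.  For stochastic policies the
#' gain-probability-weighted expected allocation is shown.
#'
#' @param x An `"alloc_policy"`.
#' @param t Breeding period to display (default 1).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted matrix of allocations.
#' @export
plot.alloc_policy <- function(x, t = 1L, ...) {
  if (t < 1 || t > x$T - 1L) stop("`t` out of range", call. = FALSE)
  if (x$mode == "deterministic") {
    ri <- x$ri_star[, t]; ro <- x$ro_star[, t]
  } else {
    p <- x$gain$probs
    ri <- as.vector(x$ri_star[, t, , drop = FALSE][, 1, ] %*% p)
    ro <- as.vector(x$ro_star[, t, , drop = FALSE][, 1, ] %*% p)
  }
  m <- cbind(immunity = ri, offspring = ro)
  graphics::matplot(x$grid, m, type = "l", lty = 1:2, col = c(2, 3),
                    xlab = "reserves r", ylab = "optimal allocation",
                    main = sprintf("Policy at t = %d", t), ...)
  graphics::legend("topleft", legend = c("r_i*", "r_o*"), lty = 1:2,
                   col = c(2, 3), bty = "n")
  invisible(m)
}
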