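# Shared fixtures and independent oracles.

# Parameters used in several tests: background mortality, immune efficacy
# and brooding fraction with the standard offspring curve.
fig_params <- function(M = 1.5, gamma = 5, f = 0.5)
  alloc_params(M = M, gamma = gamma, f = f, alpha = 0.5, phi_max = 100)

# Draw (M, gamma, f) with a guaranteed interior semelparous optimum:
# gamma is sampled at a margin above the feasibility threshold
# alpha / (r * M * f).
draw_feasible <- function(n, r = 1, alpha = 0.5, margin = c(1.2, 10)) {
  M <- runif(n, 0.5, 3)
  f <- runif(n, 0.3, 1)
  gamma <- runif(n, margin[1], margin[2]) * alpha / (r * M * f)
  data.frame(M = M, f = f, gamma = gamma)
}

# Independent backward-induction oracle for the stochastic solver:
# plain nested loops over every allocation pair on the grid, every gain
# level and every period, with its own linear interpolation of the
# continuation value.  Only usable at tiny sizes.
oracle_stochastic_W <- function(p, grid, support, probs, T) {
  n <- length(grid)
  W <- matrix(0, n, T)
  for (t in (T - 1):1) {
    for (k in seq_len(n)) {
      tot <- 0
      for (gi in seq_along(support)) {
        best <- -Inf
        for (i in seq_len(k)) {
          for (o in seq_len(k - i + 1)) {
            ri <- grid[i]
            ro <- grid[o]
            rn <- min(max(grid[k] - ri - ro + support[gi], 0), p$r_max)
            v <- approx(grid, W[, t + 1], xout = rn, rule = 2)$y
            val <- p$phi_max * ro^p$alpha *
              exp(-p$M * p$f / (1 + p$gamma * ri)) +
              exp(-p$M / (1 + p$gamma * ri)) * v
            if (val > best) best <- val
          }
        }
        tot <- tot + probs[gi] * best
      }
      W[k, t] <- tot
    }
  }
  W
}

# Minimal population_run carrying only survivor counts, for testing the
# mortality fit on planted curves.
planted_run <- function(survivors)
  structure(list(K = survivors[1], T = length(survivors),
                 survivors = survivors, mode = "stochastic"),
            class = "population_run")
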