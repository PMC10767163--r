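test_that("closed form solves the hand-derived interior case", {
  # M = 1, f = 0.5, alpha = 0.5 gives k = 1; the quadratic root with
  # gamma = 2 is (-3 + sqrt(13)) / 4
  p <- alloc_params(M = 1, gamma = 2, f = 0.5, alpha = 0.5)
  sol <- semelparous_optimum(1, p)
  expect_equal(sol$r_i_star, (-3 + sqrt(13)) / 4, tolerance = 1e-12)
  expect_true(sol$interior)
  expect_equal(sol$k, 1)
  # brute force confirms
  bf <- semelparous_optimum(1, p, method = "grid", n_grid = 1e5)
  expect_equal(bf$r_i_star, sol$r_i_star, tolerance = 1e-4)
})

test_that("optimum is exactly zero on the feasibility boundary", {
  # r * M * f * gamma / alpha = 1 at M = 0.5, gamma = 2, f = 0.5, alpha = 0.5
  p <- alloc_params(M = 0.5, gamma = 2, f = 0.5, alpha = 0.5)
  expect_identical(semelparous_optimum(1, p)$r_i_star, 0)
  bf <- semelparous_optimum(1, p, method = "grid", n_grid = 1e4)
  expect_lt(bf$r_i_star, 1e-4 + 1e-12)
})

test_that("infeasible efficacy and degenerate parameters give the boundary", {
  # r * k * gamma = 0.5 < 1: no interior root
  p <- alloc_params(M = 0.1, gamma = 5, f = 0.5, alpha = 0.5)
  sol <- semelparous_optimum(1, p)
  expect_identical(sol$r_i_star, 0)
  expect_false(sol$interior)
  # gamma = 0: investment has no effect
  sol0 <- semelparous_optimum(1, alloc_params(M = 2, gamma = 0, f = 0.9))
  expect_identical(sol0$r_i_star, 0)
  expect_false(sol0$interior)
  # M = 0: no mortality, grid search puts everything into offspring
  bf <- semelparous_optimum(1, alloc_params(M = 0, gamma = 5, f = 0.5),
                            method = "grid", n_grid = 1000)
  expect_identical(bf$r_i_star, 0)
})

test_that("feasibility threshold is alpha / (r M f)", {
  expect_equal(feasibility_threshold_gamma(1, M = 0.1, f = 0.5, alpha = 0.5), 10)
  expect_equal(feasibility_threshold_gamma(1, M = 0.5, f = 0.5, alpha = 0.5), 2)
  expect_equal(feasibility_threshold_gamma(1, M = 1.0, f = 0.5, alpha = 0.5), 1)
  expect_identical(feasibility_threshold_gamma(1, M = 0, f = 0.5, alpha = 0.5),
                   Inf)
  # just above the threshold the root is real and non-negative; just below,
  # the interior solution is absent
  above <- semelparous_optimum(
    1, alloc_params(M = 0.1, gamma = 10.01, f = 0.5, alpha = 0.5))
  below <- semelparous_optimum(
    1, alloc_params(M = 0.1, gamma = 9.99, f = 0.5, alpha = 0.5))
  expect_true(above$feasible && above$r_i_star >= 0)
  expect_false(below$feasible)
})

test_that("closed form agrees with the grid-search oracle on random draws", {
  set.seed(42)
  draws <- draw_feasible(50)
  n_grid <- 2000
  for (i in seq_len(nrow(draws))) {
    p <- alloc_params(M = draws$M[i], gamma = draws$gamma[i], f = draws$f[i])
    cf <- semelparous_optimum(1, p)
    bf <- semelparous_optimum(1, p, method = "grid", n_grid = n_grid)
    expect_lt(abs(cf$r_i_star - bf$r_i_star), 2 / n_grid)
    expect_true(cf$r_i_star >= 0 && cf$r_i_star <= 1)
    # the '-' branch of the quadratic is negative whenever feasible
    k <- cf$k
    minus <- (-(2 + k) - sqrt((2 + k)^2 - 4 * (1 - k * p$gamma))) /
      (2 * p$gamma)
    expect_lt(minus, 0)
  }
})

test_that("interior optimum is nondecreasing in the brooding fraction", {
  for (M in c(1, 2)) {
    for (gamma in c(4, 8)) {
      ri <- vapply(c(0.1, 0.5, 0.9), function(f) {
        sol <- semelparous_optimum(
          1, alloc_params(M = M, gamma = gamma, f = f, alpha = 0.5))
        sol$r_i_star
      }, numeric(1))
      expect_true(all(diff(ri) >= 0))
    }
  }
})

test_that("parameter surface covers the grid and flags infeasible cells", {
  surf <- semelparous_surface(f_values = c(0.1, 0.5, 0.9),
                              M_values = c(0.5, 1, 2),
                              gamma_values = c(1, 2, 5))
  expect_equal(nrow(surf), 27)
  boundary <- surf[surf$f == 0.5 & surf$M == 0.5 & surf$gamma == 2, ]
  expect_equal(boundary$r_i_star, 0)
  expect_false(any(surf$interior & surf$r_i_star == 0))
  # fixed M = 1, f = 0.5: r_i* rises in gamma then falls past a threshold
  gammas <- seq(1.2, 40, by = 0.4)
  ri <- semelparous_surface(0.5, 1, gammas)$r_i_star
  peak <- which.max(ri)
  expect_gt(peak, 1)
  expect_lt(peak, length(gammas))
  expect_true(all(diff(ri[1:peak]) >= 0))
  expect_true(all(diff(ri[peak:length(ri)]) <= 0))
  # peak location confirmed by the brute-force oracle
  bf <- vapply(gammas, function(g) {
    semelparous_optimum(1, alloc_params(M = 1, gamma = g, f = 0.5),
                        method = "grid", n_grid = 4000)$r_i_star
  }, numeric(1))
  expect_equal(gammas[which.max(bf)], gammas[peak], tolerance = 0.5)
})

test_that("semelparous fitness rejects allocations exceeding reserves", {
  p <- fig_params()
  expect_error(semelparous_fitness(0.8, 0.5, p), "r_i")
  expect_equal(semelparous_fitness(0.5, 0.5, p), 0)
  p0 <- alloc_params(M = 0, gamma = 2, f = 0.5, alpha = 0.5, phi_max = 100)
  expect_equal(semelparous_fitness(0, 1, p0), 100)
})
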