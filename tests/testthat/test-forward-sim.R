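test_that("forward simulation is reproducible and respects invariants", {
  pol <- solve_policy(fig_params(), gain_stochastic(N = 5), T = 10,
                      n_grid = 51)
  run1 <- simulate(pol, seed = 11, K = 300)
  run2 <- simulate(pol, seed = 11, K = 300)
  expect_identical(run1[setdiff(names(run1), "seed")],
                   run2[setdiff(names(run2), "seed")])
  expect_equal(run1$survivors[1], 300)
  expect_true(all(diff(run1$survivors) <= 0))
  expect_true(all(run1$reserves >= 0 & run1$reserves <= 1, na.rm = TRUE))
  # dead individuals carry no allocations
  expect_true(all(is.na(run1$alloc_i[!run1$alive[, 1:9]])))
  run3 <- simulate(pol, seed = 12, K = 300)
  expect_false(identical(run1$survivors, run3$survivors))
  expect_error(simulate(pol, seed = 1, K = 0), "K")
})

test_that("no one dies when background mortality is zero", {
  pol <- solve_policy(alloc_params(M = 0, gamma = 2, f = 0.5),
                      gain_stochastic(N = 4), T = 8, n_grid = 31)
  run <- simulate(pol, seed = 3, K = 50)
  expect_equal(run$survivors, rep(50, 8))
})

test_that("zero-investment control reproduces background survival", {
  M <- 1.5
  K <- 2000
  pol <- fixed_policy(alloc_params(M = M, gamma = 5, f = 0.5),
                      gain_stochastic(), T = 20, n_grid = 101, r_i = 0)
  run <- simulate(pol, seed = 7, K = K)
  expect_true(all(run$alloc_i == 0, na.rm = TRUE))
  tt <- seq_len(run$T)
  expected <- exp(-M * (tt - 1))
  se <- sqrt(expected * (1 - expected) / K)
  keep <- expected * K > 5  # skip the deep tail where counts are tiny
  dev <- abs(run$survivors / K - expected)[keep]
  expect_true(all(dev <= 3 * se[keep] + 1e-12))
})

test_that("mortality fit recovers planted exponential decay", {
  tt <- 1:15
  run <- planted_run(round(5000 * exp(-0.7 * tt)))
  em <- emergent_mortality(run)
  expect_equal(em$m_emergent, 0.7, tolerance = 0.02 / 0.7)
  expect_gt(em$r_squared, 0.99)
  # constant counts: zero decay
  expect_equal(emergent_mortality(planted_run(rep(100, 10)))$m_emergent, 0)
  # extinction too fast: fewer than 3 usable periods
  expect_error(emergent_mortality(planted_run(c(100, 10, 0, 0, 0))),
               "extinct")
})

test_that("population averages track the individuals alive at each period", {
  # a single immortal individual: the population means are its own path
  pol <- fixed_policy(alloc_params(M = 0, gamma = 2, f = 0.5),
                      gain_stochastic(N = 4), T = 6, n_grid = 51,
                      r_i = 0.2)
  run <- simulate(pol, seed = 5, K = 1)
  ser <- allocation_series(run)
  expect_equal(ser$mean_r_i, as.vector(run$alloc_i[1, ]))
  expect_equal(ser$mean_r_o, as.vector(run$alloc_o[1, ]))
  expect_equal(ser$alive_frac, rep(1, 5))
  expect_true(all(abs(ser$mean_r_i - 0.2) < 1e-12))
})

test_that("ineffective immunity leaves emergent mortality at background", {
  # gamma = 0: investment cannot shield survival, so the fitted decay rate
  # sits at M within sampling error of the fit
  M <- 1
  pol <- solve_policy(alloc_params(M = M, gamma = 0, f = 0.5),
                      gain_stochastic(N = 5), T = 15, n_grid = 51)
  run <- simulate(pol, seed = 2, K = 2000)
  em <- emergent_mortality(run)
  expect_lt(abs(em$m_emergent - M), 3 * max(em$se, 0.01))
})

test_that("population size does not drive the allocation trajectories", {
  pol <- solve_policy(fig_params(M = 1, gamma = 4), gain_stochastic(),
                      T = 12, n_grid = 51)
  s1 <- allocation_series(simulate(pol, seed = 21, K = 500))
  s2 <- allocation_series(simulate(pol, seed = 22, K = 1000))
  keep <- s1$alive_frac * 500 > 30 & s2$alive_frac * 1000 > 30
  expect_lt(max(abs(s1$mean_r_i - s2$mean_r_i)[keep]), 2 / sqrt(500))
})

test_that("emergent-mortality experiment reports one fit per f and seed", {
  res <- emergent_mortality_experiment(
    fig_params(), f_values = c(0.1, 0.9), gain = gain_stochastic(N = 5),
    T = 12, K = 500, seeds = 1:2, n_grid = 51)
  expect_equal(nrow(res), 4)
  expect_named(res, c("f", "seed", "m_emergent", "ratio", "r_squared",
                      "fit_points"))
  expect_true(all(res$m_emergent >= 0))
  expect_equal(res$ratio, res$m_emergent / 1.5)
})
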