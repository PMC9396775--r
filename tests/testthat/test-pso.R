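# particle swarm optimizer

test_that("update_velocity follows the blend-and-clamp rule", {
  # particle sitting at both bests: only inertia survives
  expect_equal(update_velocity(0.1, 0.3, 0.3, 0.3, 0.9, 2, 2, 0.7, 0.2),
               0.09)
  # pure attraction arithmetic
  expect_equal(update_velocity(0, 0, 0.5, 0.5, 0.9, 2, 2, 1, 1), 2.0)
  # clamp
  expect_equal(update_velocity(0, 0, pi, pi, 0.5, 2, 2, 1, 1, v_max = pi), pi)
  expect_error(update_velocity(c(0, 0), 0, 0, 0, 0.9, 2, 2, 1, 1))
})

test_that("update_position adds velocity and wraps into [-pi, pi)", {
  expect_equal(update_position(0, 0.5), 0.5)
  expect_equal(update_position(3.0, 1.0), 4.0 - 2 * pi)
  expect_equal(update_position(c(0.2, -0.3), c(0, 0)), c(0.2, -0.3))
})

test_that("inertia schedule is linear between its endpoints", {
  cfg <- pso_config(iters = 100)
  expect_equal(inertia_at(0, cfg), 0.9)
  expect_equal(inertia_at(100, cfg), 0.4)
  expect_equal(inertia_at(50, cfg), 0.65)
  it <- 0:100
  w <- vapply(it, inertia_at, 1, config = cfg)
  expect_true(all(diff(w) <= 0))
})

test_that("with zero learning factors velocities decay geometrically", {
  cfg <- pso_config(swarm_size = 5, iters = 10, lambda1 = 0, lambda2 = 0,
                    inertia_start = 0.8, inertia_end = 0.8)
  set.seed(5)
  sw <- init_swarm("ABAB", cfg)
  v0 <- sw$velocities
  for (k in 1:4) sw <- pso_step(sw, "ABAB", cfg)
  expect_equal(sw$velocities, v0 * 0.8^4, tolerance = 1e-12)
})

test_that("pso_step keeps the stationary swarm's best and is deterministic", {
  cfg <- pso_config(swarm_size = 4, iters = 10, lambda1 = 0, lambda2 = 0)
  set.seed(9)
  sw <- init_swarm("ABBA", cfg)
  sw$velocities[] <- 0
  sw2 <- pso_step(sw, "ABBA", cfg)
  expect_equal(sw2$gbest_e, sw$gbest_e)
  expect_equal(sw2$positions, sw$positions)

  cfg2 <- pso_config(swarm_size = 10, iters = 20, seed = 123)
  r1 <- run_pso("ABBABA", cfg2)
  r2 <- run_pso("ABBABA", cfg2)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
})

test_that("global best trace is monotone and positions stay in bounds", {
  cfg <- pso_config(swarm_size = 30, iters = 50, seed = 77)
  r <- run_pso(fibonacci_sequence(13), cfg)
  expect_equal(length(r$trace), 50)
  expect_true(all(diff(r$trace) <= 0))
  expect_equal(r$best_energy, min(r$trace))
  expect_true(all(r$swarm$positions >= -pi & r$swarm$positions < pi))
})

test_that("has_converged implements the windowed-improvement rule", {
  expect_true(has_converged(rep(-1, 60), window = 50, tolerance = 1e-4))
  expect_false(has_converged(seq(0, -59), window = 50, tolerance = 1e-4))
  # improving by tolerance/2 over the whole window counts as converged
  tr <- -cumsum(rep(1e-4 / 2 / 50, 60))
  expect_true(has_converged(tr, window = 50, tolerance = 1e-4))
  expect_false(has_converged(-1, window = 50, tolerance = 1e-4))
  expect_true(has_converged(c(-1, -2), window = 50, tolerance = 1e-4,
                            cap = 2))
})

test_that("run_pso recovers the 1-D grid minimum on the 3-mer", {
  g <- grid_minimize("AAA", 1e-3)
  r <- run_pso("AAA", pso_config(swarm_size = 40, iters = 200, seed = 4))
  expect_lt(abs(r$best_energy - g$best_energy), 1e-3)
})
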