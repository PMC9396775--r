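# tabu search: neighborhood, candidate set, tabu list, criterion, aspiration

test_that("sign_factor branches at q = 0.5 and validates its input", {
  expect_equal(sign_factor(0.3), 1)
  expect_equal(sign_factor(0.7), -1)
  expect_equal(sign_factor(0.5), -1)
  expect_error(sign_factor(1.2), "\\[0, 1\\]")
})

test_that("perturb changes exactly one coordinate by f(q)*pi*Q*K", {
  x <- c(0.5, 0.1)
  expect_equal(perturb(x, 1, q = 0.5, Q = 0, K = 0.93), x)
  expect_equal(perturb(x, 1, q = 0.3, Q = 0.1, K = 0.93)[1],
               0.5 + pi * 0.1 * 0.93)
  out <- perturb(x, 2, q = 0.8, Q = 0.1, K = 0.93)
  expect_equal(out[2], 0.1 - pi * 0.1 * 0.93)
  expect_equal(out[1], x[1])
  expect_error(perturb(x, 3, 0.5, 0.5))
})

test_that("generate_neighbors yields L single-point mutations, reproducibly", {
  cfg <- tabu_config()
  x <- runif(11, -pi, pi)
  set.seed(8)
  nb <- generate_neighbors(x, 40, cfg)
  expect_equal(dim(nb), c(40L, 11L))
  changed <- apply(nb, 1, function(row) sum(row != x))
  expect_true(all(changed <= 1))
  expect_true(all(nb >= -pi & nb < pi))
  set.seed(8)
  expect_identical(generate_neighbors(x, 40, cfg), nb)
  # dimension-1 input: every mutation hits the only coordinate
  set.seed(8)
  nb1 <- generate_neighbors(0.3, 10, cfg)
  expect_equal(dim(nb1), c(10L, 1L))
})

test_that("select_candidates takes the Lc lowest energies, earlier wins ties", {
  nb <- matrix(1:3, ncol = 1)
  cand <- select_candidates(nb, c(-1, -3, -2), 2)
  expect_equal(cand$energies, c(-3, -2))
  expect_equal(cand$index, c(2L, 3L))
  all_sorted <- select_candidates(nb, c(-1, -3, -2), 10)
  expect_equal(all_sorted$energies, c(-3, -2, -1))
  tie <- select_candidates(nb, c(-2, -2, -2), 1)
  expect_equal(tie$index, 1L)
})

test_that("tabu criterion needs closeness in BOTH energy and conformation", {
  lst <- new_tabu_list(8)
  lst <- update_tabu_list(lst, rep(0.5, 3), -1.00)
  near <- rep(0.5, 3) + 0.004 / sqrt(3)       # ||y - z|| = 0.004
  expect_true(is_tabu(near, -1.05, lst, E0 = 0.10, r0 = 0.005))
  expect_false(is_tabu(near, -1.25, lst, E0 = 0.10, r0 = 0.005))
  far <- rep(0.5, 3) + 0.01 / sqrt(3)         # ||y - z|| = 0.01
  expect_false(is_tabu(far, -1.05, lst, E0 = 0.10, r0 = 0.005))
  expect_false(is_tabu(near, -1.05, new_tabu_list(8)))
})

test_that("aspiration requires strict improvement over the incumbent", {
  expect_true(aspiration_overrides(-5, -4))
  expect_false(aspiration_overrides(-4, -4))
  expect_false(aspiration_overrides(-3.9, -4))
})

test_that("tabu list decrements tenures, expires at zero and evicts FIFO", {
  lst <- new_tabu_list(8)
  lst <- update_tabu_list(lst, c(0), -1)
  expect_length(lst$entries, 1)
  expect_equal(lst$entries[[1]]$tenure, 8L)
  # an entry with tenure 1 disappears on the next update
  lst$entries[[1]]$tenure <- 1L
  lst <- update_tabu_list(lst, c(1), -2)
  expect_length(lst$entries, 1)
  expect_equal(lst$entries[[1]]$solution, c(1))
  # FIFO eviction at capacity
  lst <- new_tabu_list(3)
  for (k in 1:4) lst <- update_tabu_list(lst, c(k), -k)
  expect_length(lst$entries, 3)
  expect_equal(vapply(lst$entries, function(e) e$solution, 1), c(2, 3, 4))
  expect_true(all(vapply(lst$entries, function(e) e$tenure, 1L) >= 1L))
})

test_that("tabu_step accepts the best admissible candidate", {
  cfg <- tabu_config(L = 10, Lc = 3, iters = 5)
  s <- "ABBAB"
  x <- runif(3, -pi, pi)
  e <- total_energy(s, x)$total
  set.seed(14)
  st <- tabu_step(x, e, x, e, new_tabu_list(cfg$Lt), s, cfg)
  expect_lte(st$best_energy, e)
  expect_length(st$tabu_list$entries, 1)
  expect_equal(st$tabu_list$entries[[1]]$solution, st$current)
  # determinism
  set.seed(14)
  st2 <- tabu_step(x, e, x, e, new_tabu_list(cfg$Lt), s, cfg)
  expect_identical(st$current, st2$current)
})

test_that("a freshly accepted solution is tabu against itself until aspirated", {
  cfg <- tabu_config()
  x <- runif(5, -pi, pi)
  lst <- update_tabu_list(new_tabu_list(cfg$Lt), x, -2)
  expect_true(is_tabu(x, -2, lst, cfg$E0, cfg$r0))
  expect_true(aspiration_overrides(-2.5, -2))
})

test_that("run_tabu never worsens the initial solution and is reproducible", {
  s <- fibonacci_sequence(13)
  init <- rep(0, 11)
  e0 <- total_energy(s, init)$total
  cfg <- tabu_config(iters = 60, seed = 99)
  r <- run_tabu(s, init, cfg)
  expect_lte(r$best_energy, e0)
  expect_true(all(diff(r$trace) <= 0))
  expect_equal(r$best_energy, min(r$trace))
  r2 <- run_tabu(s, init, cfg)
  expect_identical(r$trace, r2$trace)
  expect_error(run_tabu(s, rep(0, 4), cfg), "angles")
})
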