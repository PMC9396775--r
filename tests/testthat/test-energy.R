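# core model: polarity, geometry, potential energy

test_that("eta_of maps A to +1 and B to -1 and rejects other letters", {
  expect_equal(eta_of("AB"), c(1, -1))
  expect_equal(eta_of("BBB"), c(-1, -1, -1))
  expect_equal(sum(eta_of(fibonacci_sequence(13)) == 1), 5)
  expect_error(ab_sequence("ABH"), "position")
})

test_that("pair_coefficient takes the three canonical values and is symmetric", {
  expect_equal(pair_coefficient(1, 1), 1)
  expect_equal(pair_coefficient(-1, -1), 0.5)
  expect_equal(pair_coefficient(1, -1), -0.5)
  expect_equal(pair_coefficient(-1, 1), pair_coefficient(1, -1))
  expect_error(pair_coefficient(0.5, 1))
})

test_that("build_coordinates realizes unit-bond chains from bend angles", {
  expect_equal(build_coordinates(c(0, 0)),
               cbind(x = 0:3, y = rep(0, 4)))
  expect_equal(build_coordinates(pi / 2)[3, ], c(x = 1, y = 1),
               tolerance = 1e-12)
  expect_equal(build_coordinates(c(pi / 2, pi / 2)),
               cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
               tolerance = 1e-9)
  expect_error(build_coordinates(numeric(0)))
  expect_error(build_coordinates(c(0, NaN)))
})

test_that("bond lengths are unity for random conformations", {
  set.seed(11)
  for (rep in 1:50) {
    inst <- random_instance()
    xy <- build_coordinates(inst$angles)
    bonds <- sqrt(rowSums(diff(xy)^2))
    expect_true(all(abs(bonds - 1) < 1e-9))
  }
})

test_that("backbone and nonbonded terms match closed forms", {
  expect_equal(backbone_energy(c(0, 0, 0)), 0)
  expect_equal(backbone_energy(pi / 2), 0.25)
  expect_equal(backbone_energy(pi), 0.5)
  expect_equal(nonbonded_energy("AAA", build_coordinates(0)), -0.0615234375)
  expect_equal(nonbonded_energy("ABB", build_coordinates(0)), 0.0322265625)
  expect_equal(nonbonded_energy("AAA", build_coordinates(pi / 2)), -0.4375,
               tolerance = 1e-12)
})

test_that("total_energy matches closed forms and decomposes exactly", {
  e <- total_energy("AAA", 0)
  expect_s3_class(e, "energy_breakdown")
  expect_equal(e$total, -0.0615234375)
  expect_equal(total_energy("AAA", pi / 2)$total, -0.1875, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:20) {
    inst <- random_instance()
    b <- total_energy(inst$seq, inst$angles)
    expect_equal(b$total, b$backbone + b$nonbonded, tolerance = 1e-12)
  }
  expect_error(total_energy("AAAA", 0), "angles")
  expect_error(total_energy("AB", numeric(0)))
})

test_that("total_energy agrees with the naive oracle on random instances", {
  set.seed(31)
  for (rep in 1:200) {
    inst <- random_instance()
    expect_equal(total_energy(inst$seq, inst$angles)$total,
                 naive_energy(inst$seq, inst$angles), tolerance = 1e-12)
  }
})

test_that("energy has mirror and chain-reversal symmetry", {
  set.seed(41)
  for (rep in 1:50) {
    inst <- random_sane_instance()   # see helper: r^-12 conditioning
    e <- total_energy(inst$seq, inst$angles)$total
    expect_equal(total_energy(inst$seq, -inst$angles)$total, e,
                 tolerance = 1e-12)
    rev_seq <- paste(rev(strsplit(inst$seq, "")[[1]]), collapse = "")
    expect_equal(total_energy(rev_seq, rev(inst$angles))$total, e,
                 tolerance = 1e-12)
  }
})

test_that("coincident residues raise a domain error", {
  # four right turns close a unit square: residue 5 lands on residue 1
  expect_error(total_energy("AAAAA", c(pi / 2, pi / 2, pi / 2)),
               "diverges")
  expect_error(naive_energy("AAAAA", c(pi / 2, pi / 2, pi / 2)), "diverges")
})

test_that("wrap_angle is the mod-2pi map onto [-pi, pi)", {
  expect_equal(wrap_angle(0), 0)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_angle(-3 * pi / 2), pi / 2)
  expect_error(wrap_angle(Inf))
  set.seed(51)
  x <- runif(100, -50, 50)
  w <- wrap_angle(x)
  expect_true(all(w >= -pi & w < pi))
  expect_equal(wrap_angle(w), w)                      # idempotent
  d <- (x - w) %% (2 * pi)                            # x == w (mod 2*pi)
  expect_true(all(pmin(d, 2 * pi - d) < 1e-9))
})
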