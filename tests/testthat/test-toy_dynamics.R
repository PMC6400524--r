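test_that("potential evaluation matches closed forms", {
  sys <- toy_system(harmonic_potential(30, 2))
  at_min <- eval_potential(sys, 30)
  expect_equal(at_min$energy, 0)
  expect_equal(at_min$force, 0)
  at31 <- eval_potential(sys, 31)
  expect_equal(at31$energy, 1.0)
  expect_equal(at31$force, -2.0)

  dw <- double_well_potential(27, 42, 2)
  for (r in c(27, 42)) {
    e <- eval_potential(dw, r)
    expect_equal(e$energy, 0, tolerance = 1e-12)
    expect_lt(abs(e$force), 1e-8)
  }
  expect_equal(eval_potential(dw, 34.5)$energy, 2, tolerance = 1e-12)

  tab <- tabulated_potential(seq(10, 50, 0.1), 0.5 * 2 * (seq(10, 50, 0.1) - 30)^2)
  expect_equal(eval_potential(tab, 31)$force, -2.0, tolerance = 1e-6)
  expect_error(eval_potential(tab, 55), "domain")
})

test_that("Boltzmann profile matches the harmonic closed form and symmetry", {
  sys <- toy_system(harmonic_potential(30, 2))
  bp <- boltzmann_profile(sys, seq(25, 35, 0.01))
  expect_equal(distribution_sd(bp), sqrt(kT298 / 2), tolerance = 1e-3)
  expect_equal(distribution_mean(bp), 30, tolerance = 1e-9)

  flat <- boltzmann_profile(toy_system(tabulated_potential(seq(10, 50, 0.1),
                                                           rep(3, 401))),
                            seq(10, 50, 0.1))
  expect_lt(diff(range(flat$density)), 1e-12)

  dwp <- boltzmann_profile(fixture_double_well(), seq(14.5, 54.5, 0.1))
  expect_lt(max(abs(dwp$density - rev(dwp$density))), 1e-9)
})

test_that("zero-temperature dynamics is a fixed point at the minimum", {
  sys <- toy_system(harmonic_potential(30, 2), temperature = 0)
  st <- dynamics_state(30)
  for (i in 1:20) st <- langevin_step(sys, st, 0.002)
  expect_equal(st$r, 30, tolerance = 1e-12)
  expect_equal(st$velocity, 0, tolerance = 1e-12)
  expect_error(langevin_step(sys, st, 0), "dt")
  expect_error(langevin_step(sys, st, 2), "dt")
})

test_that("langevin_step honors an external force callback", {
  sys <- toy_system(harmonic_potential(30, 2), temperature = 0)
  st <- dynamics_state(30)
  # constant external pull displaces the zero-T fixed point to r0 + f/kappa
  for (i in 1:30000) st <- langevin_step(sys, st, 0.002, extra_force = function(r) 1)
  expect_equal(st$r, 30.5, tolerance = 1e-6)
})

test_that("long harmonic runs satisfy equipartition and are seed-deterministic", {
  sys <- toy_system(harmonic_potential(30, 2))
  tr <- run_langevin(sys, 5e5, r_start = 30, sample_stride = 50, seed = 1)
  expect_equal(var(tr$cv), kT298 / 2, tolerance = 0.05)
  tr2 <- run_langevin(sys, 5e5, r_start = 30, sample_stride = 50, seed = 1)
  expect_identical(tr$cv, tr2$cv)
  tr3 <- run_langevin(sys, 1e4, r_start = 30, seed = 2)
  expect_false(identical(tr$cv[1:100], tr3$cv[1:100]))
})

test_that("unbiased sampling converges to the Boltzmann profile", {
  # double-well occupancy equilibrates through barrier hops, so it gets the
  # longer of the two runs
  for (case in list(list(sys = basin_system(30), grid = seq(18, 42, 0.1),
                         seed = 11, nsteps = 2e6),
                    list(sys = fixture_double_well(), grid = seq(14.5, 54.5, 0.1),
                         seed = 12, nsteps = 5e6))) {
    bp <- boltzmann_profile(case$sys, case$grid)
    tr <- run_langevin(case$sys, case$nsteps,
                       r_start = case$grid[which.max(bp$density)],
                       sample_stride = 100, seed = case$seed)
    expect_lt(convergence_kl(tr$cv, bp), 0.01)
  }
})

test_that("coordination number has the analytic limits and monotonicity", {
  expect_equal(pair_coordination(1e-12, 2.5), 1, tolerance = 1e-9)
  expect_equal(pair_coordination(0, 2.5), 1)
  expect_equal(pair_coordination(2.5, 2.5), 0.8, tolerance = 1e-9)
  expect_equal(pair_coordination(5, 2.5), 255 / 1023, tolerance = 1e-12)
  # continuity through the guard band around r = R
  rr <- 2.5 * (1 + c(-2e-6, -5e-7, 0, 5e-7, 2e-6))
  expect_lt(max(abs(diff(pair_coordination(rr, 2.5)))), 1e-5)
  # strictly decreasing on (0, 3R); start past the x^8-underflow plateau
  # near r = 0 where the value is 1 at double precision
  rr <- seq(0.1, 7.5 - 1e-3, length.out = 2000)
  expect_true(all(diff(pair_coordination(rr, 2.5)) < 0))

  coords <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 5, 0))
  site <- coordination_site(1, c(2, 3), cutoff = 2.5, threshold = 1.3)
  expect_equal(coordination_number(coords, site), 0.8 + 255 / 1023,
               tolerance = 1e-9)
})

test_that("half-harmonic restraint matches the printed example and its derivative", {
  site <- coordination_site(1, 2, cutoff = 2.5, threshold = 1.3, force_const = 50)
  expect_equal(restraint_energy(1.8, site)$energy, 0)
  expect_equal(restraint_energy(1.8, site)$dEdC, 0)
  expect_equal(restraint_energy(1.1, site)$energy, 0.5 * 50 * 0.04)
  site0 <- coordination_site(1, 2, cutoff = 2.5, threshold = 1.3, force_const = 0)
  expect_equal(restraint_energy(0.5, site0)$energy, 0)

  # derivative agrees with finite differences everywhere, incl. the threshold
  h <- 1e-6
  for (c0 in c(0.5, 1.0, 1.2999, 1.3, 1.31, 2)) {
    fd <- (restraint_energy(c0 + h, site)$energy -
             restraint_energy(c0 - h, site)$energy) / (2 * h)
    expect_equal(restraint_energy(c0, site)$dEdC, fd, tolerance = 1e-4)
  }
})
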