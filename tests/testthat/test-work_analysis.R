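test_that("time-averaged bias uses exact hill residence weights", {
  tgt <- unimodal_target(30, 3, seq(15, 45, 0.1))
  g <- tgt$grid

  # one hill at t = 0 with t_f = 0: Vbar is the hill itself
  h1 <- synthetic_history(tgt, 30, 0.1)
  avg <- time_averaged_bias(h1, 0, 500)
  expect_equal(avg$vbar, bias_value(h1, g)$energy, tolerance = 1e-12)

  # a hill deposited at the last instant has vanishing residence weight
  h2 <- synthetic_history(tgt, c(30, 30), c(1e-9, 0.1))
  avg2 <- time_averaged_bias(h2, 0, 501)
  expect_lt(max(avg2$vbar), 0.1 * 1 / 501 + 2e-9)

  # constant-rate equal hills at one center: Vbar(center) = h (N + 1) / 2
  for (N in c(4, 20, 100)) {
    hN <- synthetic_history(tgt, rep(30, N), rep(0.02, N))
    avgN <- time_averaged_bias(hN, 0, N * 500)
    expect_equal(avgN$vbar[which.min(abs(g - 30))], 0.02 * (N + 1) / 2,
                 tolerance = 1e-12)
  }

  expect_error(time_averaged_bias(h1, 500, 500), "window")
  expect_error(time_averaged_bias(h1, 0, 5000), "beyond")
})

test_that("work vanishes for constant bias and matches the linear closed form", {
  g <- seq(0, 60, 0.01)
  flat <- make_distribution(g, rep(1, length(g)))
  avg_c <- averaged_bias(g, rep(3.7, length(g)), flat)
  expect_equal(work(avg_c)$W, 0, tolerance = 1e-12)

  # linear bias a*r with a = kT/L over uniform rho on [0, L]:
  # W = kT ln((kT/aL)(e^{aL/kT} - 1)) - aL/2 = kT (ln(e - 1) - 1/2)
  L <- 60; a <- kT298 / L
  avg_l <- averaged_bias(g, a * g, flat)
  W <- work(avg_l)$W
  expect_equal(W, kT298 * (log(exp(1) - 1) - 0.5), tolerance = 2e-3 * kT298)
  # independent quadrature oracle for the same integral
  oracle <- kT298 * log(integrate(function(r) (1 / L) *
      exp((a * r - a * L / 2) / kT298), 0, L)$value)
  expect_equal(W, oracle, tolerance = 2e-3 * kT298)
})

test_that("work equals kT times the KL between target and debiased (Eq. 3 identity)", {
  set.seed(403)
  g <- default_grid()
  for (i in 1:100) {
    tgt <- random_mixture(g)
    vbar <- random_vbar(g)
    avg <- averaged_bias(g, vbar, tgt)
    W <- work(avg)$W
    deb <- debias_distribution(avg)$distribution
    expect_equal(W, kT298 * kl_divergence(tgt, deb), tolerance = 1e-8)
    expect_gte(W, -1e-9)
  }
})

test_that("work is exactly invariant to constant bias offsets", {
  set.seed(404)
  g <- default_grid()
  tgt <- random_mixture(g)
  vbar <- random_vbar(g)
  W0 <- work(averaged_bias(g, vbar, tgt))$W
  for (cc in runif(10, -100, 100))
    expect_equal(work(averaged_bias(g, vbar + cc, tgt))$W, W0,
                 tolerance = 1e-10)
})

test_that("debiasing inverts a constructed bias and fixes min F at zero", {
  g <- default_grid()
  tgt <- unimodal_target(35, 4)
  res0 <- debias_distribution(averaged_bias(g, rep(2, length(g)), tgt))
  expect_equal(res0$distribution$density, tgt$density, tolerance = 1e-12)
  expect_equal(min(res0$F), 0)

  other <- bimodal_target()
  vbar <- kT298 * log(pmax(other$density, 1e-12) / pmax(tgt$density, 1e-12))
  res <- debias_distribution(averaged_bias(g, vbar, tgt))
  # densities differ only where the construction floored the logs (empty tails)
  core <- other$density > 1e-7
  expect_lt(max(abs(res$distribution$density[core] - other$density[core])), 1e-9)
})

test_that("restricted work flattens the bias above r_max against the modified reference", {
  g <- default_grid()
  tgt <- bimodal_target()
  vbar <- random_vbar(g)
  set.seed(405)
  avg <- averaged_bias(g, vbar, tgt)

  full <- work(avg)$W
  beyond <- restricted_work(avg, r_max = max(g))
  expect_equal(beyond$W_restricted, full, tolerance = 1e-9)

  const <- restricted_work(averaged_bias(g, rep(1.3, length(g)), tgt), r_max = 37)
  expect_equal(const$W_restricted, 0, tolerance = 1e-12)
  expect_equal(const$rho_modified$density, tgt$density, tolerance = 1e-12)

  # bias supported only above 37 A leaves the short-range work at zero
  high <- ifelse(g > 40, 2 * (g - 40), 0)
  avg_h <- averaged_bias(g, high, tgt)
  rw <- restricted_work(avg_h, r_max = 37)
  expect_lt(rw$W_restricted, 1e-3)
  expect_gt(work(avg_h)$W, 0.1)

  expect_error(restricted_work(avg, r_max = 5), "grid")
})

test_that("restricted work is continuous in r_max", {
  set.seed(406)
  g <- default_grid()
  tgt <- random_mixture(g)
  avg <- averaged_bias(g, random_vbar(g), tgt)
  rmaxes <- seq(34.9, 39.1, 0.02)   # crosses many grid points
  ws <- vapply(rmaxes, function(rm) restricted_work(avg, r_max = rm)$W_restricted,
               numeric(1))
  expect_lt(max(abs(diff(ws))), 0.02)
})

test_that("split-half uncertainty follows the n = 2 population SD convention", {
  tgt <- unimodal_target(30, 3, seq(15, 45, 0.1))
  set.seed(407)
  h <- synthetic_history(tgt, runif(100, 24, 36), runif(100, 0.005, 0.02))
  s <- split_half_uncertainty(h, 1e4, 5e4)
  w12 <- attr(s, "works")
  expect_equal(as.numeric(s), abs(w12[1] - w12[2]) / 2)
  s2 <- split_half_uncertainty(h, 1e4, 5e4, type = "sample")
  expect_equal(as.numeric(s2), abs(w12[1] - w12[2]) / sqrt(2))

  expect_error(split_half_uncertainty(h, 49000, 50000), "fewer than 2")
})

test_that("work ranks a matched state below a displaced state (short runs)", {
  tgt <- unimodal_target(27, 3)
  for (seed in 1:3) {
    wa <- analyze_run(run_ebmetad(basin_system(27), tgt,
                                  ebmetad_params(2e5, seed = seed)))$W
    wb <- analyze_run(suppressWarnings(run_ebmetad(basin_system(42), tgt,
                                                   ebmetad_params(2e5, seed = seed))))$W
    expect_lt(wa, wb)
  }
})
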