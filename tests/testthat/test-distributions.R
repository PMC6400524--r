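test_that("make_distribution normalizes and validates", {
  g <- seq(20, 80, 0.1)
  d <- make_distribution(g, rep(2, length(g)))
  expect_s3_class(d, "distance_distribution")
  expect_equal(sum(d$density) * d$dr, 1, tolerance = 1e-12)
  # flat density ~ 1/width (discrete normalization differs at 2e-3 level)
  expect_equal(d$density[1], 1 / 60, tolerance = 2e-3)
  expect_true(diff(range(d$density)) == 0)

  # discrete delta: all mass in one bin gives density 1/dr there
  v <- numeric(length(g)); v[100] <- 7
  dd <- make_distribution(g, v)
  expect_equal(dd$density[100], 1 / dd$dr, tolerance = 1e-12)
  expect_equal(sum(dd$density > 0), 1)

  v[3] <- -0.001
  expect_error(make_distribution(g, v), "negative")
  expect_error(make_distribution(g, numeric(length(g))), "all-zero")
  expect_error(make_distribution(c(1, 2, 3.5), c(1, 1, 1)), "uniform")
  expect_error(make_distribution(c(3, 2, 1), c(1, 1, 1)), "increasing")
})

test_that("gaussian mixtures have the analytic shape, mass split and truncation guards", {
  g <- seq(10, 50, 0.1)
  uni <- gaussian_mixture_distribution(gaussian_component(27, 3), g)
  expect_equal(g[which.max(uni$density)], 27, tolerance = 0.11)
  expect_equal(sum(uni$density) * uni$dr, 1, tolerance = 1e-12)

  bi <- bimodal_target()
  below <- sum(bi$density[bi$grid < 34.5]) * bi$dr
  expect_equal(below, 0.5, tolerance = 0.01)   # halves split at the midpoint
  expect_equal(1 - below, 0.5, tolerance = 0.01)

  expect_error(gaussian_mixture_distribution(list(), g), "non-empty")
  expect_warning(gaussian_mixture_distribution(gaussian_component(48, 1), g),
                 "truncates")
  expect_error(
    suppressWarnings(gaussian_mixture_distribution(gaussian_component(49.5, 2), g)),
    "truncates")
})

test_that("subtracting a Gaussian interprotomer component recovers the short-range peak", {
  g <- default_grid()
  mix <- gaussian_mixture_distribution(
    list(gaussian_component(27, 3, 0.7), gaussian_component(60, 5, 0.3)), g)
  # the raw mixture is normalized, so the 60-A component has amplitude 0.3
  res <- subtract_component(mix, gaussian_component(60, 5, 0.3))
  pure <- gaussian_mixture_distribution(gaussian_component(27, 3), g)
  expect_lt(max(abs(res$density - pure$density)), 1e-6)
  expect_equal(attr(res, "subtracted")[[1]]$mu, 60)

  # zero-amplitude subtraction is the identity
  expect_identical(subtract_component(mix, gaussian_component(60, 5, 0)), mix)

  # removing all mass is an error
  expect_error(subtract_component(pure, gaussian_component(27, 3, 5)),
               "all probability mass")
})

test_that("subtract-then-add round trip recovers the density where unclipped", {
  g <- default_grid()
  mix <- gaussian_mixture_distribution(
    list(gaussian_component(30, 4, 0.6), gaussian_component(55, 6, 0.4)), g)
  comp <- gaussian_component(55, 6, 0.2)
  sub <- subtract_component(mix, comp)
  resid <- mix$density - comp$weight * dnorm(g, comp$mu, comp$sigma)
  unclipped <- resid > 0
  back <- make_distribution(g, sub$density * (sum(resid[resid > 0]) * mix$dr) +
                                 comp$weight * dnorm(g, comp$mu, comp$sigma))
  expect_lt(max(abs(back$density[unclipped] - mix$density[unclipped])), 1e-9)
})

test_that("differential entropy matches closed forms", {
  g <- seq(20, 80, 0.1)
  expect_equal(differential_entropy(make_distribution(g, rep(1, length(g)))),
               log(60), tolerance = 0.01)

  gauss <- unimodal_target(40, 3, seq(10, 70, 0.1))
  expect_equal(differential_entropy(gauss), 0.5 * log(2 * pi * exp(1) * 9),
               tolerance = 1e-3)

  v <- numeric(length(g)); v[50] <- 1
  expect_equal(differential_entropy(make_distribution(g, v)), log(0.1),
               tolerance = 1e-12)

  # closed-form agreement across widths down to 5 * dr
  for (s in c(0.5, 1, 2, 5)) {
    d <- unimodal_target(45, s, seq(10, 80, 0.1))
    expect_equal(differential_entropy(d), 0.5 * log(2 * pi * exp(1) * s^2),
                 tolerance = 1e-3)
  }
})

test_that("KL divergence: identity, closed form, grid checks and flooring", {
  p <- unimodal_target(27, 3)
  expect_identical(kl_divergence(p, p), 0)

  q <- unimodal_target(28, 3)
  expect_equal(kl_divergence(p, q), 0.5 / 9, tolerance = 1e-4)

  q2 <- unimodal_target(28, 3, seq(10, 80, 0.2))
  expect_error(kl_divergence(p, q2), "grid")

  # p with mass where q is below floor: large finite value plus a warning
  narrow <- unimodal_target(27, 0.5)
  expect_warning(v <- kl_divergence(p, narrow), "floor")
  expect_true(is.finite(v) && v > 1)
})

test_that("KL is non-negative and zero only at equality (property)", {
  set.seed(401)
  for (i in 1:25) {
    g <- default_grid()
    p <- random_mixture(g); q <- random_mixture(g)
    expect_gte(suppressWarnings(kl_divergence(p, q)), 0)
  }
})

test_that("operations preserve normalization (property)", {
  set.seed(402)
  for (i in 1:10) {
    d <- random_mixture(default_grid())
    expect_equal(sum(d$density) * d$dr, 1, tolerance = 1e-9)
    s <- subtract_component(d, gaussian_component(50, 4, 0.05))
    expect_equal(sum(s$density) * s$dr, 1, tolerance = 1e-9)
    r <- resample_distribution(d, seq(12, 78, 0.05))
    expect_equal(sum(r$density) * r$dr, 1, tolerance = 1e-9)
  }
})

test_that("target stats report entropy and support", {
  d <- unimodal_target(30, 2, seq(10, 50, 0.1))
  st <- target_stats(d)
  expect_lt(st$support[1], 30 - 3 * 2)
  expect_gt(st$support[2], 30 + 3 * 2)
  expect_equal(st$entropy, differential_entropy(d))
  st2 <- target_stats(d, floor_frac = 1e-3)
  expect_true(st2$support[1] > st$support[1] && st2$support[2] < st$support[2])
})
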