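# Shared builders for the test suite.  All fixtures are generated in code.

kT298 <- ebmetad:::.kB * 298

# Unimodal target with the PELDOR-like 3-A peak width on the default grid.
unimodal_target <- function(mu = 27, sigma = 3, grid = default_grid())
  gaussian_mixture_distribution(gaussian_component(mu, sigma), grid)

# Bimodal target mirroring betaine-bound distributions (peaks ~27 and ~42 A).
bimodal_target <- function(grid = default_grid())
  gaussian_mixture_distribution(list(gaussian_component(27, 3, 0.5),
                                     gaussian_component(42, 3, 0.5)), grid)

# Harmonic state with a 2-A basin SD at `center` (kappa = kT / sd^2).
basin_system <- function(center, basin_sd = 2, temperature = 298)
  toy_system(harmonic_potential(center, ebmetad:::.kB * temperature / basin_sd^2),
             temperature = temperature)

# Double well whose well curvature matches a 2-A basin SD:
# kappa_eff = 32 * barrier / (r_b - r_a)^2 = kT / 4.
fixture_double_well <- function(r_a = 27, r_b = 42, temperature = 298) {
  barrier <- ebmetad:::.kB * temperature / 4 * (r_b - r_a)^2 / 32
  toy_system(double_well_potential(r_a, r_b, barrier), temperature = temperature)
}

# Random smooth bias profile on a grid (sum of a few Gaussians).
random_vbar <- function(grid, n = 4, amp = 2) {
  v <- numeric(length(grid))
  for (i in seq_len(n)) {
    c0 <- runif(1, min(grid), max(grid))
    w0 <- runif(1, 1, 6)
    v <- v + runif(1, -amp, amp) * exp(-(grid - c0)^2 / (2 * w0^2))
  }
  v
}

# Random valid mixture distribution on a grid.
random_mixture <- function(grid, n_comp = sample(1:3, 1)) {
  comps <- lapply(seq_len(n_comp), function(i)
    gaussian_component(runif(1, min(grid) + 10, max(grid) - 10),
                       runif(1, 1.5, 5), runif(1, 0.2, 1)))
  suppressWarnings(gaussian_mixture_distribution(comps, grid))
}

# Synthetic bias history: hills at constant stride from explicit vectors.
synthetic_history <- function(target, centers, heights, stride = 500,
                              sigma_g = 0.5, t0 = 0) {
  h <- bias_history(target, sigma_g = sigma_g, stride = stride)
  tt <- t0 + stride * (seq_along(centers) - 1)
  for (i in seq_along(centers))
    h <- deposit(h, centers[i], tt[i], height = heights[i])
  h
}
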