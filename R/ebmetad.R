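## Ensemble-biased metadynamics: history-dependent Gaussian bias whose hill
## heights are inversely proportional to the target probability density, so
## the sampled ensemble converges to the target distance distribution with the
## minimum necessary perturbation.

#' EBMetaD run parameters
#'
#' @param t_tot Total number of integration steps (>= 10 * stride).
#' @param h0 Reference hill height (kcal/mol); the geometric-mean height under
#'   the inverse-probability rule.  Default 0.01.
#' @param sigma_g Hill width (A), default 0.5.
#' @param stride Deposition stride (steps), default 500 (one hill per ps at
#'   the default 2-fs-scale time step).
#' @param fill_frac Initial "filling" fraction of the run excluded from bias
#'   averaging, default 0.2.
#' @param seed Integer seed.
#' @param dt Integration time step (ps), default 0.002.
#' @param wall_k Force constant of the half-harmonic walls holding the
#'   collective variable inside the target support (kcal/mol/A^2), default 10.
#' @param hill_floor Regularization floor for the inverse-probability rule:
#'   hill heights and the wall support are computed with the target density
#'   floored at `hill_floor * max(rho)`, default 1e-2.  This caps the largest
#'   hill at `h0 / (hill_floor * max(rho) * exp(S))` and keeps the spurious
#'   work of rare support-edge excursions negligible (see the methods
#'   vignette); the numerical floor used in logarithms elsewhere stays at
#'   1e-6.
#' @param r_start Optional start coordinate (A); defaults to the potential
#'   minimum within the target support.
#' @return An object of class `ebmetad_params`.
#' @export
ebmetad_params <- function(t_tot, h0 = 0.01, sigma_g = 0.5, stride = 500L,
                           fill_frac = 0.2, seed = 1L, dt = 0.002,
                           wall_k = 10, hill_floor = 1e-2, r_start = NULL) {
  if (!is.numeric(t_tot) || t_tot <= 0) stop_validation("t_tot must be > 0")
  if (h0 <= 0) stop_validation("h0 must be > 0")
  if (sigma_g <= 0) stop_validation("sigma_g must be > 0")
  if (stride < 1) stop_validation("stride must be >= 1")
  if (fill_frac < 0 || fill_frac >= 1) stop_validation("fill_frac must be in [0, 1)")
  if (t_tot < 10 * stride) stop_validation("t_tot must be >= 10 * stride")
  if (hill_floor <= 0 || hill_floor >= 1)
    stop_validation("hill_floor must be in (0, 1)")
  structure(list(t_tot = as.numeric(t_tot), h0 = h0, sigma_g = sigma_g,
                 stride = as.integer(stride), fill_frac = fill_frac,
                 seed = as.integer(seed), dt = dt, wall_k = wall_k,
                 hill_floor = hill_floor, r_start = r_start),
            class = "ebmetad_params")
}

#' Hill height under the inverse-probability rule
#'
#' `h(s) = h0 / (rho(s) * exp(S_rho))`, with the target density floored at
#' `1e-6 * max(rho)`.  The `rho * exp(S_rho)` scaling is dimensionless and
#' makes `h0` the geometric-mean hill height: hills are larger in
#' low-probability regions of the target and smaller in high-probability
#' regions, which is what drives the sampled ensemble toward the target.
#'
#' @param target A `distance_distribution`.
#' @param stats `target_stats(target)` (recomputed if missing).
#' @param s Proposed hill center(s) (A); must lie on the target grid.
#' @param h0 Reference height (kcal/mol).
#' @return Height(s) in kcal/mol.
#' @export
hill_height <- function(target, stats = target_stats(target), s, h0) {
  assert_distribution(target, "target")
  if (any(s < target$grid[1] | s > target$grid[length(target$grid)]))
    stop_validation("hill center outside the target grid")
  rho <- approx(target$grid, target$density, xout = s)$y
  rho <- pmax(rho, density_floor(target$density))
  h0 / (rho * exp(stats$entropy))
}

new_bias_history <- function(sigma_g, stride, target, times = numeric(0),
                             centers = numeric(0), heights = numeric(0),
                             params = NULL) {
  structure(list(sigma_g = sigma_g, stride = as.integer(stride),
                 times = times, centers = centers, heights = heights,
                 target = target,
                 target_fingerprint = distribution_fingerprint(target),
                 params = params),
            class = "bias_history")
}

#' Create an empty bias history
#'
#' @param target The `distance_distribution` being targeted.
#' @param sigma_g Hill width (A).
#' @param stride Deposition stride (steps).
#' @return An object of class `bias_history`.
#' @export
bias_history <- function(target, sigma_g = 0.5, stride = 500L) {
  assert_distribution(target, "target")
  if (sigma_g <= 0) stop_validation("sigma_g must be > 0")
  new_bias_history(sigma_g, stride, target)
}

#' @export
print.bias_history <- function(x, ...) {
  cat(sprintf("<bias_history> %d hills, sigma_g = %.3f A, stride = %d steps\n",
              length(x$times), x$sigma_g, x$stride))
  if (length(x$times))
    cat(sprintf("  t = %d .. %d; heights %.4g .. %.4g kcal/mol\n",
                as.integer(min(x$times)), as.integer(max(x$times)),
                min(x$heights), max(x$heights)))
  invisible(x)
}

#' Deposit one hill
#'
#' Appends a Gaussian hill centered at the current collective-variable value.
#' The height follows [hill_height()] unless given explicitly.  Times must
#' advance by exactly one stride.
#'
#' @param history A `bias_history`.
#' @param s Hill center (A).
#' @param t Deposition time (steps); first hill at any time, thereafter
#'   `t = last time + stride`.
#' @param height Optional explicit height (kcal/mol).
#' @param h0 Reference height used when `height` is missing.
#' @return The extended `bias_history`.
#' @export
deposit <- function(history, s, t, height = NULL, h0 = 0.01) {
  if (!inherits(history, "bias_history")) stop_validation("history must be a bias_history")
  n <- length(history$times)
  if (n > 0 && t != history$times[n] + history$stride)
    stop_validation("deposition time must be the previous time + stride")
  if (is.null(height)) height <- hill_height(history$target, s = s, h0 = h0)
  if (height <= 0) stop_validation("hill height must be > 0")
  history$times <- c(history$times, t)
  history$centers <- c(history$centers, s)
  history$heights <- c(history$heights, height)
  history
}

#' Evaluate the bias potential at a time
#'
#' `V(s, t)`: sum over hills deposited at or before `t` of
#' `h * exp(-(s - c)^2 / (2 sigma_g^2))`, with hills farther than
#' `6 sigma_g` from `s` truncated to zero.  The force is `-dV/ds`.
#'
#' @param history A `bias_history`.
#' @param s Evaluation point(s) (A).
#' @param t Time (steps); `Inf` for the full history.
#' @return List with `energy` (kcal/mol) and `force` (kcal/mol/A), same
#'   length as `s`.
#' @export
bias_value <- function(history, s, t = Inf) {
  if (!inherits(history, "bias_history")) stop_validation("history must be a bias_history")
  keep <- history$times <= t
  cen <- history$centers[keep]; hts <- history$heights[keep]
  e <- numeric(length(s)); f <- numeric(length(s))
  if (length(cen)) {
    s2 <- 2 * history$sigma_g^2
    for (i in seq_along(s)) {
      d <- s[i] - cen
      use <- abs(d) <= 6 * history$sigma_g
      g <- hts[use] * exp(-d[use]^2 / s2)
      e[i] <- sum(g)
      f[i] <- sum(g * d[use]) * 2 / s2
    }
  }
  list(energy = e, force = f)
}

#' Run an EBMetaD simulation
#'
#' Integrates the toy system with the history-dependent bias force added at
#' every step, depositing hills every `stride` steps with heights from the
#' inverse-probability rule, and recording the collective variable at every
#' deposition stride.  Half-harmonic walls at the target support edges keep
#' the coordinate on-grid.  Fully reproducible under a fixed seed.
#'
#' @param system A `toy_system`.
#' @param target The `distance_distribution` to reproduce; its grid must cover
#'   the reachable coordinate range.
#' @param params An `ebmetad_params`.
#' @return An object of class `ebmetad_run`: list with `trajectory` (data
#'   frame `step`, `time`, `cv`, `instantaneous_bias`), `history`
#'   (`bias_history`), `system`, `params`, and `t_fill` (production window
#'   start, steps).
#' @examples
#' \donttest{
#' sys <- toy_system(harmonic_potential(30, 2))
#' tgt <- gaussian_mixture_distribution(gaussian_component(31, 1),
#'                                      grid = seq(20, 40, 0.1))
#' run <- run_ebmetad(sys, tgt, ebmetad_params(t_tot = 2e5, seed = 7))
#' }
#' @export
run_ebmetad <- function(system, target, params) {
  if (!inherits(system, "toy_system")) stop_validation("system must be a toy_system")
  assert_distribution(target, "target")
  if (!inherits(params, "ebmetad_params")) stop_validation("params must be ebmetad_params")
  stats <- target_stats(target, floor_frac = params$hill_floor)
  rho_f <- pmax(target$density, params$hill_floor * max(target$density))
  h_grid <- params$h0 / (rho_f * exp(stats$entropy))
  support <- stats$support
  r_start <- params$r_start
  if (is.null(r_start)) {
    inside <- target$grid >= support[1] & target$grid <= support[2]
    u <- eval_potential(system, target$grid[inside])$energy
    r_start <- target$grid[inside][which.min(u)]
  }
  p <- system$potential
  set.seed(params$seed)
  res <- .cv_dynamics_core(pot_code(p), pot_params(p),
                           p$grid %||% numeric(0), p$energies %||% numeric(0),
                           system$temperature, system$friction, system$mass,
                           params$dt, r_start, 0, params$t_tot,
                           params$stride, TRUE, target$grid, h_grid,
                           params$sigma_g, params$stride,
                           support[1], support[2], params$wall_k)
  traj <- data.frame(step = res$step, time = res$step * params$dt,
                     cv = res$cv, instantaneous_bias = res$inst_bias)
  history <- new_bias_history(params$sigma_g, params$stride, target,
                              res$hill_time, res$hill_center, res$hill_height,
                              params)
  t_fill <- params$fill_frac * params$t_tot
  prod <- traj$cv[traj$step >= t_fill]
  off <- mean(prod < support[1] | prod > support[2])
  if (off > 0.01)
    warning(sprintf("CV outside the target support for %.1f%% of production steps",
                    100 * off))
  structure(list(trajectory = traj, history = history, system = system,
                 params = params, t_fill = t_fill), class = "ebmetad_run")
}

#' @export
print.ebmetad_run <- function(x, ...) {
  cat(sprintf("<ebmetad_run> %g steps (dt = %g ps), %d hills, seed %d\n",
              x$params$t_tot, x$params$dt, length(x$history$times),
              x$params$seed))
  invisible(x)
}

#' Convergence of the sampled ensemble to the target
#'
#' Kullback-Leibler divergence (nats) between the production-window histogram
#' of the collective variable and the target distribution, both binned at
#' `bin_width` over the target grid.  Coarser-than-grid bins keep the
#' finite-sample bias of the plug-in KL estimator small.
#'
#' @param run An `ebmetad_run`, or a numeric vector of production CV values
#'   (then `target` is required).
#' @param target Target `distance_distribution` (defaults to the run's).
#' @param bin_width Histogram bin width (A), default 0.5.
#' @return KL divergence in nats.
#' @export
convergence_kl <- function(run, target = NULL, bin_width = 0.5) {
  if (inherits(run, "ebmetad_run")) {
    target <- target %||% run$history$target
    cv <- run$trajectory$cv[run$trajectory$step >= run$t_fill]
  } else {
    cv <- run
    if (is.null(target)) stop_validation("target required for a raw CV vector")
  }
  assert_distribution(target, "target")
  breaks <- seq(target$grid[1] - bin_width / 2,
                target$grid[length(target$grid)] + 1.5 * bin_width, by = bin_width)
  cv <- cv[cv >= breaks[1] & cv <= breaks[length(breaks)]]
  p <- tabulate(findInterval(cv, breaks), nbins = length(breaks) - 1)
  q <- tabulate(findInterval(target$grid, breaks), nbins = length(breaks) - 1)
  qm <- vapply(seq_len(length(breaks) - 1), function(i) {
    sel <- target$grid >= breaks[i] & target$grid < breaks[i + 1]
    sum(target$density[sel]) * target$dr
  }, numeric(1))
  discrete_kl(p / sum(p), qm / sum(qm))
}

## Discrete KL with relative flooring of q where p has mass; p = 0 bins drop.
discrete_kl <- function(p, q) {
  idx <- p > 0
  qf <- pmax(q, 1e-6 * max(q))
  sum(p[idx] * log(p[idx] / qf[idx]))
}
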