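## Synthetic scenarios: pairs of toy states with distinct unbiased distance
## basins (mirroring outward- and inward-facing conformations of a
## transporter, with basins near 42 and 27 A), target distributions (unimodal
## or bimodal Gaussian mixtures standing in for regularized PELDOR
## distributions), and scripted ranking experiments.

#' Specify a ranking scenario
#'
#' Two toy states A and B with harmonic distance basins of equal width but
#' distinct centers, and a target distance distribution given as a Gaussian
#' mixture.  Basins must be separated by at least 3 combined standard
#' deviations so the states are genuinely distinct.
#'
#' @param name Scenario name.
#' @param basin_a,basin_b Unbiased mean distances of states A and B (A);
#'   defaults 27 and 42 mirror betaine-bound and betaine-free peak positions.
#' @param basin_sd Unbiased SD of each basin (A), default 2 (the harmonic
#'   force constant is `kT / basin_sd^2`).
#' @param target_components List of `gaussian_component`s (defaults to a
#'   single peak on basin A with width 3 A).
#' @param seeds Distinct integer seeds, default 1:5.
#' @param grid Distance grid (A).
#' @param temperature Temperature (K), default 298.
#' @param t_tot Steps per run, default 5e6.
#' @param ... Further arguments to [ebmetad_params()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, basin_a = 27, basin_b = 42, basin_sd = 2,
                          target_components = list(gaussian_component(basin_a, 3)),
                          seeds = 1:5, grid = default_grid(),
                          temperature = 298, t_tot = 5e6, ...) {
  if (basin_sd <= 0) stop_validation("basin_sd must be > 0")
  combined <- sqrt(2) * basin_sd
  if (abs(basin_b - basin_a) < 3 * combined)
    stop_validation("basins overlap: separation must be >= 3 combined SDs")
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop_validation("seeds must be distinct")
  structure(list(name = name, basin_a = basin_a, basin_b = basin_b,
                 basin_sd = basin_sd, target_components = target_components,
                 seeds = seeds, grid = grid, temperature = temperature,
                 t_tot = t_tot, extra = list(...)), class = "scenario_spec")
}

#' Materialize a scenario
#'
#' Builds the two toy systems, the target distribution and the run parameters
#' from a `scenario_spec`; deterministic given the spec.  When `dir` is given,
#' the system definitions, target distribution and parameters are also written
#' there as JSON / two-column text.
#'
#' @param spec A `scenario_spec`.
#' @param dir Optional output directory.
#' @return A list (class `scenario_bundle`) with `system_a`, `system_b`,
#'   `target`, `params_for(seed)` and the spec.
#' @export
make_scenario <- function(spec, dir = NULL) {
  if (!inherits(spec, "scenario_spec")) stop_validation("spec must be a scenario_spec")
  kT <- thermal_energy(spec$temperature)
  kappa <- kT / spec$basin_sd^2
  sys_a <- toy_system(harmonic_potential(spec$basin_a, kappa),
                      temperature = spec$temperature)
  sys_b <- toy_system(harmonic_potential(spec$basin_b, kappa),
                      temperature = spec$temperature)
  target <- gaussian_mixture_distribution(spec$target_components, spec$grid)
  params_for <- function(seed)
    do.call(ebmetad_params,
            c(list(t_tot = spec$t_tot, seed = as.integer(seed)), spec$extra))
  bundle <- structure(list(system_a = sys_a, system_b = sys_b, target = target,
                           params_for = params_for, spec = spec),
                      class = "scenario_bundle")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_toy_system(sys_a, file.path(dir, "system_a.json"))
    write_toy_system(sys_b, file.path(dir, "system_b.json"))
    write_distribution(target, file.path(dir, "target.dat"),
                       comments = paste("scenario", spec$name))
    jsonlite::write_json(
      list(name = spec$name, basin_a = spec$basin_a, basin_b = spec$basin_b,
           basin_sd = spec$basin_sd, seeds = spec$seeds, t_tot = spec$t_tot,
           temperature = spec$temperature),
      file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = I(17))
  }
  bundle
}

#' Run a ranking scenario
#'
#' Runs EBMetaD for each state and seed, computes the work, its split-half SD,
#' the range-restricted work, and the convergence KL, and returns the ranking
#' table.  Runs whose production histogram misses the target by more than
#' `kl_flag` nats are flagged (not fatal).
#'
#' @param bundle A `scenario_bundle` from [make_scenario()].
#' @param r_max Flattening threshold for the restricted work (A), default 37.
#' @param kl_flag Convergence flag threshold (nats), default 0.05.
#' @param keep_runs Keep the full run objects (memory-heavy), default FALSE.
#' @return Data frame (class `ranking_report`) with columns `state`, `seed`,
#'   `W`, `split_half_sd`, `W_restricted`, `convergence_kl`, `flagged`; full
#'   runs in attribute `"runs"` when requested.
#' @export
run_scenario <- function(bundle, r_max = 37, kl_flag = 0.05,
                         keep_runs = FALSE) {
  if (!inherits(bundle, "scenario_bundle")) stop_validation("bundle must be a scenario_bundle")
  rows <- list(); runs <- list()
  for (state in c("A", "B")) {
    sys <- if (state == "A") bundle$system_a else bundle$system_b
    for (seed in bundle$spec$seeds) {
      run <- run_ebmetad(sys, bundle$target, bundle$params_for(seed))
      res <- analyze_run(run, r_max = r_max)
      kl <- convergence_kl(run)
      rows[[length(rows) + 1L]] <- data.frame(
        state = state, seed = seed, W = res$W,
        split_half_sd = res$split_half_sd, W_restricted = res$W_restricted,
        convergence_kl = kl, flagged = kl > kl_flag)
      if (keep_runs) runs[[paste(state, seed, sep = "_")]] <- run
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ranking_report", class(out))
  if (keep_runs) attr(out, "runs") <- runs
  out
}
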