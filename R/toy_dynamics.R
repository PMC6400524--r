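## Desk-scale Langevin dynamics of a single distance-like collective variable
## over analytic potentials, plus the coordination-number restraint used to
## keep ligands bound in the atomistic setting.

#' Analytic toy potentials
#'
#' Constructors for the potential energy functions the toy engine supports:
#' a harmonic well `U = kappa/2 (r - r0)^2`, a symmetric-minima double well
#' `U = B (r - r_a)^2 (r - r_b)^2` with `B` set so the barrier between the two
#' (zero-energy) minima equals `barrier_height`, and a piecewise-linear
#' tabulated potential with reflective domain edges.
#'
#' @param r0,kappa Harmonic minimum (A) and force constant (kcal/mol/A^2).
#' @param r_a,r_b Double-well minima (A).
#' @param barrier_height Barrier at the midpoint (kcal/mol).
#' @param grid,energies Uniform grid (A) and energies (kcal/mol) for the
#'   tabulated form.
#' @return An object of class `cv_potential`.
#' @export
harmonic_potential <- function(r0, kappa) {
  if (kappa <= 0) stop_validation("kappa must be > 0")
  structure(list(type = "harmonic", r0 = r0, kappa = kappa),
            class = "cv_potential")
}

#' @rdname harmonic_potential
#' @export
double_well_potential <- function(r_a, r_b, barrier_height) {
  if (r_b <= r_a) stop_validation("r_b must be > r_a")
  if (barrier_height <= 0) stop_validation("barrier_height must be > 0")
  structure(list(type = "double_well", r_a = r_a, r_b = r_b,
                 barrier_height = barrier_height), class = "cv_potential")
}

#' @rdname harmonic_potential
#' @export
tabulated_potential <- function(grid, energies) {
  check_uniform_grid(grid)
  if (length(energies) != length(grid) || any(!is.finite(energies)))
    stop_validation("energies must be finite and match the grid length")
  structure(list(type = "tabulated", grid = as.numeric(grid),
                 energies = as.numeric(energies)), class = "cv_potential")
}

pot_code <- function(p) switch(p$type, harmonic = 0L, double_well = 1L, tabulated = 2L)

pot_params <- function(p) {
  switch(p$type,
         harmonic = c(p$r0, p$kappa),
         double_well = c(p$r_a, p$r_b, p$barrier_height),
         tabulated = numeric(0))
}

#' Define a toy system
#'
#' A one-coordinate stochastic system: an analytic potential acting on the
#' distance-like collective variable, integrated with Langevin (BAOAB)
#' dynamics at a given temperature, friction, and mass.
#'
#' @param potential A `cv_potential`.
#' @param temperature Temperature (K), default 298.
#' @param friction Langevin friction (1/ps), default 1.
#' @param mass Effective mass of the coordinate (amu), default 50.
#' @return An object of class `toy_system`.
#' @examples
#' sys <- toy_system(harmonic_potential(30, 2))
#' @export
toy_system <- function(potential, temperature = 298, friction = 1, mass = 50) {
  if (!inherits(potential, "cv_potential"))
    stop_validation("potential must be a cv_potential")
  if (temperature < 0) stop_validation("temperature must be >= 0")
  if (friction <= 0) stop_validation("friction must be > 0")
  if (mass <= 0) stop_validation("mass must be > 0")
  structure(list(potential = potential, temperature = temperature,
                 friction = friction, mass = mass), class = "toy_system")
}

#' Evaluate the toy potential
#'
#' Energy and force `-dU/dr` at one or more coordinates.  Closed forms are
#' differentiated analytically; the tabulated form uses a centered finite
#' difference with step `dr / 10` and errors outside its domain.
#'
#' @param system A `toy_system` (or `cv_potential`).
#' @param r Coordinate(s) in A.
#' @return List with numeric `energy` (kcal/mol) and `force` (kcal/mol/A).
#' @export
eval_potential <- function(system, r) {
  p <- if (inherits(system, "toy_system")) system$potential else system
  if (!inherits(p, "cv_potential")) stop_validation("not a toy system or potential")
  switch(p$type,
    harmonic = list(energy = 0.5 * p$kappa * (r - p$r0)^2,
                    force = -p$kappa * (r - p$r0)),
    double_well = {
      half <- 0.5 * (p$r_b - p$r_a)
      B <- p$barrier_height / half^4
      a <- r - p$r_a; b <- r - p$r_b
      list(energy = B * a^2 * b^2, force = -2 * B * a * b * (a + b))
    },
    tabulated = {
      if (any(r < p$grid[1] | r > p$grid[length(p$grid)]))
        stop_validation("coordinate outside tabulated potential domain")
      dr <- p$grid[2] - p$grid[1]
      u <- function(x) approx(p$grid, p$energies, xout = x, rule = 2)$y
      h <- dr / 10
      list(energy = u(r), force = -(u(r + h) - u(r - h)) / (2 * h))
    })
}

#' Boltzmann distribution of a toy system on a grid
#'
#' Normalized `exp(-U(r)/kT)` on the grid (max-shifted for overflow safety).
#' Serves as the analytic reference for debiasing and zero-bias tests.
#'
#' @param system A `toy_system`.
#' @param grid Uniform distance grid (A).
#' @param temperature Temperature (K); defaults to the system temperature.
#' @return A `distance_distribution`.
#' @export
boltzmann_profile <- function(system, grid = default_grid(),
                              temperature = system$temperature) {
  u <- eval_potential(system, grid)$energy
  kT <- thermal_energy(temperature)
  make_distribution(grid, exp(-(u - min(u)) / kT))
}

#' Dynamics state
#'
#' @param r Coordinate (A).
#' @param velocity Velocity (A/ps).
#' @param step Step counter.
#' @return An object of class `dynamics_state`.
#' @export
dynamics_state <- function(r, velocity = 0, step = 0L) {
  structure(list(r = r, velocity = velocity, step = as.integer(step),
                 force = NULL), class = "dynamics_state")
}

#' Single Langevin (BAOAB) integration step
#'
#' One step of the BAOAB splitting.  The total force is the potential force
#' plus, optionally, an external force from `extra_force(r)` (e.g. a restraint
#' or a metadynamics bias).  Uses R's RNG stream, so `set.seed()` makes
#' trajectories reproducible.  Long runs should use [run_langevin()] or
#' [run_ebmetad()], which drive the compiled integrator.
#'
#' @param system A `toy_system`.
#' @param state A `dynamics_state`.
#' @param dt Time step (ps); requires `dt * friction < 1`.
#' @param extra_force Optional function of `r` returning a force (kcal/mol/A).
#' @return The updated `dynamics_state`.
#' @export
langevin_step <- function(system, state, dt, extra_force = NULL) {
  if (!inherits(state, "dynamics_state")) stop_validation("state must be a dynamics_state")
  if (dt <= 0 || dt * system$friction >= 1)
    stop_validation("require dt > 0 and dt * friction < 1")
  ftot <- function(r) {
    f <- eval_potential(system, r)$force
    if (!is.null(extra_force)) f <- f + extra_force(r)
    f
  }
  kT <- .kB * system$temperature
  c1 <- exp(-system$friction * dt)
  sigO <- if (system$temperature > 0) sqrt(kT * .KCAL / system$mass * (1 - c1^2)) else 0
  x <- state$r; v <- state$velocity
  F <- state$force %||% ftot(x)
  v <- v + 0.5 * dt * .KCAL * F / system$mass
  x <- x + 0.5 * dt * v
  v <- c1 * v + sigO * rnorm(1)
  x <- x + 0.5 * dt * v
  F <- ftot(x)
  v <- v + 0.5 * dt * .KCAL * F / system$mass
  if (!is.finite(x) || !is.finite(v))
    stop("non-finite coordinate at step ", state$step + 1L)
  out <- dynamics_state(x, v, state$step + 1L)
  out$force <- F
  out
}

#' Run unbiased Langevin dynamics
#'
#' Compiled BAOAB integration of the toy system, recording the collective
#' variable every `sample_stride` steps.
#'
#' @param system A `toy_system`.
#' @param nsteps Number of steps.
#' @param r_start Initial coordinate (A).
#' @param dt Time step (ps).
#' @param sample_stride Recording stride (steps).
#' @param seed Optional integer seed (calls `set.seed`).
#' @return Data frame with columns `step`, `time` (ps), `cv` (A).
#' @export
run_langevin <- function(system, nsteps, r_start, dt = 0.002,
                         sample_stride = 100L, seed = NULL) {
  if (!inherits(system, "toy_system")) stop_validation("system must be a toy_system")
  if (nsteps <= 0) stop_validation("nsteps must be > 0")
  if (dt <= 0 || dt * system$friction >= 1)
    stop_validation("require dt > 0 and dt * friction < 1")
  if (!is.null(seed)) set.seed(seed)
  p <- system$potential
  res <- .cv_dynamics_core(pot_code(p), pot_params(p),
                           p$grid %||% numeric(0), p$energies %||% numeric(0),
                           system$temperature, system$friction, system$mass,
                           dt, r_start, 0, as.numeric(nsteps),
                           as.integer(sample_stride), FALSE,
                           numeric(0), numeric(0), 1, 1L, 0, 0, 0)
  data.frame(step = res$step, time = res$step * dt, cv = res$cv)
}

#' Coordination site definition
#'
#' A smooth contact count between a ligand atom and a set of coordinating
#' atoms, restrained from below by a half-harmonic.  In the atomistic setting
#' the cutoffs are 2.5 A for sodium and 2.0 A for betaine, with thresholds of
#' 1.3, 2.1 and 2.0 contacts for the Na1', Na2 and betaine sites and a force
#' constant of 50 kcal/mol.
#'
#' @param ligand Index of the ligand atom.
#' @param partners Indices of the coordinating atoms (non-empty).
#' @param cutoff Switching cutoff R (A, > 0).
#' @param threshold Minimum contact count C_min.
#' @param force_const Restraint force constant (kcal/mol, >= 0).
#' @return An object of class `coordination_site`.
#' @export
coordination_site <- function(ligand, partners, cutoff, threshold,
                              force_const = 50) {
  if (length(partners) == 0) stop_validation("partners must be non-empty")
  if (cutoff <= 0) stop_validation("cutoff must be > 0")
  if (force_const < 0) stop_validation("force_const must be >= 0")
  structure(list(ligand = as.integer(ligand), partners = as.integer(partners),
                 cutoff = cutoff, threshold = threshold,
                 force_const = force_const), class = "coordination_site")
}

#' Per-pair coordination switching function
#'
#' `(1 - x^8) / (1 - x^10)` with `x = r / R`.  The removable singularity at
#' `x = 1` is evaluated through its series expansion within `|x - 1| < 1e-6`
#' (analytic limit 8/10 = 0.8); `r = 0` gives the limit 1.
#'
#' @param r Pair distance(s) (A).
#' @param cutoff Switching cutoff R (A).
#' @return Contact contribution(s) in (0, 1].
#' @export
pair_coordination <- function(r, cutoff) {
  x <- r / cutoff
  out <- numeric(length(x))
  near <- abs(x - 1) < 1e-6
  d <- x[near] - 1
  # (1 - x^8)/(1 - x^10) = (8 + 28 d + ...)/(10 + 45 d + ...) around x = 1
  out[near] <- (8 + 28 * d) / (10 + 45 * d)
  xf <- x[!near]
  out[!near] <- (1 - xf^8) / (1 - xf^10)
  out[r == 0] <- 1
  out
}

#' Coordination number of a site
#'
#' Smooth contact count `sum_j (1 - (r_ij/R)^8) / (1 - (r_ij/R)^10)` between
#' the ligand atom and its coordinating atoms.
#'
#' @param coords Numeric matrix of atomic coordinates (rows = atoms, 3 columns, A).
#' @param site A `coordination_site`.
#' @return Contact count (dimensionless).
#' @export
coordination_number <- function(coords, site) {
  if (!inherits(site, "coordination_site")) stop_validation("site must be a coordination_site")
  coords <- as.matrix(coords)
  idx <- c(site$ligand, site$partners)
  if (any(idx < 1 | idx > nrow(coords))) stop_validation("atom index out of range")
  li <- coords[site$ligand, , drop = TRUE]
  rij <- sqrt(colSums((t(coords[site$partners, , drop = FALSE]) - li)^2))
  sum(pair_coordination(rij, site$cutoff))
}

#' Half-harmonic coordination restraint energy
#'
#' `E = force_const/2 * (c - threshold)^2` when the contact count falls below
#' the threshold, zero otherwise; the derivative is continuous at the
#' threshold.
#'
#' @param contacts Contact count(s).
#' @param site A `coordination_site`.
#' @return List with `energy` (kcal/mol) and `dEdC` (kcal/mol per contact).
#' @export
restraint_energy <- function(contacts, site) {
  if (!inherits(site, "coordination_site")) stop_validation("site must be a coordination_site")
  d <- pmin(contacts - site$threshold, 0)
  list(energy = 0.5 * site$force_const * d^2, dEdC = site$force_const * d)
}
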