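## Work analysis: the time-averaged bias, the work functional along the
## distance distribution, the debiased distribution, range-restricted work,
## and split-half uncertainties.
##
## W = kT * log( integral rho(r) exp((Vbar(r) - <Vbar>) / kT) dr ), where
## Vbar is the bias potential averaged over the production window and
## <Vbar> = integral rho Vbar dr.  W equals kT times the Kullback-Leibler
## divergence between the target (biased) and debiased distributions, is
## invariant to adding a constant to Vbar, and is >= 0 with equality iff
## Vbar is constant on the target support.

#' Construct an averaged-bias object
#'
#' Low-level constructor pairing a bias profile with the target it is scored
#' against; the offset `<Vbar>` is the quadrature mean of `vbar` under the
#' target density.  Used directly in analytic tests; simulation output goes
#' through [time_averaged_bias()].
#'
#' @param grid Uniform grid (A), identical to the target grid.
#' @param vbar Average bias potential on the grid (kcal/mol).
#' @param target A `distance_distribution`.
#' @param window Averaging window `c(t_f, t_tot)` (steps).
#' @return An object of class `averaged_bias`.
#' @export
averaged_bias <- function(grid, vbar, target, window = c(0, 1)) {
  assert_distribution(target, "target")
  if (!same_grid(list(grid = grid), target))
    stop_validation("grid must match the target grid")
  if (length(vbar) != length(grid) || any(!is.finite(vbar)))
    stop_validation("vbar must be finite and match the grid length")
  if (!(window[1] < window[2])) stop_validation("window must satisfy t_f < t_tot")
  structure(list(grid = as.numeric(grid), dr = target$dr,
                 vbar = as.numeric(vbar), window = as.numeric(window),
                 offset = sum(target$density * vbar) * target$dr,
                 target = target),
            class = "averaged_bias")
}

#' @export
print.averaged_bias <- function(x, ...) {
  cat(sprintf("<averaged_bias> window [%g, %g] steps, offset <Vbar> = %.4f kcal/mol\n",
              x$window[1], x$window[2], x$offset))
  invisible(x)
}

## Vbar on a window [a, b]: each hill deposited at time t contributes its
## Gaussian scaled by (b - max(t, a)) / (b - a) -- its exact residence time in
## the window -- so the time integral of V(r, t) is computed exactly from the
## hill record rather than from snapshots.
window_vbar <- function(history, a, b, grid) {
  keep <- history$times < b
  tt <- history$times[keep]
  w <- (b - pmax(tt, a)) / (b - a)
  cen <- history$centers[keep]; hts <- history$heights[keep] * w
  vbar <- numeric(length(grid))
  s2 <- 2 * history$sigma_g^2
  chunk <- 2000L
  for (i0 in seq(1, length(cen), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(cen))
    D <- outer(grid, cen[i0:i1], "-")
    G <- exp(-D^2 / s2)
    G[abs(D) > 6 * history$sigma_g] <- 0  # same truncation as bias_value()
    vbar <- vbar + as.numeric(G %*% hts[i0:i1])
  }
  vbar
}

#' Time-averaged bias potential
#'
#' `Vbar(r) = (t_tot - t_f)^-1 * integral_{t_f}^{t_tot} V(r, t) dt`, computed
#' exactly as a residence-weighted sum over the recorded hills, excluding the
#' initial filling time `t_f`.
#'
#' @param history A `bias_history`.
#' @param t_f Start of the averaging window (steps).
#' @param t_tot End of the averaging window (steps); at most one stride past
#'   the last hill.
#' @param target Target distribution for the offset (defaults to the history's
#'   own target).
#' @return An `averaged_bias`.
#' @export
time_averaged_bias <- function(history, t_f, t_tot,
                               target = history$target) {
  if (!inherits(history, "bias_history")) stop_validation("history must be a bias_history")
  assert_distribution(target, "target")
  if (!(t_f < t_tot)) stop_validation("empty averaging window: need t_f < t_tot")
  if (length(history$times) == 0) stop_validation("history contains no hills")
  if (t_tot > max(history$times) + history$stride)
    stop_validation("t_tot beyond the recorded history")
  vbar <- window_vbar(history, t_f, t_tot, target$grid)
  averaged_bias(target$grid, vbar, target, window = c(t_f, t_tot))
}

#' Work along the distance distribution
#'
#' The work functional scoring how much average bias was needed to impose the
#' target distribution: `W = kT * log sum(rho * exp((Vbar - <Vbar>)/kT)) * dr`,
#' evaluated with a max-shift so large biases cannot overflow.  Lower work
#' means the unbiased ensemble of the starting conformation is more compatible
#' with the target.  Adding any constant to `Vbar` leaves `W` unchanged.
#'
#' @param avg An `averaged_bias`.
#' @param target Target `distance_distribution` (defaults to `avg$target`).
#' @param temperature Temperature (K), default 298.
#' @return An object of class `work_result` with `W`, `offset`, `kT`
#'   (kcal/mol) and the averaging `window`.
#' @export
work <- function(avg, target = avg$target, temperature = 298) {
  if (!inherits(avg, "averaged_bias")) stop_validation("avg must be an averaged_bias")
  assert_distribution(target, "target")
  if (!same_grid(avg, target)) stop_validation("bias and target grids differ")
  if (any(!is.finite(avg$vbar))) stop_validation("non-finite Vbar")
  kT <- thermal_energy(temperature)
  offset <- sum(target$density * avg$vbar) * target$dr
  a <- (avg$vbar - offset) / kT
  m <- max(a)
  W <- kT * (m + log(sum(target$density * exp(a - m)) * target$dr))
  structure(list(W = W, offset = offset, split_half_sd = NA_real_,
                 r_max = NA_real_, kT = kT, window = avg$window),
            class = "work_result")
}

#' @export
print.work_result <- function(x, ...) {
  cat(sprintf("<work_result> W = %.4f kcal/mol (offset %.4f, kT = %.4f)\n",
              x$W, x$offset, x$kT))
  if (!is.na(x$split_half_sd))
    cat(sprintf("  split-half SD = %.4f kcal/mol\n", x$split_half_sd))
  if (!is.na(x$r_max))
    cat(sprintf("  restricted to r < %.1f A\n", x$r_max))
  invisible(x)
}

#' Debiased distribution
#'
#' Removes the average bias from the target ensemble:
#' `rho_debiased = exp(-F(r)/kT) / C` with `F(r) = -Vbar(r) - kT log(rho(r))`,
#' equivalently `rho_debiased` proportional to `rho * exp(Vbar / kT)`.  This
#' estimates the unbiased distribution of the collective variable of the
#' simulated system.  `F` is reported with its additive constant fixed so that
#' `min(F) = 0`; all downstream quantities are invariant to that constant.
#'
#' @param avg An `averaged_bias`.
#' @param target Target `distance_distribution` (defaults to `avg$target`).
#' @param temperature Temperature (K), default 298.
#' @return An object of class `debias_result`: `F` (kcal/mol on the grid),
#'   `distribution` (the debiased `distance_distribution`), and the
#'   normalization `C`.
#' @export
debias_distribution <- function(avg, target = avg$target, temperature = 298) {
  if (!inherits(avg, "averaged_bias")) stop_validation("avg must be an averaged_bias")
  assert_distribution(target, "target")
  if (!same_grid(avg, target)) stop_validation("bias and target grids differ")
  kT <- thermal_energy(temperature)
  a <- avg$vbar / kT
  m <- max(a)
  raw <- target$density * exp(a - m)
  if (sum(raw) <= 0)
    stop_validation("target density is zero everywhere the bias is finite")
  deb <- make_distribution(target$grid, raw)
  Fr <- -avg$vbar - kT * log(pmax(target$density, density_floor(target$density)))
  Fr <- Fr - min(Fr)
  C <- sum(exp(-Fr / kT)) * target$dr
  structure(list(F = Fr, distribution = deb, C = C), class = "debias_result")
}

#' Range-restricted work
#'
#' Recomputes the work using a bias flattened beyond `r_max`
#' (`Vbar_r(r) = Vbar(min(r, r_max))`) against a correspondingly modified
#' reference distribution `rho_modified` proportional to
#' `exp((-F(r) - Vbar_r(r)) / kT)`, i.e. `rho * exp((Vbar - Vbar_r)/kT)`,
#' normalized over the full grid.  This isolates the work spent matching the
#' distribution below `r_max` (default 37 A), the range unaffected by
#' interprotomer contributions.
#'
#' @param avg An `averaged_bias`.
#' @param target Target `distance_distribution` (defaults to `avg$target`).
#' @param temperature Temperature (K), default 298.
#' @param r_max Flattening threshold (A); must not lie below the grid start.
#' @return An object of class `restricted_work_result`: `W_restricted`,
#'   `r_max`, `rho_modified`, `C_mod`, `kT`.
#' @export
restricted_work <- function(avg, target = avg$target, temperature = 298,
                            r_max = 37) {
  if (!inherits(avg, "averaged_bias")) stop_validation("avg must be an averaged_bias")
  assert_distribution(target, "target")
  if (!same_grid(avg, target)) stop_validation("bias and target grids differ")
  grid <- target$grid
  if (r_max < grid[1]) stop_validation("r_max lies below the grid start")
  kT <- thermal_energy(temperature)
  vbar_r <- approx(grid, avg$vbar, xout = pmin(grid, r_max))$y
  a <- (avg$vbar - vbar_r) / kT
  m <- max(a)
  rho_mod <- make_distribution(grid, target$density * exp(a - m))
  avg_r <- averaged_bias(grid, vbar_r, rho_mod, window = avg$window)
  wr <- work(avg_r, rho_mod, temperature)
  Cm <- sum(target$density * exp(a - m)) * target$dr # normalization before scaling
  structure(list(W_restricted = wr$W, r_max = r_max, rho_modified = rho_mod,
                 C_mod = Cm * exp(m), kT = kT), class = "restricted_work_result")
}

#' Split-half uncertainty of the work
#'
#' Computes the time-averaged bias separately on the two halves of the
#' production window, the work for each, and returns their dispersion.  With
#' only two values the population SD `|W1 - W2| / 2` is reported by default
#' (the spread of the two numbers); `type = "sample"` gives `|W1 - W2| /
#' sqrt(2)`.
#'
#' @param history A `bias_history`.
#' @param t_f,t_tot Production window (steps).
#' @param target Target distribution (defaults to the history's).
#' @param temperature Temperature (K), default 298.
#' @param type `"population"` (default) or `"sample"`.
#' @return The SD (kcal/mol), with the two half-window work values attached as
#'   attribute `"works"`.
#' @export
split_half_uncertainty <- function(history, t_f, t_tot,
                                   target = history$target, temperature = 298,
                                   type = c("population", "sample")) {
  type <- match.arg(type)
  if (!inherits(history, "bias_history")) stop_validation("history must be a bias_history")
  if (!(t_f < t_tot)) stop_validation("need t_f < t_tot")
  t_mid <- (t_f + t_tot) / 2
  n1 <- sum(history$times >= t_f & history$times < t_mid)
  n2 <- sum(history$times >= t_mid & history$times < t_tot)
  if (n1 < 2 || n2 < 2)
    stop_validation("fewer than 2 hills in one half of the production window")
  w1 <- work(averaged_bias(target$grid, window_vbar(history, t_f, t_mid, target$grid),
                           target, c(t_f, t_mid)), target, temperature)$W
  w2 <- work(averaged_bias(target$grid, window_vbar(history, t_mid, t_tot, target$grid),
                           target, c(t_mid, t_tot)), target, temperature)$W
  s <- abs(w1 - w2) / if (type == "population") 2 else sqrt(2)
  attr(s, "works") <- c(w1, w2)
  s
}

#' Full work analysis of an EBMetaD run
#'
#' Convenience wrapper: averages the bias over the production window and
#' returns the work, the split-half SD, and (optionally) the range-restricted
#' work.
#'
#' @param run An `ebmetad_run`.
#' @param temperature Temperature (K); defaults to the system temperature.
#' @param r_max Optional flattening threshold (A) for the restricted work.
#' @return A `work_result`, with `W_restricted` attached when `r_max` is given.
#' @export
analyze_run <- function(run, temperature = run$system$temperature,
                        r_max = NULL) {
  if (!inherits(run, "ebmetad_run")) stop_validation("run must be an ebmetad_run")
  avg <- time_averaged_bias(run$history, run$t_fill, run$params$t_tot)
  res <- work(avg, temperature = temperature)
  res$split_half_sd <- as.numeric(
    split_half_uncertainty(run$history, run$t_fill, run$params$t_tot,
                           temperature = temperature))
  if (!is.null(r_max)) {
    res$r_max <- r_max
    res$W_restricted <- restricted_work(avg, temperature = temperature,
                                        r_max = r_max)$W_restricted
  }
  res
}
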