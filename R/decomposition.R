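## Attribute the total work to individual molecular features by comparing the
## biased distribution of each feature with its debiased (reweighted)
## counterpart, per-feature work = kT * D_KL(biased || debiased).

#' Debiasing frame weights
#'
#' Weights proportional to `exp(+Vbar(s_t) / kT)` for the production-window
#' frames, normalized to mean 1.  Reweighting any per-frame observable with
#' these weights estimates its distribution in the unbiased ensemble; in
#' particular the reweighted histogram of the collective variable itself
#' reproduces the debiased distribution in the converged limit.  The
#' time-averaged bias (not the instantaneous final bias) is used, consistent
#' with the averaging window of the work functional.
#'
#' @param traj An `ebmetad_run`, a trajectory data frame with a `cv` column,
#'   or a numeric vector of collective-variable values.  For a run, only
#'   production-window frames are used.
#' @param avg An `averaged_bias` (defaults to the run's production average).
#' @param temperature Temperature (K), default 298.
#' @return Numeric weights (mean 1) with attribute `"ess"`, the Kish effective
#'   sample size.  A warning is raised if the weights concentrate on fewer
#'   than 1% of frames.
#' @export
frame_weights <- function(traj, avg = NULL, temperature = 298) {
  if (inherits(traj, "ebmetad_run")) {
    if (is.null(avg))
      avg <- time_averaged_bias(traj$history, traj$t_fill, traj$params$t_tot)
    cv <- traj$trajectory$cv[traj$trajectory$step >= traj$t_fill]
  } else if (is.data.frame(traj)) {
    cv <- traj$cv
  } else {
    cv <- as.numeric(traj)
  }
  if (is.null(avg)) stop_validation("avg (averaged_bias) is required")
  if (!inherits(avg, "averaged_bias")) stop_validation("avg must be an averaged_bias")
  if (length(cv) == 0) stop_validation("no frames in the averaging window")
  kT <- thermal_energy(temperature)
  v <- approx(avg$grid, avg$vbar, xout = cv, rule = 2)$y
  w <- exp((v - max(v)) / kT)
  w <- w / mean(w)
  ess <- sum(w)^2 / sum(w^2)
  if (ess < 0.01 * length(w))
    warning(sprintf("effective sample size %.1f (< 1%% of %d frames)",
                    ess, length(w)))
  attr(w, "ess") <- ess
  w
}

#' Freedman-Diaconis histogram breaks
#'
#' @param x Sample values.
#' @return Break points covering the observed range.
#' @export
fd_breaks <- function(x) {
  h <- 2 * IQR(x) / length(x)^(1 / 3)
  if (h <= 0) h <- diff(range(x)) / 10
  if (h <= 0) h <- 1
  n <- max(1L, ceiling(diff(range(x)) / h))
  seq(min(x) - 1e-9, max(x) + 1e-9, length.out = n + 1L)
}

#' Angle histogram breaks
#'
#' Bins on `[-180, 180)` degrees; negative angles denote probes pointing
#' toward one another, positive away.
#'
#' @param width Bin width in degrees, default 5.
#' @return Break points.
#' @export
angle_breaks <- function(width = 5) seq(-180, 180, by = width)

#' Per-feature work
#'
#' Histograms one molecular feature (a distance, an angle, or a 0/1 contact
#' indicator) with unit weights (biased) and with debiasing weights
#' (debiased), and returns `kT * D_KL(biased || debiased)` (forward direction,
#' the default) as the work associated with imposing or preventing that
#' feature.  Both histograms share the same bins (Freedman-Diaconis on the
#' biased sample unless given).
#'
#' @param feature Numeric per-frame feature values, aligned with `weights`.
#' @param weights Debiasing weights from [frame_weights()].
#' @param bins Histogram breaks; `NULL` for Freedman-Diaconis,
#'   [angle_breaks()] for angular features.
#' @param temperature Temperature (K), default 298.
#' @param name Feature name for reporting.
#' @param direction `"forward"` (`D_KL(biased || debiased)`, as reported) or
#'   `"reverse"`.
#' @return An object of class `feature_work`: `name`, `work` (kcal/mol),
#'   normalized `biased` and `debiased` histograms, `breaks`, `ess`.
#' @export
feature_work <- function(feature, weights, bins = NULL, temperature = 298,
                         name = "feature", direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  feature <- as.numeric(feature)
  if (length(feature) == 0) stop_validation("empty feature series")
  if (any(!is.finite(feature))) stop_validation("feature values must be finite")
  if (length(weights) != length(feature))
    stop_validation("weights and feature must have the same length")
  breaks <- bins %||% fd_breaks(feature)
  if (min(feature) < breaks[1] || max(feature) > breaks[length(breaks)])
    stop_validation("bins do not cover the observed feature range")
  idx <- findInterval(feature, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  cnt <- tabulate(idx, nbins = nb)
  wsum <- vapply(seq_len(nb), function(i) sum(weights[idx == i]), numeric(1))
  occ <- cnt > 0
  if (any(cnt[occ] < 10))
    warning("fewer than 10 counts in some occupied bins; feature work may be noisy")
  p <- cnt / sum(cnt)
  q <- wsum / sum(wsum)
  kT <- thermal_energy(temperature)
  kl <- if (direction == "forward") discrete_kl(p, q) else discrete_kl(q, p)
  structure(list(name = name, work = kT * kl, biased = p, debiased = q,
                 breaks = breaks, ess = attr(weights, "ess")),
            class = "feature_work")
}

#' @export
print.feature_work <- function(x, ...) {
  cat(sprintf("<feature_work> %s: %.4f kcal/mol over %d bins\n",
              x$name, x$work, length(x$biased)))
  invisible(x)
}

#' Decompose a run into per-feature work contributions
#'
#' Applies [feature_work()] to each column of a feature table using the run's
#' debiasing weights.
#'
#' @param run An `ebmetad_run`.
#' @param features Data frame of per-frame feature values for the production
#'   window (one column per feature), aligned with the production frames.
#' @param bins Optional named list of break vectors per feature.
#' @param temperature Temperature (K); defaults to the system temperature.
#' @return Data frame with columns `name`, `work`, `n_frames`, `ess`.
#' @export
decompose_work <- function(run, features, bins = list(),
                           temperature = run$system$temperature) {
  if (!inherits(run, "ebmetad_run")) stop_validation("run must be an ebmetad_run")
  w <- frame_weights(run, temperature = temperature)
  if (nrow(features) != length(w))
    stop_validation("features must have one row per production frame")
  rows <- lapply(names(features), function(nm) {
    fw <- feature_work(features[[nm]], w, bins = bins[[nm]],
                       temperature = temperature, name = nm)
    data.frame(name = nm, work = fw$work, n_frames = length(w),
               ess = attr(w, "ess"))
  })
  do.call(rbind, rows)
}
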