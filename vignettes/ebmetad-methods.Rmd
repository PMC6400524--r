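---
title: "Ensemble-biased metadynamics on distance distributions: models, parameters and design choices"
author: "ebmetad package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-biased metadynamics on distance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmetad)
```

## The problem

Pulsed EPR (DEER/PELDOR) on a pair of nitroxide spin labels yields a full
probability distribution ρ(r) of the label–label distance, not a single
number.  When several structural models of a protein are available — say the
outward- and inward-facing conformations of a secondary transporter — a
natural question is which model is most *compatible* with that measured
ensemble.  Ensemble-biased metadynamics (EBMetaD) answers it by force: a
simulation started from each model is biased, as gently as possible, until its
sampled distance distribution matches ρ(r), and the amount of biasing energy
required becomes the compatibility score.  Less work ⇒ the unbiased ensemble
of that model was already closer to the data.

This package implements the full method at "desk scale": the distance
coordinate is evolved by Langevin dynamics over analytic toy potentials
instead of all-atom molecular dynamics.  Everything downstream of the dynamics
— the hill-deposition rule, the work functional, debiasing, range restriction,
split-half errors, per-feature decomposition — is the method itself, and is
exercised against analytic oracles.

## The sampling model

The collective variable r (Å) follows underdamped Langevin dynamics under a
potential U(r), integrated with the BAOAB splitting.  Units are Å, kcal/mol,
ps and amu, with k = 0.0019872041 kcal mol⁻¹ K⁻¹ and T = 298 K by default, so
kT ≈ 0.592 kcal/mol.  Defaults: time step dt = 0.002 ps (the 2-fs scale of
atomistic simulation), friction γ = 1 ps⁻¹, mass m = 50 amu.  These give a
position decorrelation time of a few ps in a harmonic well, i.e. a few
thousand steps; 5×10⁶-step production runs therefore contain thousands of
effectively independent samples.  The integrator is exact enough at these
settings that a 5×10⁵-step unbiased harmonic run reproduces the equipartition
variance kT/κ to within a few percent, and 2×10⁶–5×10⁶-step runs reproduce the
Boltzmann density to KL < 0.01 nats.

Available potentials: harmonic (r₀, κ), a quartic double well
U = B(r−r_a)²(r−r_b)² with B set by the barrier height, and a tabulated
piecewise-linear form with reflective domain edges.

## The bias

Every `stride` steps (default 500, i.e. one hill per ps) a Gaussian hill of
width σ_G = 0.5 Å is added at the current CV position s:

  h(s) = h₀ / (ρ(s) · e^{S_ρ}),

where S_ρ is the differential entropy of the target.  Hills are *larger where
the target density is smaller*; at stationarity the deposition rate ρ(s)·h(s)
is uniform, so the bias grows evenly and the sampled ensemble stays on the
target.  The factor e^{S_ρ} is a dimensionless normalization that makes h₀
(default 0.01 kcal/mol) the geometric-mean hill height; for a uniform target
every hill is exactly h₀.

### Regularizing the inverse-probability rule

Taken literally, h ∝ 1/ρ diverges in the target's tails.  Two floors are used,
with different jobs:

* a **numerical floor** of 10⁻⁶ × max ρ in logarithms and exponentials
  (entropy sums, KL, free-energy profiles), which only prevents singularities;
* a **regularization floor** of 10⁻² × max ρ for hill heights and for the
  placement of the confining walls.

The second floor is a genuine methodological parameter.  The height cap it
implies is 100·h₀/(max ρ · e^{S_ρ}) ≈ 100·h₀/√e ≈ 0.6 kcal/mol ≈ kT for any
Gaussian-like target — i.e. even the largest hill remains quasi-static.  With
a much smaller floor the cap grows into the multi-kcal/mol range and a single
rare excursion to the support edge deposits a hill that overwhelms the local
landscape; such hills pile up against the walls, punch through them, or dig
self-trapping pockets, and they dominate the work as heavy-tailed noise.  With
the kT-scale cap the spurious work in the zero-bias limit (see below) is a few
×10⁻³ kcal/mol across seeds and run lengths.  The cost is that the walls sit
at ±3.0σ rather than ±3.7σ of a Gaussian peak, truncating ~0.2% of the target
mass — negligible against every tolerance used here.

Half-harmonic walls (κ = 10 kcal mol⁻¹ Å⁻²) at the support edges keep the CV
on the target grid.  The CV is recorded at every deposition stride, so hill
centers and trajectory frames are the same time series.

### Expected bias noise

For a converged run the average-bias fluctuations obey a simple budget: with
N hills, the spurious work of a perfectly matched target is approximately
N·h₀²·e^{−2S_ρ}·E[w²]·√π·σ_G·L / (2kT), with w the residence weights below and
L the support length.  At the defaults (N = 10⁴, basin SD 2 Å) this is a few
×10⁻² kcal/mol at most — the resolution floor of the ranking currency.  This
budget, not trial and error, sets the default h₀: at 0.01 kcal/mol the floor
sits two orders of magnitude below typical state-discriminating work
differences while still accumulating several kcal/mol of shaping bias within
the filling window.

## The work functional

Let V(r,t) be the accumulated bias.  The time-averaged bias over the
production window [t_f, t_tot] is computed *exactly* from the hill record:
each hill deposited at time t contributes its Gaussian scaled by
(t_tot − max(t, t_f))/(t_tot − t_f), its residence fraction.  No snapshotting
error enters.  By default t_f = 0.2·t_tot — the filling time is excluded, the
last 80% is analyzed.

The work along the distance distribution is

  W = kT ln ∫ ρ(r) e^{(V̄(r) − ⟨V̄⟩)/kT} dr,  ⟨V̄⟩ = ∫ ρ V̄ dr.

The offset ⟨V̄⟩ makes W invariant to constant shifts of V̄, so runs of
different lengths and starting structures are comparable.  W equals kT times
the Kullback–Leibler divergence between the target and the *debiased*
distribution

  ρ_deb(r) ∝ ρ(r) · e^{V̄(r)/kT},

which estimates the unbiased ensemble of the starting model.  This identity is
algebraic, and the package treats it as such: all quadrature is the same
uniform-weight sum over the shared grid (normalization, ⟨V̄⟩, the work
integral, and KL), so the identity holds to machine precision rather than to
quadrature tolerance.  Two exactness-motivated choices follow:

* `kl_divergence` floors its second argument only at *true zeros* (with a
  warning); flooring all sub-threshold bins would perturb the identity at the
  10⁻⁵ level for targets with deep tails.
* `make_distribution` is idempotent — an already-normalized density is not
  rescaled — so file and JSON round trips are bit-exact.

### Range-restricted work

To ask how much work was spent matching the distribution *below* a threshold
r_max (default 37 Å, below typical interprotomer contributions), the bias is
flattened above r_max, V̄_r(r) = V̄(min(r, r_max)), and the reference
distribution is modified accordingly:

  ρ_mod(r) ∝ e^{(−F(r) − V̄_r(r))/kT} ∝ ρ(r) · e^{(V̄(r) − V̄_r(r))/kT},

with F(r) = −V̄(r) − kT ln ρ(r), normalized over the full grid.  The work is
then recomputed with V̄_r against ρ_mod.  Two limits pin the construction
down: r_max beyond the grid reproduces the full-range W exactly, and a bias
supported only above r_max yields zero restricted work.  F(r) is reported with
min F = 0; every downstream quantity is invariant to that constant.

### Uncertainty

The split-half SD recomputes V̄ and W separately on the two halves of the
production window and reports their dispersion.  For two values the population
convention |W₁ − W₂|/2 is used (the spread of the two numbers); the sample
convention |W₁ − W₂|/√2 is available via `type = "sample"`.

## Decomposition into molecular features

Per-frame debiasing weights w_t ∝ e^{+V̄(s_t)/kT} (normalized to mean 1,
with the Kish effective sample size attached) reweight any per-frame feature
to the unbiased ensemble.  The work attributed to a feature is
kT·D_KL(biased ‖ debiased) between its unit-weight and reweighted histograms
on shared bins (Freedman–Diaconis on the biased sample by default; 5° bins on
[−180°, 180°) for angles; a 4.5 Å cutoff for contact indicators).  The
forward KL direction is the default, with the reverse behind a flag.  The
time-averaged bias — not the final instantaneous bias — drives the weights,
consistent with the averaging window of W itself.

Two internal consistency properties hold by construction and are enforced in
the tests: the feature work of the CV itself reproduces the total W up to
binning and sampling error (within 10% on a converged run), and any
deterministic coarsening of a feature can only lower its feature work
(data-processing inequality).

## Preprocessing multi-peak distributions

Long-distance components of measured distributions that arise from labels on
*different* protomers of an oligomer are removed before targeting by
subtracting a fitted Gaussian (center ≈ 60 Å in the motivating data),
clipping negative residuals to zero and renormalizing; the subtracted
component is recorded in a sidecar JSON.  The amplitude and width are explicit
parameters — no attempt is made to infer them from the distribution itself.

## Coordination-number restraints

For completeness of the simulation-setup toolbox, the smooth contact count
C_num = Σⱼ (1 − (r_ij/R)⁸)/(1 − (r_ij/R)¹⁰) is provided with its removable
singularity at r_ij = R handled by a series expansion inside |r/R − 1| < 10⁻⁶
(analytic limit 0.8), together with the half-sided harmonic restraint
E = κ_c/2 (C − C_min)² for C < C_min (κ_c = 50 kcal/mol by default; cutoffs of
2.5 Å for sodium and 2.0 Å for quaternary-amine coordination are the
motivating values).  These operate on explicit coordinates and are not coupled
into the one-dimensional CV engine; `langevin_step` accepts an arbitrary
external force callback for such couplings.

## The synthetic scenarios

The fixture generator mirrors the motivating experimental scales without
claiming to model any particular protein:

* two states with harmonic distance basins at 27 and 42 Å (the peak positions
  of the substrate-bound and substrate-free measurements) and basin SD 2 Å
  (κ = kT/4 ≈ 0.148 kcal mol⁻¹ Å⁻²);
* targets that are Gaussian mixtures with 3 Å peak widths — the scale set by
  spin-label flexibility — either unimodal (on one basin) or bimodal (one
  peak per basin);
* the double-well system uses a barrier of 1.04 kcal/mol, the value at which
  the quartic's well curvature equals the same kT/4, so biased and unbiased
  scenarios share one basin width;
* runs of 5×10⁶ steps (10⁴ hills) with five seeds per condition.

These sizes keep a full ranking experiment (two states × five seeds × two
targets) under a minute of CPU while leaving every acceptance margin wide.
What the toys do *not* emulate: experimental noise and background in the
distance distributions, multi-spin ghost peaks, label rotamer physics, or any
coupling between the distance coordinate and slow orthogonal degrees of
freedom.  Passing tests therefore demonstrate the correctness of the method's
machinery and its statistical behavior under ideal sampling — not that a
particular protein system would converge in 1 µs.

The expected qualitative pattern reproduces the motivating study's logic:
a unimodal target centered on a state's own basin costs ~0.1 kcal/mol (the
noise floor plus the basin/target width mismatch), the same target costs a
state displaced by 15 Å roughly a hundred times more, and a bimodal target is
expensive for *every* single state (here ~2.7 kcal/mol) because no unimodal
ensemble covers both peaks — the signature of a conformational mixture.

## Numerical choices and degenerate inputs

* All exponentials are max-shifted; work and debiasing are overflow-safe for
  arbitrary bias magnitudes.
* Distributions must share bit-identical uniform grids (relative jitter
  < 10⁻⁹); resampling is linear interpolation plus renormalization.
* Hills beyond 6σ_G are truncated to exactly zero, identically in the
  on-the-fly accumulation, `bias_value` and the time-averaged bias.
* The tabulated potential differentiates by centered finite differences with
  step Δr/10 and reflects the particle at its domain edges.
* Validation failures (negative densities, non-uniform grids, out-of-order
  hills, empty windows, all-mass-removed subtractions) raise a dedicated
  condition class that the command-line interface maps to exit status 2;
  runtime failures map to 1.
* A run that spends more than 1% of its production window outside the target
  support warns; a non-finite coordinate aborts with the step index.

## Known limitations

* One-dimensional CV only; no multiple walkers, no well-tempered variant, no
  mixture-of-states targeting across replicas.
* The work of a strongly displaced state is dominated by the filling
  transient and should be read as "incompatible", not as a converged free
  energy; its convergence flag will be raised in ranking reports.
* The split-half SD on two numbers is a coarse error bar; it understates the
  seed-to-seed spread for poorly converged runs.
* The plug-in KL estimator used for convergence checks is biased upward by
  roughly (bins − 1)/(2 × effective samples); the default 0.5 Å bins keep
  this well below the 0.05-nat acceptance threshold, but very short runs
  should use coarser bins.
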