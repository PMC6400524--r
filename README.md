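# ebmetad

Rank structural models of a protein by how much *work* it takes to force each
one to reproduce a measured spin–spin distance distribution.

Pulsed EPR (DEER/PELDOR) experiments on a doubly spin-labeled protein yield
the probability distribution ρ(r) of the label–label distance — an ensemble
observable that a single crystal structure cannot be compared against
directly.  Ensemble-biased metadynamics (EBMetaD) makes the comparison
operational: a simulation started from each candidate conformation is biased,
with the minimum necessary perturbation, until its sampled distance
distribution matches ρ(r); the average biasing energy this required is the
incompatibility score.  The package is aimed at structural biologists and
simulation methodologists who want the complete analysis machinery of this
approach in a form that runs in seconds, with every component testable
against analytic results: the dynamics are Langevin sampling of the distance
coordinate over analytic toy potentials rather than all-atom MD.

## The method in brief

Hills of width σ_G = 0.5 Å are deposited on the distance coordinate every
`stride` steps with height inversely proportional to the target density,

&nbsp;&nbsp;h(s) = h₀ / (ρ(s)·e^{S_ρ}),

so at stationarity the sampled ensemble equals ρ.  From the hill record, the
bias averaged over the production window (the last 80% of the run, excluding
the filling time) gives the **work along the distance distribution**

&nbsp;&nbsp;W = kT ln ∫ ρ(r) e^{(V̄(r) − ⟨V̄⟩)/kT} dr,&nbsp;&nbsp;⟨V̄⟩ = ∫ ρ V̄ dr,

which equals kT·D_KL(ρ ‖ ρ_debiased) with ρ_debiased ∝ ρ·e^{V̄/kT}, the
estimate of the unbiased ensemble.  Lower W ⇒ the starting model is more
compatible with the data.  The package also computes range-restricted work
(bias flattened above r_max, default 37 Å, to exclude interprotomer
contributions), split-half uncertainties, per-feature work decompositions via
reweighting, Gaussian subtraction of interprotomer peaks from measured
distributions, and the smooth coordination-number restraint used to keep
ligands bound in atomistic setups.  The methods vignette
(`vignettes/ebmetad-methods.Rmd`) documents the model, every tunable
parameter, and the design decisions.

## Worked example

Two candidate states with distance basins at 27 Å ("inward-like") and 42 Å
("outward-like", both basin SD ≈ 2 Å), scored against a unimodal target
centered on the inward basin — the analog of a measurement in which only one
conformation is populated:

```r
library(ebmetad)

target  <- gaussian_mixture_distribution(gaussian_component(27, 3))
inward  <- toy_system(harmonic_potential(27, 0.148))
outward <- toy_system(harmonic_potential(42, 0.148))

run_in  <- run_ebmetad(inward,  target, ebmetad_params(t_tot = 5e6, seed = 1))
run_out <- run_ebmetad(outward, target, ebmetad_params(t_tot = 5e6, seed = 1))
analyze_run(run_in,  r_max = 37)
analyze_run(run_out, r_max = 37)
convergence_kl(run_in)
```

```
<work_result> W = 0.1272 kcal/mol (offset 6.0559, kT = 0.5922)
  split-half SD = 0.0054 kcal/mol
  restricted to r < 37.0 A
<work_result> W = 12.2177 kcal/mol (offset 6.0649, kT = 0.5922)
  split-half SD = 0.7934 kcal/mol
  restricted to r < 37.0 A
[1] 0.002
```

The matched state needs 0.13 kcal/mol of average bias — essentially the
method's noise floor plus the small width mismatch between a 2 Å basin and a
3 Å target peak — and its production histogram sits on the target
(KL ≈ 0.002 nats).  The displaced state needs ~100× more work and fails to
converge, the signature of an incompatible model.  With a bimodal target
(one peak per basin, the substrate-bound analog) *both* single states cost
~2.7 kcal/mol: no unimodal ensemble covers two peaks, indicating a mixture of
states.  `scenario_spec()` / `run_scenario()` script this whole comparison,
and `ebmetad_cli()` (launcher in `inst/scripts/ebmetad`) exposes
`gen-target`, `filter-dist`, `simulate`, `analyze`, `restrict`, `decompose`
and `scenario` subcommands.

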