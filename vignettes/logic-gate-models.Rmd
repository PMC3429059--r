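---
title: "Modeling multicellular yeast logic gates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multicellular yeast logic gates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(yeastgates)
```

This vignette explains the models implemented in `yeastgates`, the
assumptions behind them, the numerical machinery, and the design choices
that were genuinely open. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The system

Four engineered yeast cell types form a communication circuit. Three sender
types produce the mating pheromone alpha-factor in response to a chemical
input — NaCl through the HOG MAPK pathway (salt-cell), absence of
doxycycline through a Tet-Off promoter (dox-cell), galactose through the
GAL1 promoter (gal-cell) — and secrete it into the shared medium. Reporter
cells sense the pooled alpha-factor with the Ste2 receptor; the
Ste5-scaffolded MAPK cascade activates Fus3, and nuclear phospho-Fus3
drives GFP expression from the FUS1 promoter. Logic gates are obtained by
which senders are present and which chemical plays the role of a logical
input; a cell is called GFP-positive at 4.5 μM cytoplasmic mature GFP.

## Deterministic cell models

Each cell type is a mass-action ODE system over named species
(`salt_cell()`, `dox_cell()`, `gal_cell()`, `reporter_cell()`). Canonical
internal units are mmol/ml (numerically mol/L) for concentrations and
seconds for time; user-facing inputs are converted at the boundary (NaCl in
M is numerically canonical; 2% w/v galactose corresponds to 0.11 mmol/ml;
doxycycline in μg/ml is converted with a molecular weight of 444.4 g/mol,
making 1 μg/ml repress Tet-Off transcription about 23-fold with
`Ki38 = 1e7 ml/mmol`).

Structural conventions the equations are built on:

* **Compartments.** mRNA and protein species live in the cytoplasm (29 fL);
  the `*n`/`*ppn` kinase forms in the nucleus (4.06 fL); alpha-factor in
  the medium. Nucleocytoplasmic transport terms carry explicit
  `Vnuc/Vcyt` (appearing in a cytoplasmic balance) or `Vcyt/Vnuc`
  (nuclear balance) factors, which makes every shuttling pair conserve
  molecule number exactly. Transcription terms driven by a nuclear kinase
  (`k31·[Hog1ppn]`, `k34·[Fus3ppn]`) are used as calibrated, with any
  compartment bridging absorbed into the fitted constant.
* **Conservation as a constraint.** The phospho/dephospho and
  import/export assignments for Fus3 and the Ste5 complex are fixed by
  requiring that the volume-weighted totals of Fus3, Hog1, Pbs2 and Ste5
  are exact invariants of the equations; the test suite asserts a relative
  drift below 1e-6 over 6 h.
* **No sinks for the outputs.** Neither medium alpha-factor nor mature GFP
  degrades — both are monotone accumulators on the 4–6 h time scale of an
  experiment, and the tests assert that monotonicity.
* **Basal transcription is exactly zero** for the salt- and gal-cells; the
  dox-cell is constitutive and only ever repressed.

The osmostress input of the salt-cell is `max(w·[NaCl] − [Int_osmo], 0)`:
internal osmolytes accumulate under active Hog1 and feed back on both the
stress level and the osmolyte leak (the `1/(1 + Ki30·osmostress)` factor
models stress-closed Fps1 channels). This adaptation makes the salt
response transient at the signaling level while alpha-factor export
continues from the accumulated mRNA/pre-protein pools.

### The dilution law

Per-cell export flux becomes a medium concentration through a
time-decreasing dilution factor

```
dilution(t) = 13 800 · (5e6 / density) · exp(−(ln 2 / T_d) · t[h])
```

The factor halves every doubling time `T_d` (default 4 h) because the
number of secreting cells doubles. The coefficient 13 800 is the calibrated
value for the reference density of 5×10⁶ cells/ml per population; it is
about twice the naive `1/(density · Vcyt)` estimate and is kept as a
configurable coefficient rather than re-derived — only its inverse scaling
with density and the link between decay rate and doubling time are asserted
structurally.

### Pre-culture conditioning

Gates involving gal- or dox-cells start from a 16-h pre-simulation
(`precondition()`): gal-cells in 2% galactose (and therefore without the
3-h GAL induction delay during the gate run), dox-cells without
doxycycline. The media exchange at gate start removes all extracellular
alpha-factor but keeps the intracellular mRNA (~0.6–0.9 nM) and
prepro-alpha (~540–830 nM) pools, which is why unstimulated NOT/OR/IMPLIES
gates still leak GFP. Two alternatives are provided: `mode = "zero"`
(pools reset, modeling complete decay during handling) and a
`handling_delay_min` that decays the pools exponentially at their
degradation/processing rates — both exist because the pools' half-lives
(5 and 3.7 min) make gate output sensitive to handling time.

## Deterministic engine

`simulate_cell()`/`run_gate()` integrate with `deSolve::lsoda`
(stiff-capable; the receptor binding/release pair at `k2 = 3250/s` against
gene-expression rates of ~1e-3/s spans seven orders of magnitude).
Defaults: relative tolerance 1e-8, absolute 1e-12 mmol/ml, 60-s report
grid; a test asserts that tightening both tolerances tenfold moves
GFP(4 h) by less than 0.1%. The GAL induction delay is handled by
segmenting the integration at the 3-h switch rather than by letting the
solver step across a discontinuity. `steady_state()` integrates in chunks
until `max |d/dt| < 1e-15 mmol/ml/s`, excluding the pure accumulators;
it is only offered for single-cell models because the dilution factor
makes any gate assembly non-autonomous.

Gate assemblies couple one representative cell per population: sender
populations add their export fluxes to the single shared `Alpha_in_medium`
species, and reporters read it without depleting it. Receptor binding does
consume pheromone in reality, but at 13 800-fold dilution the per-cell
consumption is negligible against the pool, and the model therefore omits
it; a corollary is that reporter density does not enter the equations, so
one cell per reporter variant suffices.

## Stochastic engine

`gillespie_direct()` implements the exact direct method in molecule counts
(Rcpp): exponential waiting times from the total propensity, next reaction
proportional to its propensity, zero-propensity states frozen. Counts are
converted with Avogadro's number fixed at 6.022e23 so the shipped
initial-count table reproduces its printed integers. A uniform generator
(xoshiro256++) is seeded from R's RNG stream per call, so `set.seed()`
makes single runs and whole ensembles reproducible.

### Full reporter model with receptor QSSA

The fast receptor binding/release cycle (`k1·alpha` and `k2` both in the
1e3/s range) is eliminated with a quasi-steady-state assumption:
`ste2_qssa()` solves the receptor subsystem equilibrium at the given
alpha-factor concentration and the resulting bound-receptor count enters
the Ste5-activation propensity as a constant. A test checks the QSSA value
against a long deterministic integration.

Two choices in the stochastic parameterization deserve explanation:

* **Nuclear shuttling rates.** In molecule units the deterministic
  import/export fluxes are `k_nuc_imp · N_cyt` and `k_nuc_exp · N_nuc` —
  the compartment volume factors cancel exactly, so the per-molecule
  propensity constants equal the deterministic constants (16.8/s in,
  85.7/s out, half of that for the retained phospho-form). The shipped
  stochastic parameter table (`stochastic_parameters()`) instead lists the
  pair (21.423, 8.4) for these two reactions; that pair follows no volume
  rule and, taken literally, would move almost half of all Fus3 into the
  nucleus, roughly tripling the nuclear phospho-Fus3 pool and halving
  every downstream coefficient of variation. `reporter_stochastic_model()`
  therefore defaults to the flux-consistent rates
  (`nuclear_rates = "derived"`), which reproduce the deterministic
  nucleocytoplasmic distribution; the tabulated pair remains available as
  `nuclear_rates = "printed"` for comparison.
* **Fast-cycle rescaling.** At the literal rates the Fus3
  phosphorylation/dephosphorylation cycle (about 600 and 680 events per
  second per molecule pool) dominates the simulation: a single 4-h
  trajectory costs on the order of 1e10 SSA events while every species
  that anything downstream reads changes on time scales of minutes. The
  seven Fus3-cycle reactions form a conditionally linear subsystem —
  molecules hop independently among four states — so dividing all seven
  propensity constants by a common factor leaves the subsystem's
  stationary distribution exactly unchanged and all slow-species
  statistics unchanged to first order in the time-scale ratio.
  `fast_scale = 2000` (the default) leaves the slowest rescaled relaxation
  at ~30 s against the ~130 s Ste5 and ~470 s mRNA scales. The test suite
  compares ensembles at `fast_scale` 500 versus 2000 and asserts that
  means and coefficients of variation agree within Monte-Carlo error.
  `fast_scale = 1` recovers the literal model.

### Hybrid scheme for gates

In a gate the alpha-factor input rises continuously, so no receptor QSSA
applies and the full model would have to be re-simulated per cell.
Instead, the deterministic gate trajectory supplies the mean of nuclear
phospho-Fus3: `hybrid_drive()` converts it to molecule counts, fits an
interpolating cubic spline (a held-out-knot check estimates the
between-knot fit error, required < 1%), clamps the derivative at zero, and
`gfp_module_model()` uses that time-varying propensity as a birth-only
source for Fus3ppn feeding the stochastic GFP module (transcription, mRNA
decay, translation, maturation). Time-inhomogeneity is handled exactly by
thinning against the drive's global maximum. Fus3ppn then is an
inhomogeneous Poisson counting process — its CV must equal
`100/sqrt(mean)`, which the tests assert — and the ensemble mean of the
(linear) GFP module must track the deterministic trajectory, asserted
within three standard errors. For gates with a dead time the stochastic
clock starts when the deterministic curve first reaches one molecule
(~6 min for the IDENTITY gate at 0.4 M NaCl); report times before the
onset hold the initial counts.

Noise is quantified as `coefficient_of_variation()`: 100·sd/mean across
trajectories at a report time, defined as 0 when the mean count is 0 (an
unstimulated culture has no variation to measure). The ensemble mean is
used as the normalizer; a per-trajectory normalization would not yield one
number per time point.

## Sensitivity analysis

`sensitivity_scan()` computes scaled (relative) sensitivities
`S = d ln GFP / d ln p` of mature GFP by forward finite differences with
relative step `delta = 1e-3` (absolute floor 1e-12), re-integrating the
whole gate per perturbed quantity: every kinetic constant of the
participating cells, every non-zero initial concentration, the dilution
coefficient and the doubling time, at nine report times between 15 and
240 min. Scaled coefficients were chosen because they are unit-free and
comparable across quantities; forward differences because a single step
suffices at these smooth, well-scaled outputs — a test halves the step and
requires the top coefficients to move by less than 1%. Two analytic
anchors: GFP is exactly first-order in the transcription and translation
constants `k34`/`k35`, so their scaled sensitivities are exactly 1;
conversely parameters with no path to GFP report 0 (with a division guard
when the baseline GFP is still 0).

## Fixture generator

`generate_fixtures()` writes small deterministic reference trajectories
(sender pre-cultures, basal reporter, the IDENTITY gate) plus a
50-trajectory hybrid mini-ensemble summary, with a JSON sidecar carrying
the seed, package version and a parameter-set hash. Regeneration with the
same seed is byte-identical — the regression tests rely on that. These
fixtures emulate idealized, well-mixed, constant-temperature cultures with
perfectly synchronized media exchange; they do not emulate extrinsic
cell-to-cell parameter variability, pheromone degradation by Bar1 (the
reporters are *bar1Δ*), cell-cycle arrest under pheromone, or
carbon-source-dependent growth-rate changes. Passing tests therefore
demonstrate internal consistency of the models, not fidelity to any
particular experimental culture.

## Problem sizes

The shipped tests and the acceptance script use the sizes a desk run
affords: 100-cell ensembles for the full stochastic reporter model,
1000-cell ensembles per reporter population for the hybrid gate runs,
10⁴ samples for the birth-death distributional check, 40-cell ensembles
for the rescaling-invariance comparison. Monte-Carlo standard error on a
CV estimated from n cells is roughly `CV/sqrt(2n)` (≈7% relative at
n = 100), which sets the tolerances used in the noise assertions.

## Known limitations

* The logic verdicts near the threshold are sensitive to the 3-digit
  precision of the shipped rate constants: the deterministic IDENTITY gate
  at 0.4 M NaCl reaches 4.46 μM GFP at 4 h, a hair under the 4.5 μM
  threshold (it crosses comfortably by 5 h). Quantities tied to steady
  states or to noise statistics are insensitive to this.
* The threshold comparison is `>=`; a cell at exactly 4.5 μM counts
  positive.
* Senders are simulated deterministically even in stochastic gate runs;
  only reporter-cell noise is modeled, on the grounds that the medium pools
  the output of ~10⁶ sender cells per ml.
* `steady_state()` refuses non-autonomous systems (gate assemblies, the
  delayed gal-cell) by design.
* No tau-leaping or other approximate SSA variants; no extrinsic noise.
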