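---
title: "Tandem two-site binding kinetics: model, fitting pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem two-site binding kinetics: model, fitting pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemsite)
```

## The mechanism

Classical muscarinic antagonists such as N-methylscopolamine (NMS) and
quinuclidinyl benzilate (QNB) bind in the orthosteric pocket buried among
the transmembrane helices of the receptor. To get there, a ligand must
pass through the extracellular vestibule between the second and third
extracellular loops — and it must pass through the same vestibule again on
the way out. The tandem two-site mechanism adds one consequence: if a
second (unlabelled) ligand molecule occupies the vestibule while the
radiolabelled tracer sits in the orthosteric pocket, the tracer cannot
leave. Saturating concentrations of unlabelled ligand therefore *slow*
tracer dissociation instead of leaving it unchanged, which is the
operational signature of an allosteric interaction.

`tandemsite` implements this mechanism as a mass-action scheme over five
receptor species (free receptor; tracer at the vestibule; tracer
orthosteric; tracer orthosteric with competitor at the vestibule;
competitor at the vestibule):

```
R + L  <-> RLv      k_on_vest / k_off_vest      (vestibule binding)
RLv    <-> RLo      k_in / k_out                (translocation)
RLo + A <-> RLoA    k_on_block / k_off_block    (vestibule blockade)
R + A  <-> RAv      k_on_block / k_off_block
RLoA    -> RAv + L  leak * k_out                (imperfect blockade)
```

Two derived constants organise the behaviour. The vestibule dissociation
constant `K_A_vest = k_off_vest/k_on_vest` is weak (defaults around 1 mM),
and the translocation equilibrium `K_iso = k_out/k_in` strongly favours
the orthosteric state. The apparent orthosteric affinity is their product:

\[
K_D = K_{A,vest} \cdot \frac{K_{iso}}{1 + K_{iso}},
\]

so sub-nanomolar orthosteric binding emerges from a millimolar vestibule
site combined with a strongly inward translocation step
(`apparent_kd()`). The `leak` parameter (fraction of `k_out` that persists
with a blocked vestibule) distinguishes NMS-like complete retardation
(`leak = 0`) from QNB-like incomplete retardation (`leak > 0`), for which
the observed rate plateaus at `leak * k_0` instead of falling to zero.

In the fast-exchange regime — competitor hopping on and off the vestibule
much faster than translocation — the observed dissociation rate of
pre-bound tracer follows the retardation law used for data analysis
(the dissociation-rate method of Lazareno & Birdsall):

\[
k_{obs}(X) = \frac{k_0}{1 + (X/K_A)^{n_H}},
\]

with `k_0` the competitor-free rate, `K_A` the apparent vestibule affinity
of the unlabelled ligand for the tracer-occupied receptor, and `n_H` a
slope factor (1 for a simple one-site hyperbola). The mechanistic
simulator with a single vestibule site reproduces this law with
`n_H = 1`; steeper curves (`n_H` around 1.5, as observed for wild-type M2
and M5 receptors) are represented in the closed-form generator and
fitting layer, since their mechanistic origin is an open question the
scheme deliberately does not prejudge.

## Units, conventions and key defaults

* Time in minutes, concentrations in molar; affinities are reported as
  negative decadic logarithms (`pK = -log10 K/M`).
* ODE integration: `deSolve::lsoda`, `rtol = 1e-8`, `atol = 1e-12`.
  The state vector holds *fractional occupancies*, not molar
  concentrations: the scheme is linear in the receptor species under
  pseudo-first-order conditions, and integrating fractions keeps the
  absolute tolerance meaningful regardless of receptor concentration
  (at 0.1 nM receptor, molar states would sit below any sensible `atol`
  and the stiff integrator's error control would silently degrade).
* Pseudo-first-order: free ligand concentrations are held constant within
  a protocol phase. Membranes are dilute and the competitor is in vast
  excess (>= 10 uM against <= 1 nM tracer), so depletion is negligible.
* The bound-tracer observable counts orthosteric species only
  (`RLo`, `RLoA`): vestibule complexes are orders of magnitude weaker and
  are lost during filtration and washing. Configurable via
  `binding_protocol(observable = ...)`.
* Competitor cannot enter the orthosteric site of a tracer-occupied
  receptor; only vestibule binding is allowed on occupied receptors
  (steric exclusion).
* Receptor mass is checked for conservation at every integration output
  (tolerance 1e-7, observed errors ~1e-10 or better).

## The synthetic-data generator

`gen_saturation()` and `gen_dissociation_series()` emulate the standard
bench design: saturation with 8 log-spaced tracer concentrations
(32 pM-1 nM for NMS), 3 independent experiments in triplicate;
dissociation retardation with 7 competitor concentrations log-spaced from
10 uM to 10 mM plus a competitor-free control, 4 independent experiments
in duplicate wells, 9 time points per curve spanning three half-lives of
the expected rate at that concentration. Ground-truth parameter presets
for the wild-type subtypes and the vestibule mutants are available from
`ground_truth()`.

Noise is multiplicative Gaussian on the bound signal, truncated at zero,
because scintillation-counting error grows with the signal. The default
CV of 3% is a design choice (no assay noise magnitude is stated for the
reference experiments); it yields standard errors on recovered pK values
of roughly 0.02-0.06, comparable to published pharmacology tables.
Nonspecific binding is linear in tracer concentration and scaled so that
it contributes 10% of total binding at `X = K_D`; subtraction happens in
the fitting layer, never in the generator. One global seed expands into
per-experiment substreams, so adding experiments never reshuffles
existing ones.

What the generator does *not* emulate: filtration losses, radioactive
decay, instrument dead time, inter-membrane-batch variability, or any
correlation structure between wells. Passing recovery tests therefore
demonstrates that the pipeline inverts its own generating model at
realistic noise — not that it is robust to every systematic error of a
real assay.

```{r generator-example}
truth <- ground_truth("M2 wt")
dd <- gen_dissociation_series(truth, assay_design(rng_seed = 1))
head(dd, 3)
```

## The fitting pipeline

Per experiment, the stages mirror standard radioligand practice:

1. **Saturation** (`fit_saturation()`): specific = total - nonspecific,
   then least squares on `Y = Bmax X/(K_D + X)`. `K_D` is parameterised
   as `pK_D` internally, which makes the error surface near-quadratic
   across the picomolar-nanomolar range.
2. **Dissociation** (`fit_dissociation()`): mono-exponential
   `Y = 100 e^{-k t}` against bi-exponential
   `Y = (100-f) e^{-k_1 t} + f e^{-k_2 t}`, both with the amplitude fixed
   at 100% of initial binding. The bi-exponential is accepted only when
   the extra-sum-of-squares F-test rejects the mono fit at alpha = 0.05
   (AIC is available as an alternative). When the bi-exponential wins,
   the *slower* phase is carried forward — the faster phase at high
   competitor mostly reflects the unretarded subpopulation, and the
   retardation law concerns the blocked one.
3. **Retardation** (`fit_allosteric()`): `k_obs` versus `X` fitted with
   the hyperbolic law or the slope-factor law; `K_A` parameterised as
   `pK_A`; `k_0` floated by default (fixing it to a measured control rate
   is available via `fix_k0`, and `fix_nH = 1` reproduces the hyperbolic
   model to machine precision). `slope_model = "auto"` adopts the slope
   factor only when the F-test demands it, which in practice selects it
   for M2/M5-like steep curves and not otherwise.
4. **Group summary** (`run_pipeline()`): parameters are estimated per
   independent experiment, then summarised as mean +/- SEM *across
   experiments* (never across wells), and compared against a named
   reference condition with Dunnett's multiplicity-adjusted many-to-one
   tests (`stats::aov` + `multcomp::glht`).

Numerical safeguards: rates bounded in [1e-6, 10] per minute and pK
values in [0, 12]; log-scale rate parameterisation; up to five jittered
restarts on non-convergence (a clean first fit never touches the RNG);
flat dissociation traces flagged `no_dissociation`; flat retardation
profiles flagged with a warning (`K_A` unbounded). Least squares is
unweighted, matching the reference analysis.

```{r pipeline-example}
dd$condition <- "M2 wt"
gs <- run_pipeline(dd)
gs$summary[, c("condition", "pK_A_mean", "pK_A_sem", "k_off_mean", "nH_mean")]
```

Two points were genuinely open and resolved as follows. Whether `k_0`
should be fixed to the rate measured at the lowest competitor
concentration or floated in the fit: floated by default (the measured
control rate is itself an estimate; fixing it propagates its noise into
`K_A` unacknowledged), with `fix_k0` as the alternative. Whether the
steep curves should be fitted jointly across experiments or
per-experiment for `n_H`: per-experiment, consistent with the
means-±-SEM-across-experiments convention; a pooled fit across
experiments remains possible by passing concatenated tables to
`fit_allosteric()` directly.

## Trajectory statistics

`rmsf_profile()` computes per-residue root mean square fluctuation after
rigid-body (Kabsch) superposition of every frame onto the reference
frame (frame 1) over the chosen atom subset — backbone (N, CA, C, O) or
all heavy atoms. Residue-level RMSF is the RMS over the residue's subset
atoms of displacement from their *reference* positions (not from the
time-average), matching the fluctuation definition with an explicit
reference time. A rigidly translating or rotating structure therefore has
zero RMSF, and duplicated trajectories leave the profile unchanged.

`contact_frequency()` counts, per frame, hydrogen bonds (donor-acceptor
distance <= 3.5 A and donor-H-acceptor angle >= 120 deg by default) and
ring-stacking contacts (ring-centroid distance <= 5.5 A, interplanar
angle <= 30 deg by default) between the ligand and each residue, and
normalises by the frame count: `100 * count / n_frames`. A ligand making
two simultaneous hydrogen bonds to one residue in every frame scores 200
— values above 100 are meaningful, not errors. The geometric thresholds
of vendor analysis tools are not published; the defaults here are the
conventional ones and every threshold is exposed in
`contact_criteria()`. Ligand rings can be declared explicitly by atom
name, or detected from a distance-based bond graph when `igraph` is
available.

## The steered-escape toy

`run_escape()` is an explicitly qualitative one-dimensional analogue of
steered ligand egress, not a reimplementation of any all-atom protocol.
A Brownian particle (overdamped Euler-Maruyama, kT = 1, friction = 1)
moves on a double-well landscape: a deep orthosteric well at 0 A
(default 10 kT), a shallow vestibule well at 16 A (default 3 kT), flat
bulk beyond 28 A. Steering follows the distance-dependent schedules:
dissociation applies `min(a0/d, cap)` outward with the cap (default
4000 nm ns^-2) applied *after* the division — the published bookkeeping
(initial values up to 8000 against a cap of 4000) is internally puzzling,
and taking it as written means the cap binds only near the pocket bottom
while discrimination between `a0` values happens at vestibule distances.
Association applies `a0/(scale - d)` inward and is singular at the scale
distance (default 30 A). Steering is re-evaluated every 100 steps and
held constant in between.

The steering gain (2e-3 kT/A per nm ns^-2) and well depths were
calibrated once, by a design sweep, so that the dissociation threshold
falls inside the schedule's working range: below about a0 = 3000 the
particle stays orthosteric, at 4000 it leaves the orthosteric well but
lingers in the vestibule, and well above that it crosses into bulk —
reproducing the two-station phenomenology qualitatively. Absolute `a0`
values carry no physical correspondence to any molecular-dynamics
protocol; only their ordering is meaningful. The detailed-balance
property (zero steering, residence ratio against the Boltzmann weight)
is exercised on a closer-spaced landscape in the tests because
equilibration across the default 16 A well separation requires
impractically long runs.

## Problem sizes and runtime

All tests and the acceptance script run on synthetic data at the standard
design: recovery targets use 4 kinetic experiments (duplicates, 8 curves
of 9 time points) or 3 saturation experiments (triplicates, 8
concentrations), which fit in a second or two each. The model-selection
error-rate study uses 500 seeded replications; the escape sweep 50 seeds
at 6 acceleration values and 2e4 steps; the replication study of pK_A
recovery 100 seeded repeats. These sizes were chosen to make Monte Carlo
error comfortably smaller than the tolerances being asserted.

## Known limitations

* A single vestibule site: no multiple allosteric sites, no cooperative
  vestibule binding, hence `n_H > 1` is phenomenological in the fitting
  layer and outside the mechanistic scheme.
* Pseudo-first-order only; ligand depletion is not modelled.
* The equilibrium competition (ternary-complex) analysis of allosteric
  modulators and association-kinetics fitting are out of scope.
* Contact detection uses geometric criteria on explicit hydrogens; it
  does not infer protonation or tautomer states.
* The escape toy is one-dimensional and calibrated, not predictive.
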