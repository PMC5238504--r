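# tandemsite

Simulation and analysis of radioligand binding kinetics under the
**tandem two-site mechanism** at muscarinic acetylcholine receptors.

## The problem

High concentrations of unlabelled N-methylscopolamine (NMS) or
quinuclidinyl benzilate (QNB) *slow down* the dissociation of their own
radiolabelled species from muscarinic receptors. A purely competitive
ligand cannot do that: once the orthosteric site is occupied by tracer,
more competitor should change nothing. The observation is explained by
the tandem two-site mechanism — orthosteric ligands transit a weak
allosteric site in the extracellular vestibule on their way in *and* out,
and a second ligand molecule parked in the vestibule blocks the egress of
orthosterically bound tracer. Retardation of tracer dissociation by the
unlabelled ligand then measures the ligand's apparent vestibule affinity.

The package is for receptor pharmacologists and modellers who want to
simulate this mechanism, generate realistic synthetic assay data from it,
and run the standard multi-stage kinetic analysis on real or synthetic
experiments.

## What it computes

**Mechanistic simulator** (`rate_set()`, `simulate_binding()`): stiff
mass-action ODE integration of the five-species scheme

```
R + L <-> RLv <-> RLo;   RLo + A <-> RLoA;   R + A <-> RAv
```

with apparent orthosteric affinity `K_D = K_A_vest * K_iso/(1 + K_iso)`
(`apparent_kd()`) and simulated observed dissociation rates
(`predicted_kobs()`), which in the fast-exchange regime follow the
dissociation-retardation law of Lazareno & Birdsall:

    k_obs(X) = k_0 / (1 + (X/K_A)^nH)

**Synthetic experiments** (`ground_truth()`, `assay_design()`,
`gen_saturation()`, `gen_dissociation_series()`,
`write_fixture_suite()`): replicate-structured saturation and
dissociation-retardation data with multiplicative counting noise, from
reference parameter presets for wild-type M1-M5 receptors and
vestibule mutants.

**Fitting pipeline** (`fit_saturation()`, `fit_dissociation()`,
`fit_allosteric()`, `run_pipeline()`): one-site saturation fits
(`Y = Bmax X/(K_D + X)`), mono/bi-exponential dissociation fits with
extra-sum-of-squares F-test model selection and the slower-phase rule,
retardation fits for `pK_A` (and slope factor `nH`), and per-condition
mean ± SEM summaries with Dunnett many-to-one comparisons against a
reference condition.

**Trajectory statistics** (`rmsf_profile()`, `contact_frequency()`):
per-residue RMSF after Kabsch superposition, and per-residue
hydrogen-bond / ring-stacking contact frequencies normalised over a
trajectory (values above 100 are possible — multiple simultaneous
contacts count).

**Steered-escape toy** (`steering_schedule()`, `run_escape()`,
`escape_sweep()`): a one-dimensional Brownian-dynamics analogue of
steered ligand egress driven by capped inverse-distance acceleration
schedules, reproducing the orthosteric-pause-in-vestibule-then-bulk
two-station pattern qualitatively.

## Worked example

Generate a standard synthetic dissociation-retardation study for the
wild-type M2 receptor (4 independent experiments, duplicate wells, 7
competitor concentrations from 10 µM to 10 mM plus a competitor-free
control, 3% noise) and run the full pipeline:

```r
library(tandemsite)
truth <- ground_truth("M2 wt")      # pK_A 3.62, k_off 0.27 /min, nH 1.5
dd <- gen_dissociation_series(truth, assay_design(rng_seed = 1))
dd$condition <- "M2 wt"
run_pipeline(dd)
#> Group summary (mean +/- SEM across independent experiments):
#>  condition n pK_A_mean    pK_A_sem k_off_mean    k_off_sem  nH_mean     nH_sem
#>      M2 wt 4  3.618983 0.004436849  0.2701383 0.0007532661 1.497103 0.01072589
```

The recovered vestibule affinity (`pK_A` 3.62 ± 0.004), control
dissociation rate (0.270 ± 0.001 per minute) and slope factor (1.50 ±
0.011) match the generating parameters. A single experiment's
intermediate results are available too:

```r
an <- analyse_dissociation_experiment(dd[dd$experiment_id == 1, ],
                                      slope_model = "eq_slope")
round(an$kobs_table$k_obs, 4)
#> [1] 0.2717 0.2683 0.2590 0.2138 0.1092 0.0280 0.0057 0.0010
```

showing the observed dissociation rate falling from the control value of
about 0.27 per minute toward zero as competitor occupancy of the
vestibule approaches saturation. The methods vignette
(`vignettes/tandem-two-site-kinetics.Rmd`) documents the model,
assumptions, defaults and numerical choices in detail.

## Command line

A thin CLI over the same functions lives at `inst/cli/tandemsite.R`:

```sh
Rscript inst/cli/tandemsite.R run-pipeline --input data.csv \
    --reference "M2 wt" --seed 1 --out report --format json
Rscript inst/cli/tandemsite.R escape --a0 6000 --seed 2 --out traj.csv
```

Exit codes distinguish validation (1), fit (2) and numerical (3)
failures.
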