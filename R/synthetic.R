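#' Ground-truth binding parameters for wild-type and mutant receptors
#'
#' Reference parameter sets for NMS and QNB binding to wild-type muscarinic
#' receptor subtypes (M1-M5), to M3 receptors with ECL3 mutations, and to
#' M2 receptors with point mutations in the extracellular vestibule.  Each
#' row carries the orthosteric affinity (`pK_D`), the control dissociation
#' rate constant (`k_off`, per minute; also used as the retardation
#' baseline `k_0`), the apparent vestibule affinity (`pK_A`) and the slope
#' factor `nH` of the retardation curve (1.5 for the steep wild-type M2
#' and M5 NMS curves, 1 otherwise).  `B_max` is an arbitrary consistent
#' signal unit used by the saturation generator.
#'
#' @param condition optional condition name (e.g. `"M2 wt"`, `"M2 N419A"`,
#'   `"M3 wt"`, `"M1 wt"`); when given, the single matching NMS row is
#'   returned as a one-row data frame.
#' @param tracer `"NMS"` or `"QNB"` (QNB rows have no reliable `pK_A`).
#' @return data frame of class `ground_truth` with columns `condition`,
#'   `tracer`, `table`, `pK_D`, `k_off`, `pK_A`, `nH`, `k_0`, `B_max`.
#' @examples
#' ground_truth("M2 wt")$pK_A
#' head(ground_truth())
#' @export
ground_truth <- function(condition = NULL, tracer = "NMS") {
  nms1 <- data.frame(
    condition = c("M1 wt", "M2 wt", "M3 wt", "M4 wt", "M5 wt"),
    tracer = "NMS", table = "subtypes",
    pK_D = c(9.60, 9.43, 9.64, 9.66, 9.52),
    k_off = c(0.056, 0.27, 0.034, 0.043, 0.0162),
    pK_A = c(3.52, 3.62, 3.25, 3.31, 3.86),
    nH = c(1, 1.5, 1, 1, 1.5))
  qnb1 <- data.frame(
    condition = c("M1 wt", "M2 wt", "M3 wt", "M4 wt", "M5 wt"),
    tracer = "QNB", table = "subtypes",
    pK_D = c(9.82, 9.80, 9.87, 9.83, 9.85),
    k_off = c(1.71e-3, 3.0e-3, 1.21e-3, 1.58e-3, 1.40e-3),
    pK_A = NA_real_, nH = 1)
  m3 <- data.frame(
    condition = c("M3 wt", "M3 S->P", "M3 K->N", "M3 KFN->NVT",
                  "M3 DKFN->ANVT", "M3 SK->PN", "M3 SKFN->PNVT",
                  "M3 DSKFN->APNVT", "M2 wt"),
    tracer = "NMS", table = "M3_ECL3",
    pK_D = c(9.64, 9.65, 9.63, 9.55, 9.56, 9.63, 9.48, 9.45, 9.43),
    k_off = c(0.034, 0.057, 0.097, 0.26, 0.21, 0.12, 0.25, 0.26, 0.27),
    pK_A = c(3.25, 3.25, 3.52, 3.65, 3.64, 3.55, 3.65, 3.66, 3.62),
    nH = c(1, 1, 1, 1, 1, 1, 1, 1, 1.5))
  m2 <- data.frame(
    condition = c("M2 wt", "M2 D97N", "M2 D97A", "M2 E172A", "M2 E175A",
                  "M2 Y177A", "M2 N419A"),
    tracer = "NMS", table = "M2_vestibule",
    pK_D = c(9.43, 9.03, 9.04, 9.21, 9.19, 9.44, 8.95),
    k_off = c(0.27, 0.42, 0.41, 0.45, 0.44, 0.27, 0.78),
    pK_A = c(3.62, 3.24, 3.23, 3.39, 3.40, 3.63, 3.11),
    nH = c(1.5, 1, 1, 1, 1, 1, 1))
  tab <- rbind(nms1, qnb1, m3, m2)
  tab$k_0 <- tab$k_off
  tab$B_max <- 1000
  class(tab) <- c("ground_truth", class(tab))
  if (is.null(condition)) return(tab)
  hit <- tab[tab$condition == condition & tab$tracer == tracer, , drop = FALSE]
  if (!nrow(hit)) stop_param("unknown condition: ", condition)
  hit[1, , drop = FALSE]
}

#' Synthetic assay design
#'
#' Describes the replicate structure, concentration grids and noise level
#' of a synthetic radioligand experiment.  The defaults mirror the bench
#' design analysed by the fitting pipeline: 4 independent kinetic
#' experiments in duplicate wells (saturation: 3 experiments in
#' triplicate), 8 log-spaced tracer concentrations from 32 pM to 1 nM, 7
#' competitor concentrations log-spaced from 10 uM to 10 mM plus a
#' competitor-free control curve, 9 time points per dissociation curve
#' spanning three half-lives of the expected rate at that concentration,
#' and 3% multiplicative noise on the bound signal.
#'
#' @param n_experiments number of independent experiments.
#' @param n_wells replicate wells per point (2 for kinetics, 3 for
#'   saturation in the standard design).
#' @param tracer_concs molar tracer concentrations for saturation curves.
#' @param competitor_concs molar competitor concentrations for
#'   dissociation retardation.
#' @param include_control add a competitor-free (X = 0) dissociation curve
#'   measuring the control rate `k_0`.
#' @param n_time_points time points per dissociation curve (includes t = 0).
#' @param n_halflives time span of each dissociation curve, in half-lives
#'   of the expected observed rate at that competitor concentration.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   noise on bound signal (truncated at zero).
#' @param nonspecific_fraction fraction of total binding that is
#'   nonspecific at the tracer's K_D; nonspecific binding is linear in
#'   tracer concentration.
#' @param rng_seed integer seed; expanded into per-experiment substreams.
#' @return an object of class `assay_design`.
#' @export
assay_design <- function(n_experiments = 4, n_wells = 2,
                         tracer_concs = 10^seq(log10(32e-12), log10(1e-9),
                                               length.out = 8),
                         competitor_concs = 10^seq(-5, -2, length.out = 7),
                         include_control = TRUE,
                         n_time_points = 9, n_halflives = 3,
                         noise_cv = 0.03, nonspecific_fraction = 0.1,
                         rng_seed = 1L) {
  if (n_experiments < 1) stop_param("n_experiments must be >= 1")
  if (n_wells < 1) stop_param("n_wells must be >= 1")
  if (noise_cv < 0) stop_param("noise_cv must be >= 0")
  if (!length(tracer_concs)) stop_param("tracer_concs must be non-empty")
  if (any(tracer_concs <= 0) || any(competitor_concs <= 0))
    stop_param("all concentrations must be positive")
  if (nonspecific_fraction < 0 || nonspecific_fraction >= 1)
    stop_param("nonspecific_fraction must lie in [0, 1)")
  structure(list(
    n_experiments = as.integer(n_experiments), n_wells = as.integer(n_wells),
    tracer_concs = tracer_concs, competitor_concs = competitor_concs,
    include_control = include_control,
    n_time_points = as.integer(n_time_points), n_halflives = n_halflives,
    noise_cv = noise_cv, nonspecific_fraction = nonspecific_fraction,
    rng_seed = as.integer(rng_seed)), class = "assay_design")
}

#' @rdname assay_design
#' @param ... overrides passed on to [assay_design()].
#' @export
saturation_design <- function(n_experiments = 3, n_wells = 3, ...) {
  assay_design(n_experiments = n_experiments, n_wells = n_wells, ...)
}

#' Generate a synthetic saturation binding experiment
#'
#' Simulates total and nonspecific binding wells for each tracer
#' concentration of the design.  Specific binding follows the one-site
#' isotherm `B_max X / (K_D + X)` in expectation; nonspecific binding is
#' linear in tracer concentration and scaled so that at `X = K_D` it makes
#' up `nonspecific_fraction` of total binding; both carry multiplicative
#' Gaussian noise at `noise_cv`.
#'
#' @param truth a one-row [ground_truth()] data frame (or any list with
#'   `pK_D` and `B_max`).
#' @param design an [assay_design()]; for the standard bench layout use
#'   [saturation_design()].
#' @return data frame of class `saturation_curve` with columns
#'   `experiment_id`, `well`, `conc_tracer_M`, `total`, `nonspecific`.
#' @export
gen_saturation <- function(truth, design = saturation_design()) {
  if (!length(design$tracer_concs)) stop_param("empty tracer concentration list")
  KD <- from_pK(truth$pK_D)
  Bmax <- truth$B_max
  nf <- design$nonspecific_fraction
  ns_slope <- if (nf > 0) (nf / (1 - nf)) * (Bmax / 2) / KD else 0
  rows <- list()
  for (e in seq_len(design$n_experiments)) {
    set.seed(substream_seed(design$rng_seed, e))
    for (X in design$tracer_concs) {
      spec0 <- Bmax * X / (KD + X)
      ns0 <- ns_slope * X
      for (w in seq_len(design$n_wells)) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = e, well = w, conc_tracer_M = X,
          total = apply_cv_noise(spec0 + ns0, design$noise_cv),
          nonspecific = apply_cv_noise(ns0, design$noise_cv))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_curve", class(out))
  attr(out, "truth") <- truth
  out
}

# expected observed dissociation rate under the retardation law
kobs_closed_form <- function(k_0, K_A, nH, X) {
  ifelse(X <= 0, k_0, k_0 / (1 + (X / K_A)^nH))
}

# per-curve sampling grid: n points from 0 over n_halflives of rate k
dissociation_time_grid <- function(k, n_points, n_halflives) {
  seq(0, n_halflives * log(2) / k, length.out = n_points)
}

#' Generate a synthetic dissociation retardation experiment series
#'
#' For each independent experiment and each competitor concentration X
#' (plus a competitor-free control when `design$include_control` is TRUE),
#' generates a dissociation time course normalised to 100% at the start of
#' dissociation in expectation.
#'
#' In `closed_form` mode the decay is `Y(t) = 100 exp(-k_obs(X) t)` with
#' `k_obs(X) = k_0 / (1 + (X/K_A)^nH)` taken from the ground truth.  In
#' `mechanistic` mode the time course is produced by the mass-action
#' simulator of the tandem two-site scheme ([simulate_binding()]) from a
#' supplied [rate_set()].  Either way, multiplicative Gaussian noise at
#' `design$noise_cv` is applied per well.
#'
#' @param truth a one-row [ground_truth()] (needs `k_0`, `pK_A`, `nH` in
#'   closed-form mode).
#' @param design an [assay_design()].
#' @param mode `"closed_form"` or `"mechanistic"`.
#' @param scheme a [rate_set()], required in mechanistic mode.
#' @param tracer tracer concentration used for pre-equilibration in
#'   mechanistic mode (molar).
#' @param receptor_total receptor concentration in mechanistic mode (molar).
#' @return data frame of class `dissociation_series` with columns
#'   `experiment_id`, `well`, `time_min`, `conc_tracer_M`,
#'   `conc_competitor_M`, `bound_pct`.
#' @examples
#' tc <- gen_dissociation_series(ground_truth("M2 wt"),
#'                               assay_design(noise_cv = 0, rng_seed = 7))
#' head(tc)
#' @export
gen_dissociation_series <- function(truth, design = assay_design(),
                                    mode = c("closed_form", "mechanistic"),
                                    scheme = NULL, tracer = 1e-9,
                                    receptor_total = 1e-10) {
  mode <- match.arg(mode)
  if (mode == "mechanistic" && is.null(scheme))
    stop_validation("mechanistic mode requires a rate_set scheme")
  Xs <- design$competitor_concs
  if (design$include_control) Xs <- c(0, Xs)
  KA <- from_pK(truth$pK_A)

  expected_curve <- function(X, times) {
    if (mode == "closed_form") {
      100 * exp(-kobs_closed_form(truth$k_0, KA, truth$nH, X) * times)
    } else {
      pr <- dissociation_protocol(tracer = tracer, competitor = X,
                                  sample_times = times)
      tc <- simulate_binding(scheme, pr, receptor_total)
      100 * tc$bound_pct[match(times, tc$time_min)] /
        tc$bound_pct[tc$time_min == 0][1]
    }
  }

  rows <- list()
  for (e in seq_len(design$n_experiments)) {
    set.seed(substream_seed(design$rng_seed, e))
    for (X in Xs) {
      k_exp <- if (mode == "closed_form") {
        kobs_closed_form(truth$k_0, KA, truth$nH, X)
      } else {
        k0g <- scheme$k_out * scheme$k_off_vest /
          (scheme$k_off_vest + scheme$k_in)
        KAg <- scheme$k_off_block / scheme$k_on_block
        kobs_closed_form(k0g, KAg, 1, X) + scheme$leak * k0g * X / (X + KAg)
      }
      times <- dissociation_time_grid(max(k_exp, 1e-9),
                                      design$n_time_points,
                                      design$n_halflives)
      y0 <- expected_curve(X, times)
      for (w in seq_len(design$n_wells)) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = e, well = w, time_min = times,
          conc_tracer_M = tracer, conc_competitor_M = X,
          bound_pct = apply_cv_noise(y0, design$noise_cv))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dissociation_series", class(out))
  attr(out, "truth") <- truth
  out
}

#' Write a suite of synthetic fixture files for every ground-truth row
#'
#' For each row of the ground-truth tables with a defined vestibule
#' affinity, writes one saturation CSV and one dissociation CSV generated
#' with a per-row seed derived from `seed`, plus a YAML manifest mapping
#' each fixture file to its ground-truth parameters and seed.
#' Regeneration with the same seed is byte-identical.
#'
#' @param output_dir writable directory (created if absent).
#' @param seed integer master seed.
#' @param design kinetic [assay_design()] template (the per-row seed is
#'   substituted); the saturation design is derived from it with 3
#'   experiments in triplicate.
#' @return invisibly, the manifest as a list.
#' @export
write_fixture_suite <- function(output_dir, seed = 20170116,
                                design = assay_design()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, 2) != 0)
    stop_validation("output directory is not writable: ", output_dir)
  tab <- ground_truth()
  tab <- tab[is.finite(tab$pK_A), , drop = FALSE]
  manifest <- list()
  for (i in seq_len(nrow(tab))) {
    truth <- tab[i, , drop = FALSE]
    slug <- gsub("[^A-Za-z0-9]+", "_", paste(truth$table, truth$condition))
    row_seed <- substream_seed(seed, i)
    kin_design <- design; kin_design$rng_seed <- row_seed
    sat_design <- saturation_design(
      tracer_concs = design$tracer_concs,
      noise_cv = design$noise_cv,
      nonspecific_fraction = design$nonspecific_fraction,
      rng_seed = substream_seed(seed, i + 1000L))
    sat_file <- file.path(output_dir, paste0(slug, "_saturation.csv"))
    dis_file <- file.path(output_dir, paste0(slug, "_dissociation.csv"))
    utils::write.csv(gen_saturation(truth, sat_design), sat_file,
                     row.names = FALSE)
    utils::write.csv(gen_dissociation_series(truth, kin_design), dis_file,
                     row.names = FALSE)
    manifest[[slug]] <- list(
      condition = truth$condition, tracer = truth$tracer,
      table = truth$table,
      truth = list(pK_D = truth$pK_D, k_off = truth$k_off,
                   pK_A = truth$pK_A, nH = truth$nH, k_0 = truth$k_0,
                   B_max = truth$B_max),
      seed_kinetic = row_seed, seed_saturation = sat_design$rng_seed,
      files = list(saturation = basename(sat_file),
                   dissociation = basename(dis_file)))
  }
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(manifest)
}
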