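test_that("ground-truth tables carry the reference parameter sets", {
  tab <- ground_truth()
  expect_true(all(c("pK_D", "k_off", "pK_A", "nH", "k_0") %in% names(tab)))
  m3 <- ground_truth("M3 wt")
  expect_equal(m3$pK_A, 3.25)
  expect_equal(m3$k_off, 0.034)
  expect_equal(ground_truth("M2 wt")$nH, 1.5)
  expect_error(ground_truth("M9 wt"), class = "tandemsite_parameter_error")
})

test_that("noise-free saturation generation reproduces the isotherm exactly", {
  truth <- ground_truth("M2 wt")
  des <- saturation_design(noise_cv = 0, rng_seed = 1)
  cur <- gen_saturation(truth, des)
  KD <- from_pK(truth$pK_D)
  spec <- cur$total - cur$nonspecific
  expect_equal(spec,
               truth$B_max * cur$conc_tracer_M / (KD + cur$conc_tracer_M),
               tolerance = 1e-12)
  # half-saturation at X = K_D
  at_kd <- gen_saturation(truth, saturation_design(
    noise_cv = 0, tracer_concs = c(KD, KD / 3, 3 * KD, 10 * KD),
    rng_seed = 1))
  spec_kd <- with(at_kd[at_kd$conc_tracer_M == KD, ], total - nonspecific)
  expect_equal(spec_kd, rep(truth$B_max / 2, length(spec_kd)),
               tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  truth <- ground_truth("M2 wt")
  d <- assay_design(rng_seed = 99)
  expect_identical(gen_dissociation_series(truth, d),
                   gen_dissociation_series(truth, d))
  expect_identical(gen_saturation(truth, saturation_design(rng_seed = 5)),
                   gen_saturation(truth, saturation_design(rng_seed = 5)))
  # different experiments get different substreams
  dd <- gen_dissociation_series(truth, d)
  e1 <- dd$bound_pct[dd$experiment_id == 1]
  e2 <- dd$bound_pct[dd$experiment_id == 2]
  expect_false(identical(e1, e2))
})

test_that("closed-form dissociation generator evaluates the retardation law", {
  truth <- ground_truth("M2 wt")   # k_0 = 0.27, pK_A = 3.62, nH = 1.5
  des <- assay_design(n_experiments = 1, noise_cv = 0, rng_seed = 1)
  dd <- gen_dissociation_series(truth, des)
  # control curve decays at k_0: Y(t) = 100 exp(-0.27 t)
  ctrl <- dd[dd$conc_competitor_M == 0 & dd$well == 1, ]
  expect_equal(ctrl$bound_pct, 100 * exp(-0.27 * ctrl$time_min),
               tolerance = 1e-12)
  # at X = 10 mM the observed rate is ~1.0e-3 /min
  top <- dd[dd$conc_competitor_M == 1e-2 & dd$well == 1, ]
  fit <- fit_dissociation(top)
  k_expected <- 0.27 / (1 + (1e-2 / 10^-3.62)^1.5)
  expect_equal(fit$selected_rate, k_expected, tolerance = 1e-6)
  expect_lt(abs(k_expected / 1.0e-3 - 1), 0.05)
})

test_that("slope factor of 1 reduces the generator to the hyperbolic law", {
  truth <- ground_truth("M3 wt")
  expect_equal(truth$nH, 1)
  des <- assay_design(n_experiments = 1, noise_cv = 0, rng_seed = 1)
  dd <- gen_dissociation_series(truth, des)
  KA <- from_pK(truth$pK_A)
  for (X in unique(dd$conc_competitor_M[dd$conc_competitor_M > 0])) {
    sub <- dd[dd$conc_competitor_M == X & dd$well == 1, ]
    expect_equal(sub$bound_pct,
                 100 * exp(-truth$k_0 / (1 + X / KA) * sub$time_min),
                 tolerance = 1e-12)
  }
})

test_that("replicate-well noise converges to the design CV", {
  truth <- ground_truth("M2 wt")
  des <- saturation_design(n_experiments = 1, n_wells = 1000,
                           tracer_concs = from_pK(truth$pK_D) * c(1, 3, 9, 27),
                           noise_cv = 0.03, rng_seed = 42)
  cur <- gen_saturation(truth, des)
  cv <- sapply(unique(cur$conc_tracer_M), function(X) {
    y <- cur$total[cur$conc_tracer_M == X]
    sd(y) / mean(y)
  })
  expect_true(all(abs(cv / 0.03 - 1) < 0.2))
})

test_that("noise-free generation followed by fitting recovers ground truth", {
  truth <- ground_truth("M2 N419A")
  des <- assay_design(n_experiments = 1, noise_cv = 0, rng_seed = 1)
  an <- analyse_dissociation_experiment(gen_dissociation_series(truth, des),
                                        slope_model = "eq_hyperbolic")
  expect_lt(abs(an$allosteric$pK_A - truth$pK_A) / truth$pK_A, 1e-6)
  expect_lt(abs(an$k_off_control - truth$k_off) / truth$k_off, 1e-6)
  sat <- gen_saturation(truth, saturation_design(n_experiments = 1,
                                                 noise_cv = 0, rng_seed = 1))
  sfit <- fit_saturation(sat)
  expect_lt(abs(sfit$pK_D - truth$pK_D) / truth$pK_D, 1e-6)
  expect_lt(abs(sfit$B_max - truth$B_max) / truth$B_max, 1e-6)
})

test_that("mechanistic and closed-form modes agree in fast exchange", {
  truth <- ground_truth("M3 wt")
  rs <- rate_set_from_truth(truth)
  des <- assay_design(n_experiments = 1, noise_cv = 0, rng_seed = 3)
  am <- analyse_dissociation_experiment(
    gen_dissociation_series(truth, des, mode = "mechanistic", scheme = rs),
    slope_model = "eq_hyperbolic")
  ac <- analyse_dissociation_experiment(
    gen_dissociation_series(truth, des, mode = "closed_form"),
    slope_model = "eq_hyperbolic")
  expect_true(all(abs(am$kobs_table$k_obs / ac$kobs_table$k_obs - 1) < 0.03))
  expect_error(gen_dissociation_series(truth, des, mode = "mechanistic"),
               class = "tandemsite_validation_error")
})

test_that("fixture suite covers every table row and is reproducible", {
  dir1 <- withr::local_tempdir()
  man <- write_fixture_suite(dir1, seed = 7,
                             design = assay_design(n_experiments = 2,
                                                   n_time_points = 5))
  tab <- ground_truth()
  expect_length(man, sum(is.finite(tab$pK_A)))
  m3 <- man[["M3_ECL3_M3_wt"]]
  expect_equal(m3$truth$pK_A, 3.25)
  expect_true(file.exists(file.path(dir1, m3$files$dissociation)))
  expect_true(file.exists(file.path(dir1, "manifest.yaml")))
  # byte-identical regeneration
  dir2 <- withr::local_tempdir()
  write_fixture_suite(dir2, seed = 7,
                      design = assay_design(n_experiments = 2,
                                            n_time_points = 5))
  f <- m3$files$dissociation
  expect_identical(readLines(file.path(dir1, f)),
                   readLines(file.path(dir2, f)))
})
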