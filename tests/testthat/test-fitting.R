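test_that("saturation fit recovers noise-free parameters exactly", {
  truth <- ground_truth("M2 wt")
  cur <- gen_saturation(truth, saturation_design(n_experiments = 1,
                                                 noise_cv = 0, rng_seed = 1))
  fit <- fit_saturation(cur)
  expect_equal(fit$pK_D, 9.43, tolerance = 1e-6)
  expect_equal(fit$B_max, truth$B_max, tolerance = 1e-6)
  # scale equivariance: doubling the signal doubles B_max, K_D unchanged
  cur2 <- cur
  cur2$total <- 2 * cur2$total
  cur2$nonspecific <- 2 * cur2$nonspecific
  fit2 <- fit_saturation(cur2)
  expect_equal(fit2$pK_D, fit$pK_D, tolerance = 1e-8)
  expect_equal(fit2$B_max, 2 * fit$B_max, tolerance = 1e-6)
})

test_that("saturation fit flags unidentifiable K_D via SE blowup", {
  truth <- ground_truth("M2 wt")
  KD <- from_pK(truth$pK_D)
  # every concentration far above K_D: top plateau only
  des <- saturation_design(n_experiments = 1,
                           tracer_concs = KD * c(200, 400, 800, 1600, 3200),
                           noise_cv = 0.03, rng_seed = 3)
  fit <- fit_saturation(gen_saturation(truth, des))
  des_ok <- saturation_design(n_experiments = 1, noise_cv = 0.03,
                              rng_seed = 3)
  fit_ok <- fit_saturation(gen_saturation(truth, des_ok))
  expect_true(is.na(fit$se[["pK_D"]]) ||
                fit$se[["pK_D"]] > 20 * fit_ok$se[["pK_D"]])
})

test_that("saturation fit rejects degenerate inputs", {
  expect_error(fit_saturation(data.frame(conc_tracer_M = 1:8)),
               class = "tandemsite_validation_error")
  expect_error(
    fit_saturation(data.frame(conc_tracer_M = c(1, 2, 3) * 1e-10,
                              specific = c(1, 2, 3))),
    class = "tandemsite_validation_error")  # < 4 concentrations
  expect_error(
    fit_saturation(data.frame(conc_tracer_M = c(1, 2, 3, 4) * 1e-10,
                              specific = rep(0, 4))),
    class = "tandemsite_fit_error")
})

test_that("mono-exponential data yield a mono fit at the true rate", {
  fit <- fit_dissociation(mono_tc(0.27))
  expect_identical(fit$model, "mono")
  expect_equal(fit$selected_rate, 0.27, tolerance = 1e-6)
  expect_false(fit$no_dissociation)
})

test_that("bi-exponential data select bi and report the slower phase", {
  t <- seq(0, 60, length.out = 13)
  y <- 50 * exp(-0.5 * t) + 50 * exp(-0.05 * t)
  fit <- fit_dissociation(data.frame(time_min = t, bound_pct = y))
  expect_identical(fit$model, "bi")
  expect_equal(fit$f, 50, tolerance = 1e-3)
  expect_equal(fit$selected_rate, 0.05, tolerance = 1e-4)
  # slower-phase rule: selected rate never exceeds either component
  expect_lte(fit$selected_rate, fit$k_off)
  expect_lte(fit$selected_rate, fit$k_off2)
})

test_that("flat time courses are flagged as no-dissociation", {
  t <- seq(0, 10, length.out = 9)
  fit <- fit_dissociation(data.frame(time_min = t, bound_pct = rep(100, 9)))
  expect_true(fit$no_dissociation)
  expect_lt(fit$selected_rate, 1e-5)
})

test_that("the slower-phase rule holds across noisy seeded fits", {
  for (seed in 1:25) {
    set.seed(seed)
    t <- rep(seq(0, 30, length.out = 9), 2)
    y <- pmax(0, (40 * exp(-0.4 * t) + 60 * exp(-0.06 * t)) *
                (1 + rnorm(length(t), 0, 0.03)))
    fit <- fit_dissociation(data.frame(time_min = t, bound_pct = y))
    if (fit$model == "bi") {
      expect_lte(fit$selected_rate, fit$k_off + 1e-12)
      expect_lte(fit$selected_rate, fit$k_off2 + 1e-12)
    } else {
      expect_identical(fit$selected_rate, fit$k_off)
    }
  }
})

test_that("allosteric fit recovers noise-free pK_A exactly", {
  X <- 10^seq(-5, -2, length.out = 7)
  tab <- data.frame(conc_competitor_M = X,
                    k_obs = 0.034 / (1 + X / 10^-3.25))
  fit <- fit_allosteric(tab, "eq_hyperbolic")
  expect_equal(fit$pK_A, 3.25, tolerance = 1e-6)
  expect_equal(fit$k_0, 0.034, tolerance = 1e-6)
  # at X = K_A the law gives k_0/2
  expect_equal(0.034 / (1 + 10^-3.25 / 10^-3.25), 0.034 / 2)
})

test_that("steep retardation needs the slope factor and recovers nH", {
  X <- 10^seq(-5, -2, length.out = 7)
  k <- 0.27 / (1 + (X / 10^-3.62)^1.5)
  tab <- data.frame(conc_competitor_M = X, k_obs = k)
  f5 <- fit_allosteric(tab, "eq_slope")
  expect_equal(f5$nH, 1.5, tolerance = 1e-4)
  expect_equal(f5$pK_A, 3.62, tolerance = 1e-4)
  # the hyperbolic fit leaves structured residuals on steep data
  f4 <- fit_allosteric(tab, "eq_hyperbolic")
  expect_gt(f4$rss, 10 * f5$rss)
})

test_that("slope model with nH fixed at 1 equals the hyperbolic model", {
  X <- 10^seq(-5, -2, length.out = 7)
  set.seed(8)
  tab <- data.frame(conc_competitor_M = X,
                    k_obs = 0.27 / (1 + X / 10^-3.62) *
                      (1 + rnorm(7, 0, 0.03)))
  f4 <- fit_allosteric(tab, "eq_hyperbolic")
  f5 <- fit_allosteric(tab, "eq_slope", fix_nH = 1)
  expect_lt(abs(f5$pK_A - f4$pK_A), 1e-8)
  expect_lt(abs(f5$k_0 - f4$k_0), 1e-8)
})

test_that("allosteric fit validates input and warns on flat profiles", {
  expect_error(fit_allosteric(data.frame(conc_competitor_M = 1:3,
                                         k_obs = c(1, 2, 3))),
               class = "tandemsite_validation_error")
  X <- c(1e-5, 1e-4, 1e-3, 1e-2)
  expect_error(
    fit_allosteric(data.frame(conc_competitor_M = X,
                              k_obs = c(0.2, 0.1, -0.1, 0.05))),
    class = "tandemsite_validation_error")
  expect_warning(
    fit_allosteric(data.frame(conc_competitor_M = X,
                              k_obs = rep(0.27, 4))),
    "unbounded")
})

test_that("mono/bi model selection keeps type-I error near alpha", {
  n_bi <- 0
  for (i in 1:500) {
    set.seed(i)
    t <- rep(seq(0, 3 * log(2) / 0.27, length.out = 9), 2)
    y <- pmax(0, 100 * exp(-0.27 * t) * (1 + rnorm(length(t), 0, 0.03)))
    fit <- fit_dissociation(data.frame(time_min = t, bound_pct = y))
    if (fit$model == "bi") n_bi <- n_bi + 1
  }
  expect_lte(n_bi / 500, 0.07)
})
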