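#' Fit a one-site saturation binding isotherm
#'
#' Fits the hyperbolic saturation law
#' \deqn{Y = B_{max} X / (K_D + X)}
#' to specific binding, where X is the free tracer concentration and Y the
#' specifically bound tracer.  Nonspecific binding (measured in the
#' presence of excess atropine) is subtracted first: specific = total -
#' nonspecific.  `K_D` is parameterised as `pK_D = -log10(K_D)` internally,
#' which linearises the error surface across the picomolar-nanomolar range.
#'
#' @param curve a data frame with columns `conc_tracer_M`, `total` and
#'   `nonspecific` (a `saturation_curve` as produced by
#'   [gen_saturation()]), or columns `conc_tracer_M` and `specific`.
#' @return an object of class `saturation_fit`: a list with elements
#'   `K_D` (molar), `pK_D`, `B_max`, `se` (named standard errors on the
#'   `pK_D` and `B_max` scales), `rss`, `df` and the `fit` object.
#' @examples
#' truth <- ground_truth("M2 wt")
#' cur <- gen_saturation(truth, assay_design(noise_cv = 0, rng_seed = 1))
#' fit_saturation(cur)$pK_D
#' @export
fit_saturation <- function(curve) {
  if (!is.data.frame(curve)) stop_validation("curve must be a data frame")
  if (!"conc_tracer_M" %in% names(curve))
    stop_validation("curve must have a conc_tracer_M column")
  if ("specific" %in% names(curve)) {
    y <- curve$specific
  } else if (all(c("total", "nonspecific") %in% names(curve))) {
    y <- curve$total - curve$nonspecific
  } else {
    stop_validation("curve needs either a specific column or total + nonspecific")
  }
  x <- curve$conc_tracer_M
  if (length(unique(x)) < 4)
    stop_validation("need at least 4 distinct tracer concentrations")
  if (all(y <= 0)) stop_fit("degenerate data: no specific binding")

  dat <- data.frame(x = x, y = y)
  start <- list(pK = -log10(stats::median(x)), Bmax = max(y) * 1.2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Bmax * x / (10^(-pK) + x), data = dat,
                      start = start,
                      lower = c(pK = 0, Bmax = 1e-12),
                      upper = c(pK = 15, Bmax = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_fit("saturation fit failed: ",
                                 conditionMessage(e)))
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(pK = NA_real_, Bmax = NA_real_))
  structure(list(
    K_D = 10^(-co[["pK"]]), pK_D = co[["pK"]], B_max = co[["Bmax"]],
    se = c(pK_D = unname(se["pK"]), B_max = unname(se["Bmax"])),
    rss = sum(stats::resid(fit)^2), df = stats::df.residual(fit),
    fit = fit), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit: pK_D = %.3f (SE %.3g), B_max = %.4g (SE %.3g), RSS = %.4g\n",
              x$pK_D, x$se[["pK_D"]], x$B_max, x$se[["B_max"]], x$rss))
  invisible(x)
}
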