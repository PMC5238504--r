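#' Per-experiment dissociation analysis: exponential fits then K_A fit
#'
#' Runs the two-stage dissociation analysis on one experiment: fits each
#' competitor concentration's time course with mono/bi-exponential decay
#' (selecting the model by F-test and carrying the slower phase forward),
#' assembles the table of observed rates versus competitor concentration,
#' and fits the allosteric retardation law for `pK_A` (and `nH` under
#' `"eq_slope"`).  The competitor-free control curve, when present,
#' supplies the measured `k_off` but is excluded from the retardation fit
#' (the law is defined for X > 0).
#'
#' @param series a `dissociation_series` data frame (one experiment).
#' @param slope_model passed to [fit_allosteric()]; `"auto"` first fits the
#'   simple hyperbola and switches to the slope-factor form when the
#'   extra-sum-of-squares F-test prefers it at `alpha`.
#' @param alpha significance level for model selection (both the
#'   mono/bi-exponential F-test and the `"auto"` slope-model choice).
#' @param fix_k0 passed to [fit_allosteric()].
#' @return list with `kobs_table` (columns `conc_competitor_M`, `k_obs`,
#'   `model`), `allosteric` (an `allosteric_fit`), `k_off_control`
#'   (per minute, NA when no control curve), `dissociation_fits`.
#' @export
analyse_dissociation_experiment <- function(series,
                                            slope_model = c("auto",
                                                            "eq_hyperbolic",
                                                            "eq_slope"),
                                            alpha = 0.05, fix_k0 = NULL) {
  slope_model <- match.arg(slope_model)
  series <- normalize_dissociation(series)
  Xs <- sort(unique(series$conc_competitor_M))
  fits <- lapply(Xs, function(X) {
    fit_dissociation(series[series$conc_competitor_M == X, , drop = FALSE],
                     alpha = alpha)
  })
  names(fits) <- format(Xs, digits = 8)
  kobs <- data.frame(
    conc_competitor_M = Xs,
    k_obs = vapply(fits, function(f) f$selected_rate, numeric(1)),
    model = vapply(fits, function(f) f$model, character(1)))
  k_off_control <- if (any(Xs == 0)) kobs$k_obs[Xs == 0] else NA_real_
  ktab <- kobs[kobs$conc_competitor_M > 0, , drop = FALSE]

  if (slope_model == "auto") {
    f4 <- fit_allosteric(ktab, "eq_hyperbolic", fix_k0 = fix_k0)
    f5 <- tryCatch(fit_allosteric(ktab, "eq_slope", fix_k0 = fix_k0),
                   error = function(e) NULL)
    allo <- f4
    if (!is.null(f5) && f5$df > 0 && f5$rss < f4$rss) {
      Fstat <- ((f4$rss - f5$rss) / (f4$df - f5$df)) / (f5$rss / f5$df)
      p <- stats::pf(Fstat, f4$df - f5$df, f5$df, lower.tail = FALSE)
      if (is.finite(p) && p < alpha) allo <- f5
    }
  } else {
    allo <- fit_allosteric(ktab, slope_model, fix_k0 = fix_k0)
  }
  list(kobs_table = kobs, allosteric = allo,
       k_off_control = k_off_control, dissociation_fits = fits)
}

# Accepts either ready percent-normalised data (bound_pct) or raw counts
# (bound, optionally nonspecific): subtract nonspecific, then normalise to
# the mean signal at the start of dissociation.
normalize_dissociation <- function(series) {
  if ("bound_pct" %in% names(series)) return(series)
  if (!"bound" %in% names(series))
    stop_validation("dissociation data needs a bound_pct or bound column")
  y <- series$bound
  if ("nonspecific" %in% names(series)) y <- y - series$nonspecific
  out <- series
  out$bound_pct <- NA_real_
  for (X in unique(series$conc_competitor_M)) {
    sel <- series$conc_competitor_M == X
    t0 <- min(series$time_min[sel])
    y0 <- mean(y[sel & series$time_min == t0])
    if (!is.finite(y0) || y0 <= 0)
      stop_validation("non-positive binding at start of dissociation")
    out$bound_pct[sel] <- 100 * y[sel] / y0
  }
  out
}

#' Dunnett-style many-to-one comparisons against a reference condition
#'
#' One-way ANOVA on per-experiment parameter estimates followed by
#' Dunnett's multiplicity-adjusted comparisons of every condition against
#' the named reference (via `multcomp::glht`).
#'
#' @param values data frame with columns `condition` and `value` (one row
#'   per independent experiment).
#' @param reference reference condition name.
#' @return data frame with columns `condition`, `estimate` (difference
#'   from reference), `p_adj`, `significant` (at `alpha`).
#' @param alpha significance level used for the `significant` flag.
#' @export
dunnett_vs_reference <- function(values, reference, alpha = 0.05) {
  if (!all(c("condition", "value") %in% names(values)))
    stop_validation("values needs condition and value columns")
  if (!reference %in% values$condition)
    stop_validation("reference condition not present: ", reference)
  values$condition <- stats::relevel(factor(values$condition), ref = reference)
  if (nlevels(values$condition) < 2)
    return(data.frame(condition = character(0), estimate = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  fit <- stats::aov(value ~ condition, data = values)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  sm <- summary(gl)
  cmp <- sub(" - .*$", "", names(sm$test$coefficients))
  data.frame(condition = cmp,
             estimate = as.numeric(sm$test$coefficients),
             p_adj = as.numeric(sm$test$pvalues),
             significant = as.numeric(sm$test$pvalues) < alpha)
}

#' Full multi-experiment analysis pipeline with group summary
#'
#' Runs the per-experiment dissociation analysis
#' ([analyse_dissociation_experiment()]) for every condition and
#' experiment, optionally fits saturation curves
#' ([fit_saturation()]) per experiment, and summarises each condition as
#' mean +/- SEM across independent experiments (never across wells).
#' Conditions are then compared against a named reference with Dunnett's
#' many-to-one adjusted tests on the per-experiment estimates of `pK_A`,
#' `k_off` and (when saturation data are given) `pK_D`.
#'
#' @param dissociation `dissociation_series`-style data frame with an
#'   additional `condition` column covering one or more conditions.
#' @param reference reference condition for the Dunnett comparisons
#'   (default: first condition).
#' @param saturation optional `saturation_curve`-style data frame with a
#'   `condition` column.
#' @param slope_model,alpha,fix_k0 passed to the per-experiment analysis.
#' @return object of class `group_summary`: list with `summary` (one row
#'   per condition: n, mean and SEM of `pK_A`, `k_off`, `nH`, optionally
#'   `pK_D`), `comparisons` (named list of Dunnett tables per parameter),
#'   `per_experiment` (the underlying estimates) and `reference`.
#' @examples
#' des <- assay_design(n_experiments = 2, rng_seed = 11)
#' dd <- rbind(
#'   cbind(condition = "M2 wt",
#'         gen_dissociation_series(ground_truth("M2 wt"), des)),
#'   cbind(condition = "M2 N419A",
#'         gen_dissociation_series(ground_truth("M2 N419A"), des)))
#' \donttest{run_pipeline(dd, reference = "M2 wt")}
#' @export
run_pipeline <- function(dissociation, reference = NULL, saturation = NULL,
                         slope_model = "auto", alpha = 0.05, fix_k0 = NULL) {
  if (!"condition" %in% names(dissociation))
    stop_validation("dissociation data needs a condition column")
  conds <- unique(dissociation$condition)
  reference <- reference %||% conds[1]
  if (!reference %in% conds)
    stop_validation("reference condition not present: ", reference)

  per <- list()
  for (cond in conds) {
    sub <- dissociation[dissociation$condition == cond, , drop = FALSE]
    exps <- sort(unique(sub$experiment_id))
    if (length(exps) < 2)
      stop_validation("need >= 2 experiments per condition (", cond, ")")
    grids <- lapply(exps, function(e)
      sort(unique(sub$conc_competitor_M[sub$experiment_id == e])))
    if (length(unique(vapply(grids, paste, character(1), collapse = ","))) > 1)
      stop_validation("mixed concentration designs across experiments in ",
                      cond)
    for (e in exps) {
      an <- analyse_dissociation_experiment(
        sub[sub$experiment_id == e, , drop = FALSE],
        slope_model = slope_model, alpha = alpha, fix_k0 = fix_k0)
      per[[length(per) + 1L]] <- data.frame(
        condition = cond, experiment_id = e,
        pK_A = an$allosteric$pK_A, nH = an$allosteric$nH,
        k_0 = an$allosteric$k_0,
        k_off = if (is.finite(an$k_off_control)) an$k_off_control
                else an$allosteric$k_0)
    }
  }
  per <- do.call(rbind, per)

  if (!is.null(saturation)) {
    if (!"condition" %in% names(saturation))
      stop_validation("saturation data needs a condition column")
    per$pK_D <- NA_real_
    for (cond in unique(saturation$condition)) {
      sub <- saturation[saturation$condition == cond, , drop = FALSE]
      for (e in sort(unique(sub$experiment_id))) {
        fit <- fit_saturation(sub[sub$experiment_id == e, , drop = FALSE])
        key <- per$condition == cond & per$experiment_id == e
        if (any(key)) {
          per$pK_D[key] <- fit$pK_D
        } else {
          row <- per[1, , drop = FALSE]
          row[] <- NA
          row$condition <- cond; row$experiment_id <- e; row$pK_D <- fit$pK_D
          per <- rbind(per, row)
        }
      }
    }
  }

  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  params <- intersect(c("pK_A", "k_off", "nH", "pK_D"), names(per))
  summary_tab <- do.call(rbind, lapply(unique(per$condition), function(cond) {
    sub <- per[per$condition == cond, , drop = FALSE]
    row <- data.frame(condition = cond, n = nrow(sub))
    for (p in params) {
      row[[paste0(p, "_mean")]] <- mean(sub[[p]], na.rm = TRUE)
      row[[paste0(p, "_sem")]] <- sem(sub[[p]])
    }
    row
  }))

  comparisons <- list()
  if (length(conds) > 1) {
    for (p in setdiff(params, "nH")) {
      vals <- data.frame(condition = per$condition, value = per[[p]])
      vals <- vals[is.finite(vals$value), , drop = FALSE]
      if (reference %in% vals$condition &&
          length(unique(vals$condition)) > 1)
        comparisons[[p]] <- dunnett_vs_reference(vals, reference,
                                                 alpha = alpha)
    }
  }
  structure(list(summary = summary_tab, comparisons = comparisons,
                 per_experiment = per, reference = reference),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary (mean +/- SEM across independent experiments):\n")
  print(x$summary, row.names = FALSE)
  if (length(x$comparisons)) {
    cat("\nDunnett comparisons vs ", x$reference, ":\n", sep = "")
    for (p in names(x$comparisons)) {
      cat(" ", p, "\n")
      print(x$comparisons[[p]], row.names = FALSE)
    }
  }
  invisible(x)
}
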