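#' Simulate a binding protocol under the tandem two-site mechanism
#'
#' Integrates the mass-action rate equations of the tandem two-site scheme
#' (see [rate_set()]) through the phases of a protocol.  Free ligand
#' concentrations are held constant within each phase (pseudo-first-order
#' conditions: membranes are dilute and competitor is in vast excess).  The
#' integrator is `deSolve::lsoda`, which switches to an implicit stiff
#' method automatically; the rate constants of realistic schemes span six
#' or more orders of magnitude.
#'
#' @param scheme a [rate_set()].
#' @param protocol a [binding_protocol()].
#' @param receptor_total total receptor concentration (molar, > 0).  Under
#'   pseudo-first-order conditions it only sets the scale of the observable.
#' @param rtol,atol integration tolerances.  The defaults keep receptor
#'   mass conserved to a relative error below 1e-8.
#' @return a data frame of class `time_course` with columns `phase`,
#'   `time_min` (time within the phase), `conc_tracer_M`,
#'   `conc_competitor_M`, `bound` (molar concentration of the observable)
#'   and `bound_pct` (percent of `receptor_total`).
#' @examples
#' rs <- rate_set(1e6, 1000, 10, 0.3, 1e4, 2.4)
#' pr <- dissociation_protocol(tracer = 1e-9, competitor = 0,
#'                             sample_times = seq(0, 10, 1))
#' tc <- simulate_binding(rs, pr, receptor_total = 1e-10)
#' @export
simulate_binding <- function(scheme, protocol, receptor_total,
                             rtol = 1e-8, atol = 1e-12) {
  if (!inherits(scheme, "rate_set")) stop_param("scheme must be a rate_set")
  if (!inherits(protocol, "binding_protocol"))
    stop_param("protocol must be a binding_protocol")
  if (!is.finite(receptor_total) || receptor_total <= 0)
    stop_param("receptor_total must be positive")

  species <- c("R", "RLv", "RLo", "RLoA", "RAv")
  # integrate fractional occupancies: the scheme is linear in the receptor
  # species once L and A are fixed, and tolerances on O(1) fractions keep
  # the error control meaningful at any receptor concentration
  state <- c(R = 1, RLv = 0, RLo = 0, RLoA = 0, RAv = 0)

  deriv <- function(t, y, p) {
    with(as.list(c(y, p)), {
      v_Lv   <- k_on_vest * L * R - k_off_vest * RLv        # R + L <-> RLv
      v_iso  <- k_in * RLv - k_out * RLo                    # RLv <-> RLo
      v_blk  <- k_on_block * A * RLo - k_off_block * RLoA   # RLo + A <-> RLoA
      v_Av   <- k_on_block * A * R - k_off_block * RAv      # R + A <-> RAv
      v_leak <- leak * k_out * RLoA                         # RLoA -> RAv + L
      list(c(R    = -v_Lv - v_Av,
             RLv  =  v_Lv - v_iso,
             RLo  =  v_iso - v_blk,
             RLoA =  v_blk - v_leak,
             RAv  =  v_Av + v_leak))
    })
  }

  out <- data.frame()
  max_cons_err <- 0
  for (i in seq_along(protocol$phases)) {
    ph <- protocol$phases[[i]]
    pars <- c(unlist(scheme), L = ph$tracer, A = ph$competitor)
    times <- sort(unique(c(0, ph$sample_times, ph$duration)))
    sol <- tryCatch(
      deSolve::ode(y = state, times = times, func = deriv, parms = pars,
                   method = "lsoda", rtol = rtol, atol = atol),
      warning = function(w) stop_numeric("integrator failure in phase ", i,
                                         ": ", conditionMessage(w)))
    sol <- as.data.frame(sol)
    # conservation check: the scheme has no receptor source or sink
    tot <- rowSums(sol[species])
    max_cons_err <- max(max_cons_err, max(abs(tot - 1)))
    if (max(abs(tot - 1)) > 1e-7)
      stop_numeric("receptor conservation violated in phase ", i,
                   " (max rel. error ", format(max(abs(tot - 1))), ")")
    if (min(as.matrix(sol[species])) < -atol * 10)
      stop_numeric("negative concentrations in phase ", i)
    sol[species] <- pmax(as.matrix(sol[species]), 0)
    if (length(ph$sample_times)) {
      keep <- sol[sol$time %in% ph$sample_times, , drop = FALSE]
      frac <- rowSums(keep[, protocol$observable, drop = FALSE])
      out <- rbind(out, data.frame(
        phase = i, time_min = keep$time,
        conc_tracer_M = ph$tracer, conc_competitor_M = ph$competitor,
        bound = frac * receptor_total, bound_pct = 100 * frac))
    }
    state <- unlist(sol[nrow(sol), species])
  }
  class(out) <- c("time_course", class(out))
  attr(out, "receptor_total") <- receptor_total
  attr(out, "observable") <- protocol$observable
  attr(out, "conservation_error") <- max_cons_err
  out
}

#' Apparent orthosteric dissociation constant of a tandem scheme
#'
#' Under the tandem mechanism the tracer's apparent equilibrium dissociation
#' constant at the orthosteric site is the product of the vestibule
#' dissociation constant and the fraction of bound receptor that sits in the
#' vestibule state at equilibrium:
#' `K_D = K_A_vest * K_iso / (1 + K_iso)` with `K_iso = k_out/k_in`.
#' High-affinity orthosteric binding thus arises from a weak vestibule site
#' combined with a strongly inward translocation equilibrium.
#'
#' @param scheme a [rate_set()].
#' @return apparent `K_D` in molar.
#' @export
apparent_kd <- function(scheme) {
  if (!inherits(scheme, "rate_set")) stop_param("scheme must be a rate_set")
  Ki <- k_iso(scheme)
  if (!is.finite(Ki)) stop_param("K_iso must be finite")
  if (scheme$k_in == 0)
    stop_param("k_in = 0: orthosteric site unreachable, apparent K_D infinite")
  k_a_vest(scheme) * Ki / (1 + Ki)
}

#' Observed dissociation rate at a given competitor concentration
#'
#' Simulates a full dissociation experiment (tracer pre-equilibration, then
#' dissociation into tracer-free medium containing the unlabelled
#' competitor) and extracts the dominant slower exponential rate from the
#' simulated time course using the same mono/bi-exponential machinery as
#' the data-analysis pipeline.  In the fast-exchange regime (competitor
#' binding and unbinding at the vestibule much faster than translocation)
#' with `leak = 0` the result follows the retardation law
#' `k_obs = k_0 / (1 + X/K_A)` with `K_A = k_off_block/k_on_block`.
#'
#' @param scheme a [rate_set()].
#' @param competitor_conc competitor concentration X (molar).
#' @param tracer tracer concentration used for pre-equilibration (molar).
#' @param receptor_total total receptor concentration (molar).
#' @param n_halflives,n_times sampling grid of the dissociation phase:
#'   `n_times` points spanning `n_halflives` half-lives of the expected
#'   rate (the grid is refined iteratively if the first guess is off).
#' @return observed dissociation rate constant (per minute).
#' @export
predicted_kobs <- function(scheme, competitor_conc, tracer = 1e-9,
                           receptor_total = 1e-10,
                           n_halflives = 3, n_times = 25) {
  if (competitor_conc < 0) stop_param("competitor concentration must be >= 0")
  # competitor-free observed rate: two-step egress through the vestibule
  k0_guess <- scheme$k_out * scheme$k_off_vest /
    (scheme$k_off_vest + scheme$k_in)
  KA <- scheme$k_off_block / scheme$k_on_block
  occ <- competitor_conc / (competitor_conc + KA)
  k_guess <- k0_guess * (1 - occ) + scheme$leak * k0_guess * occ
  k_guess <- max(k_guess, 1e-9)
  times <- seq(0, n_halflives * log(2) / k_guess, length.out = n_times)
  pr <- dissociation_protocol(tracer = tracer, competitor = competitor_conc,
                              sample_times = times)
  tc <- simulate_binding(scheme, pr, receptor_total)
  y0 <- tc$bound_pct[tc$time_min == 0]
  if (y0 <= 0) stop_numeric("no bound tracer at start of dissociation")
  tc$bound_pct <- 100 * tc$bound_pct / y0
  fit <- fit_dissociation(tc)
  fit$selected_rate
}
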