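#' Microscopic rate constants of the tandem two-site binding scheme
#'
#' The tandem two-site mechanism holds that an orthosteric ligand (the
#' radiolabelled tracer L) reaches the orthosteric pocket through a
#' low-affinity extracellular vestibule site, and leaves through the same
#' site.  A second, unlabelled ligand A bound at the vestibule blocks the
#' egress of orthosterically bound tracer.  The scheme has five receptor
#' species:
#'
#' \preformatted{
#'   R        free receptor
#'   RLv      tracer bound at the vestibule
#'   RLo      tracer bound at the orthosteric site, vestibule empty
#'   RLoA     tracer orthosteric + competitor at the vestibule (ternary)
#'   RAv      competitor at the vestibule, orthosteric site empty
#' }
#'
#' and transitions
#' \preformatted{
#'   R   + L  <-> RLv      k_on_vest / k_off_vest
#'   RLv      <-> RLo      k_in / k_out
#'   RLo + A  <-> RLoA     k_on_block / k_off_block
#'   R   + A  <-> RAv      k_on_block / k_off_block
#'   RLoA      -> RAv + L  leak * k_out   (tracer squeezes past the blocker)
#' }
#'
#' The vestibule dissociation constant is `K_A_vest = k_off_vest/k_on_vest`
#' and the isomerisation (translocation) equilibrium is
#' `K_iso = k_out/k_in`.  The macroscopic vestibule affinity measured by
#' dissociation retardation corresponds to `k_off_block/k_on_block`.
#' `leak` is the fraction of the translocation rate `k_out` that persists
#' when the vestibule is occupied by competitor: 0 reproduces complete
#' retardation (NMS-like), values above 0 reproduce the incomplete
#' retardation seen with QNB.
#'
#' @param k_on_vest tracer association to the vestibule (per molar per minute).
#' @param k_off_vest tracer dissociation from the vestibule (per minute).
#' @param k_in vestibule-to-orthosteric translocation (per minute).
#' @param k_out orthosteric-to-vestibule translocation (per minute).
#' @param k_on_block competitor association to the vestibule (per molar per
#'   minute); used both for free and for orthosterically occupied receptors.
#' @param k_off_block competitor dissociation from the vestibule (per minute).
#' @param leak fraction in \[0, 1\] of `k_out` that remains when the
#'   vestibule is occupied by competitor.
#' @return an object of class `rate_set`.
#' @examples
#' rs <- rate_set(k_on_vest = 1e6, k_off_vest = 1000, k_in = 10, k_out = 0.3,
#'                k_on_block = 1e4, k_off_block = 2.4)
#' apparent_kd(rs)
#' @export
rate_set <- function(k_on_vest, k_off_vest, k_in, k_out,
                     k_on_block, k_off_block, leak = 0) {
  vals <- c(k_on_vest = k_on_vest, k_off_vest = k_off_vest, k_in = k_in,
            k_out = k_out, k_on_block = k_on_block, k_off_block = k_off_block,
            leak = leak)
  if (!all(is.finite(vals))) stop_param("all rate constants must be finite")
  if (any(vals < 0)) stop_param("all rate constants must be non-negative")
  if (leak < 0 || leak > 1) stop_param("leak must lie in [0, 1]")
  if (k_on_vest <= 0 || k_off_vest <= 0)
    stop_param("vestibule rates must be positive (K_A_vest must exist)")
  if (k_in <= 0 || k_out <= 0)
    stop_param("translocation rates k_in and k_out must be positive")
  structure(as.list(vals), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Tandem two-site rate set (per minute, per molar per minute):\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  cat(sprintf("  K_A_vest = %.4g M, K_iso = %.4g\n",
              x$k_off_vest / x$k_on_vest, x$k_out / x$k_in))
  invisible(x)
}

#' Vestibule dissociation constant and isomerisation ratio of a rate set
#' @param scheme a [rate_set()].
#' @return molar `K_A_vest` or dimensionless `K_iso`.
#' @keywords internal
k_a_vest <- function(scheme) scheme$k_off_vest / scheme$k_on_vest

k_iso <- function(scheme) scheme$k_out / scheme$k_in

#' Experimental protocol for the mass-action simulator
#'
#' A protocol is an ordered list of phases.  Each phase fixes the free
#' tracer and competitor concentrations (pseudo-first-order: ligand is in
#' vast excess over receptor and is not depleted) for a given duration and
#' states when the bound-tracer observable is sampled.  The standard
#' dissociation protocol is a long pre-incubation with tracer followed by a
#' dissociation phase in which competitor is added (and, ideally, tracer
#' rebinding is blocked).
#'
#' @param phases list of phases, each a list with elements `duration`
#'   (minutes), `tracer` (molar), `competitor` (molar) and `sample_times`
#'   (minutes from phase start; may be empty).
#' @param observable which species count as "bound tracer".  The default
#'   counts only orthosterically bound tracer (`RLo`, `RLoA`): vestibule
#'   complexes are low-affinity and are lost during filtration.
#' @return an object of class `binding_protocol`.
#' @export
binding_protocol <- function(phases,
                             observable = c("RLo", "RLoA")) {
  if (!length(phases)) stop_param("protocol needs at least one phase")
  species <- c("RLv", "RLo", "RLoA")
  observable <- match.arg(observable, choices = species, several.ok = TRUE)
  phases <- lapply(phases, function(p) {
    p$sample_times <- p$sample_times %||% numeric(0)
    p$tracer <- p$tracer %||% 0
    p$competitor <- p$competitor %||% 0
    if (!is.finite(p$duration) || p$duration <= 0)
      stop_param("phase durations must be positive")
    if (p$tracer < 0 || p$competitor < 0)
      stop_param("ligand concentrations must be non-negative")
    if (length(p$sample_times) &&
        (min(p$sample_times) < 0 || max(p$sample_times) > p$duration))
      stop_param("sampling times must lie within the phase")
    p
  })
  structure(list(phases = phases, observable = observable),
            class = "binding_protocol")
}

#' Standard two-phase dissociation protocol
#'
#' Pre-equilibration with tracer followed by a dissociation phase in which
#' unlabelled competitor is added.  Mirrors the bench protocol of
#' pre-incubating membranes with tracer overnight and then initiating
#' dissociation by addition of excess unlabelled ligand.
#'
#' @param tracer tracer concentration during pre-incubation (molar).
#' @param competitor competitor concentration during dissociation (molar).
#' @param sample_times sampling times of the dissociation phase (minutes).
#' @param preincubation_min pre-incubation length (minutes; default 720,
#'   i.e. 12 h, long enough for full equilibrium at typical rates).
#' @param tracer_during_dissociation free tracer concentration during the
#'   dissociation phase; defaults to 0 (infinite-dilution idealisation).
#' @inheritParams binding_protocol
#' @return a [binding_protocol()].
#' @export
dissociation_protocol <- function(tracer, competitor, sample_times,
                                  preincubation_min = 720,
                                  tracer_during_dissociation = 0,
                                  observable = c("RLo", "RLoA")) {
  binding_protocol(list(
    list(duration = preincubation_min, tracer = tracer, competitor = 0,
         sample_times = numeric(0)),
    list(duration = max(sample_times), tracer = tracer_during_dissociation,
         competitor = competitor, sample_times = sample_times)
  ), observable = observable)
}

#' Derive a fast-exchange rate set matching a ground-truth parameter row
#'
#' Builds a [rate_set()] whose macroscopic dissociation behaviour matches a
#' ground-truth parameter set: the competitor-free observed rate equals
#' `k_0` (via `k_out = k_0 (k_off_vest + k_in)/k_off_vest`, the two-step
#' egress expression) and the vestibule blocking affinity equals
#' `10^-pK_A` (via `k_on_block = k_off_block / K_A`).  The default
#' vestibule kinetics put the scheme deep in the fast-exchange regime
#' (vestibule exchange orders of magnitude faster than translocation), in
#' which the observed dissociation rate follows the hyperbolic
#' retardation law with slope factor 1; the mechanistic scheme with a
#' single vestibule site cannot produce nH > 1.
#'
#' @param truth one-row [ground_truth()] (uses `k_0` and `pK_A`).
#' @param k_on_vest,k_off_vest tracer vestibule kinetics; the default
#'   vestibule affinity is 1 mM, a typical weak allosteric-site value.
#' @param k_in vestibule-to-orthosteric translocation rate.
#' @param k_off_block competitor vestibule exit rate; must exceed the
#'   translocation rates for fast exchange.
#' @param leak see [rate_set()].
#' @return a [rate_set()].
#' @export
rate_set_from_truth <- function(truth, k_on_vest = 1e6, k_off_vest = 1000,
                                k_in = 10, k_off_block = 1000, leak = 0) {
  if (!is.finite(truth$pK_A)) stop_param("truth needs a finite pK_A")
  k_out <- truth$k_0 * (k_off_vest + k_in) / k_off_vest
  rate_set(k_on_vest = k_on_vest, k_off_vest = k_off_vest,
           k_in = k_in, k_out = k_out,
           k_on_block = k_off_block / from_pK(truth$pK_A),
           k_off_block = k_off_block, leak = leak)
}
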