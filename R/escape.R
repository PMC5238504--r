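#' Distance-dependent steering acceleration schedule
#'
#' Encodes the steering laws used to drive a ligand out of (or into) the
#' binding pocket along the pocket axis.  During steered dissociation the
#' applied acceleration is inversely proportional to the distance d of the
#' ligand from the pocket bottom, `a(d) = min(a0/d, cap)`, directed
#' outward; the cap is applied after the division by distance.  During
#' steered association the acceleration grows as the ligand approaches
#' from a starting shell, `a(d) = a0/(scale - d)`, directed inward, and is
#' singular at `d = scale`.
#'
#' @param mode `"dissociation"` or `"association"`.
#' @param a0 initial acceleration before the distance division
#'   (nm ns^-2).
#' @param cap acceleration cap applied after the distance division
#'   (nm ns^-2; dissociation mode only).
#' @param apply_interval steering is re-evaluated and applied every this
#'   many integration steps (held constant in between).
#' @param scale_A association scale constant (Angstrom): distance at
#'   which the association law diverges.
#' @return object of class `steering_schedule`.
#' @export
steering_schedule <- function(mode = c("dissociation", "association"),
                              a0 = 4000, cap = 4000, apply_interval = 100L,
                              scale_A = 30) {
  mode <- match.arg(mode)
  if (a0 <= 0) stop_param("a0 must be positive")
  if (cap <= 0) stop_param("cap must be positive")
  if (apply_interval < 1) stop_param("apply_interval must be >= 1")
  structure(list(mode = mode, a0 = a0, cap = cap,
                 apply_interval = as.integer(apply_interval),
                 scale_A = scale_A), class = "steering_schedule")
}

#' Steering acceleration at a given ligand distance
#'
#' @param schedule a [steering_schedule()].
#' @param distance distance of the ligand centre from the pocket bottom
#'   (Angstrom for the toy coordinate; the schedule itself is agnostic of
#'   units as the division is by the bare distance value).
#' @return signed acceleration (nm ns^-2): positive = outward
#'   (dissociation), negative = inward (association).
#' @examples
#' steering_accel(steering_schedule("dissociation", a0 = 4000), 2)   # 2000
#' steering_accel(steering_schedule("association", a0 = 500), 10)    # -25
#' @export
steering_accel <- function(schedule, distance) {
  if (!inherits(schedule, "steering_schedule"))
    stop_param("schedule must be a steering_schedule")
  if (schedule$mode == "dissociation") {
    if (any(distance <= 0)) stop_param("distance must be positive")
    pmin(schedule$a0 / distance, schedule$cap)
  } else {
    if (any(distance >= schedule$scale_A))
      stop_param("association law singular at distance >= scale (",
                 schedule$scale_A, " A)")
    -schedule$a0 / (schedule$scale_A - distance)
  }
}

#' Double-well potential landscape along the escape coordinate
#'
#' One-dimensional free-energy model of the egress path: a deep orthosteric
#' well near the pocket bottom, a shallower vestibule well in the
#' extracellular vestibule (about 16 Angstrom out), and flat bulk beyond a
#' boundary.  Wells are inverted Gaussians; energies in kT.
#'
#' @param well_positions_A positions of the orthosteric and vestibule
#'   wells (Angstrom).
#' @param well_depths_kT depths of the two wells (kT, positive).
#' @param well_widths_A Gaussian widths of the two wells (Angstrom).
#' @param bulk_boundary_A distance beyond which the ligand counts as
#'   dissociated into bulk.
#' @return object of class `potential_landscape` with `energy(x)` and
#'   `force(x)` functions.
#' @export
potential_landscape <- function(well_positions_A = c(0, 16),
                                well_depths_kT = c(10, 3),
                                well_widths_A = c(2.5, 2.5),
                                bulk_boundary_A = 28) {
  if (length(well_positions_A) != 2 || diff(well_positions_A) <= 0)
    stop_param("need two ordered well positions")
  if (any(well_depths_kT <= 0)) stop_param("well depths must be positive")
  if (any(well_widths_A <= 0)) stop_param("well widths must be positive")
  p <- well_positions_A; D <- well_depths_kT; w <- well_widths_A
  energy <- function(x)
    -D[1] * exp(-(x - p[1])^2 / (2 * w[1]^2)) -
     D[2] * exp(-(x - p[2])^2 / (2 * w[2]^2))
  force <- function(x)   # -dU/dx
    -D[1] * (x - p[1]) / w[1]^2 * exp(-(x - p[1])^2 / (2 * w[1]^2)) -
     D[2] * (x - p[2]) / w[2]^2 * exp(-(x - p[2])^2 / (2 * w[2]^2))
  structure(list(well_positions_A = p, well_depths_kT = D,
                 well_widths_A = w, bulk_boundary_A = bulk_boundary_A,
                 energy = energy, force = force),
            class = "potential_landscape")
}

#' Overdamped Brownian-dynamics simulation of steered ligand escape
#'
#' Euler-Maruyama integration of an overdamped particle on the
#' one-dimensional landscape, in reduced units (kT = 1, friction = 1;
#' distances in Angstrom, time in integration steps of length `dt`).  The
#' steering acceleration is converted to a force through `steering_gain`
#' (kT/Angstrom per nm ns^-2) and is re-evaluated every
#' `schedule$apply_interval` steps, held constant in between, mirroring
#' the update cadence of the steered-MD protocol.  Reflecting boundaries
#' confine the coordinate to `[x_min, x_max]`.
#'
#' @param landscape a [potential_landscape()].
#' @param schedule a [steering_schedule()], or NULL for free diffusion on
#'   the landscape.
#' @param n_steps number of integration steps.
#' @param seed integer RNG seed.
#' @param dt time step (reduced units).
#' @param steering_gain conversion from schedule acceleration to force on
#'   the toy coordinate (kT/Angstrom per nm ns^-2).  The default is
#'   calibrated so that the escape threshold of the default landscape
#'   falls inside the schedule's working range of a0 values: below
#'   roughly a0 = 3000 the ligand stays orthosteric, around 4000 it
#'   leaves the orthosteric well and lingers in the vestibule, and well
#'   above that it crosses into bulk.  Absolute a0 values are not
#'   comparable to any all-atom protocol; only their ordering is.
#' @param x0 starting position (Angstrom; default the orthosteric well).
#' @param x_min,x_max reflecting boundaries of the coordinate.
#' @param record_every thin the stored trajectory to every this many steps.
#' @return list with `trajectory` (data frame `step`, `distance_A`),
#'   `escaped` (crossed the bulk boundary), `left_orthosteric`,
#'   `reached_vestibule`, `residence_steps` (named: orthosteric,
#'   vestibule, bulk) and `final_distance_A`.
#' @examples
#' land <- potential_landscape()
#' sch <- steering_schedule("dissociation", a0 = 6000)
#' run_escape(land, sch, n_steps = 2e4, seed = 1)$escaped
#' @export
run_escape <- function(landscape, schedule, n_steps, seed,
                       dt = 1e-3, steering_gain = 2e-3,
                       x0 = NULL, x_min = -4, x_max = 40,
                       record_every = 100L) {
  if (!inherits(landscape, "potential_landscape"))
    stop_param("landscape must be a potential_landscape")
  if (!is.null(schedule) && !inherits(schedule, "steering_schedule"))
    stop_param("schedule must be a steering_schedule or NULL")
  if (n_steps < 1 || dt <= 0) stop_param("need positive n_steps and dt")
  set.seed(as.integer(seed))

  p <- landscape$well_positions_A
  midpoint <- mean(p)
  bulk <- landscape$bulk_boundary_A
  x <- x0 %||% p[1]
  sqrt2dt <- sqrt(2 * dt)
  interval <- if (is.null(schedule)) n_steps + 1L else schedule$apply_interval

  res <- c(orthosteric = 0L, vestibule = 0L, bulk = 0L)
  left_orth <- FALSE; reached_vest <- FALSE; escaped <- FALSE
  steer <- 0
  n_rec <- floor(n_steps / record_every) + 1L
  rec_x <- numeric(n_rec); rec_s <- integer(n_rec)
  rec_x[1] <- x; rec_s[1] <- 0L; ri <- 1L

  noise <- stats::rnorm(n_steps)
  for (s in seq_len(n_steps)) {
    if (!is.null(schedule) && (s - 1L) %% interval == 0L) {
      d <- max(x - p[1], 1e-3)  # distance from the pocket bottom
      steer <- if (schedule$mode == "dissociation") {
        steering_gain * min(schedule$a0 / d, schedule$cap)
      } else {
        if (d >= schedule$scale_A)
          stop_param("association law singular at distance >= scale")
        -steering_gain * schedule$a0 / (schedule$scale_A - d)
      }
    }
    dx <- (landscape$force(x) + steer) * dt + sqrt2dt * noise[s]
    # a single step larger than the whole domain signals a blown-up force
    if (!is.finite(dx) || abs(dx) > (x_max - x_min))
      stop_numeric("integration unstable: reduce dt")
    x <- x + dx
    if (x < x_min) x <- 2 * x_min - x
    if (x > x_max) x <- 2 * x_max - x
    zone <- if (x > bulk) 3L else if (x > midpoint) 2L else 1L
    res[zone] <- res[zone] + 1L
    if (zone >= 2L) left_orth <- TRUE
    if (zone == 2L) reached_vest <- TRUE
    if (zone == 3L) escaped <- TRUE
    if (s %% record_every == 0L) {
      ri <- ri + 1L
      rec_x[ri] <- x; rec_s[ri] <- s
    }
  }
  list(trajectory = data.frame(step = rec_s[1:ri], distance_A = rec_x[1:ri]),
       escaped = escaped, left_orthosteric = left_orth,
       reached_vestibule = reached_vest,
       residence_steps = res, final_distance_A = x)
}

#' Escape probability across a sweep of initial accelerations
#'
#' Repeats [run_escape()] over `n_seeds` seeds for each `a0` and reports
#' the fraction of runs that left the orthosteric well and the fraction
#' that crossed into bulk.  Escape probability is expected to be monotone
#' non-decreasing in `a0`.
#'
#' @param a0_values vector of initial accelerations (nm ns^-2).
#' @param n_seeds independent replicate runs per value.
#' @param landscape a [potential_landscape()].
#' @param seed master seed; replicate r of value i runs with a substream
#'   seed derived from it.
#' @param ... passed to [run_escape()].
#' @inheritParams run_escape
#' @return data frame with columns `a0`, `p_left_orthosteric`, `p_escaped`.
#' @export
escape_sweep <- function(a0_values, n_seeds = 50,
                         landscape = potential_landscape(),
                         n_steps = 2e4, seed = 1, ...) {
  out <- lapply(seq_along(a0_values), function(i) {
    sch <- steering_schedule("dissociation", a0 = a0_values[i])
    runs <- lapply(seq_len(n_seeds), function(r)
      run_escape(landscape, sch, n_steps = n_steps,
                 seed = substream_seed(seed, i * 1000L + r), ...))
    data.frame(a0 = a0_values[i],
               p_left_orthosteric = mean(vapply(runs, `[[`, logical(1),
                                                "left_orthosteric")),
               p_escaped = mean(vapply(runs, `[[`, logical(1), "escaped")))
  })
  do.call(rbind, out)
}
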