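#' Per-residue root mean square fluctuation after superposition
#'
#' Each frame is rigid-body superposed (least-squares Kabsch alignment via
#' `bio3d::fit.xyz`) onto the reference frame over the chosen atom subset,
#' and the fluctuation of residue i is the root mean square displacement
#' of its subset atoms from their reference positions, over frames and
#' atoms:
#' \deqn{RMSF_i = \sqrt{\frac{1}{T}\sum_t \langle |r_i(t) - r_i(t_{ref})|^2 \rangle}}
#' Superposition removes global rigid-body motion, so a rigidly rotating
#' or translating structure has zero RMSF everywhere.
#'
#' @param traj an [md_trajectory()].
#' @param subset `"backbone"` (N, CA, C, O) or `"heavy"` (all non-hydrogen
#'   receptor atoms).
#' @param reference_frame frame used as reference (default first frame).
#' @return data frame of class `fluctuation_profile` with columns `resno`,
#'   `resid`, `rmsf` (Angstrom) and `n_atoms`.
#' @examples
#' co <- array(rnorm(12 * 3 * 5), c(12, 3, 5))
#' at <- data.frame(elety = "CA", resno = rep(1:12),
#'                  resid = "ALA", element = "C")
#' rmsf_profile(md_trajectory(co, at))
#' @export
rmsf_profile <- function(traj, subset = c("backbone", "heavy"),
                         reference_frame = 1L) {
  subset <- match.arg(subset)
  if (!inherits(traj, "md_trajectory"))
    stop_validation("traj must be an md_trajectory")
  sel <- subset_atoms(traj, subset)
  a <- traj$atoms
  residues <- unique(a$resno[!a$ligand])
  if (any(vapply(residues, function(r) !any(sel & a$resno == r), logical(1))))
    stop_validation("subset '", subset, "' is empty for some residue")
  n_fr <- dim(traj$coords)[3]
  if (reference_frame < 1 || reference_frame > n_fr)
    stop_param("reference_frame out of range")

  # superpose every frame on the reference over the subset atoms
  xyz <- t(apply(traj$coords, 3, function(m) as.vector(t(m))))  # frames x 3N
  inds <- as.vector(t(outer((which(sel) - 1) * 3, 1:3, `+`)))
  fitted <- tryCatch(
    suppressWarnings(bio3d::fit.xyz(fixed = xyz[reference_frame, ],
                                    mobile = xyz,
                                    fixed.inds = inds, mobile.inds = inds)),
    error = function(e) stop_numeric("superposition failed (degenerate ",
                                     "geometry?): ", conditionMessage(e)))

  ref <- fitted[reference_frame, ]
  disp2 <- sweep(fitted, 2, ref)^2
  # per-atom mean squared displacement over frames
  msd_xyz <- colMeans(disp2)
  msd_atom <- msd_xyz[seq(1, length(msd_xyz), 3)] +
    msd_xyz[seq(2, length(msd_xyz), 3)] + msd_xyz[seq(3, length(msd_xyz), 3)]

  out <- do.call(rbind, lapply(residues, function(r) {
    at <- which(sel & a$resno == r)
    data.frame(resno = r, resid = a$resid[at[1]],
               rmsf = sqrt(mean(msd_atom[at])), n_atoms = length(at))
  }))
  class(out) <- c("fluctuation_profile", class(out))
  attr(out, "subset") <- subset
  attr(out, "reference_frame") <- reference_frame
  out
}

#' Write a per-residue profile to CSV
#' @param profile a `fluctuation_profile` or `contact_profile` data frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
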