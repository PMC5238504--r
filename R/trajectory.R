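#' Build a coordinate trajectory object
#'
#' A trajectory is an ordered set of coordinate frames (Angstrom) over a
#' fixed atom table.  Used by [rmsf_profile()] and [contact_frequency()].
#'
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames`.
#' @param atoms data frame with one row per atom and columns `elety` (atom
#'   name, e.g. "CA"), `resno` (residue number), `resid` (residue name,
#'   e.g. "TYR"), `element` (e.g. "C", "N", "H"); an optional logical
#'   column `ligand` marks ligand atoms.
#' @param dt_ns optional time step between frames (ns), metadata only.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, atoms, dt_ns = NA_real_) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop_validation("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[3] < 2) stop_validation("a trajectory needs >= 2 frames")
  if (!all(is.finite(coords))) stop_validation("coordinates must be finite")
  need <- c("elety", "resno", "resid", "element")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop_validation("atoms needs columns ", paste(need, collapse = ", "))
  if (nrow(atoms) != dim(coords)[1])
    stop_validation("atom table and coordinate array disagree on atom count")
  if (!"ligand" %in% names(atoms)) atoms$ligand <- FALSE
  structure(list(coords = coords, atoms = atoms, dt_ns = dt_ns),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, %d residues (%d ligand atoms)\n",
              dim(x$coords)[1], dim(x$coords)[3],
              length(unique(x$atoms$resno[!x$atoms$ligand])),
              sum(x$atoms$ligand)))
  invisible(x)
}

#' Read a multi-model PDB or XYZ trajectory
#'
#' Multi-model PDB files are read with `bio3d::read.pdb` (each MODEL is a
#' frame); XYZ files are read as repeated element/x/y/z blocks, each block
#' one frame (all atoms are then assigned to one pseudo-residue per atom
#' index, suitable for per-atom fluctuation analysis).
#'
#' @param path file path; format chosen by extension (`.pdb` or `.xyz`).
#' @param ligand_resid optional residue name(s) marking ligand atoms
#'   (PDB only), e.g. `"QNB"`.
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, ligand_resid = NULL) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz                       # frames x 3N
    n_at <- nrow(pdb$atom)
    n_fr <- nrow(xyz)
    coords <- array(NA_real_, c(n_at, 3, n_fr))
    for (f in seq_len(n_fr))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    el <- pdb$atom$elesy
    if (is.null(el) || all(is.na(el)) || all(el == ""))
      el <- substr(gsub("[0-9]", "", pdb$atom$elety), 1, 1)
    atoms <- data.frame(elety = pdb$atom$elety, resno = pdb$atom$resno,
                        resid = pdb$atom$resid, element = trimws(el))
    atoms$ligand <- atoms$resid %in% (ligand_resid %||% character(0))
    md_trajectory(coords, atoms)
  } else if (ext == "xyz") {
    read_xyz_trajectory(path)
  } else {
    stop_validation("unsupported trajectory format: .", ext)
  }
}

# XYZ: repeated blocks of (n_atoms, comment, n_atoms lines "El x y z")
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_validation("empty XYZ file")
  frames <- list()
  i <- 1L
  elements <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_validation("malformed XYZ header at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[`, character(1), 1)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(co))) stop_validation("non-numeric XYZ coordinates")
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop_validation("atom count changes between XYZ frames")
    frames[[length(frames) + 1L]] <- co
    i <- i + 2L + n
  }
  coords <- array(unlist(frames), c(length(elements), 3, length(frames)))
  atoms <- data.frame(elety = elements,
                      resno = seq_along(elements),
                      resid = elements, element = elements)
  md_trajectory(coords, atoms)
}

# logical index of receptor atoms belonging to the chosen subset
subset_atoms <- function(traj, subset = c("backbone", "heavy")) {
  subset <- match.arg(subset)
  a <- traj$atoms
  base <- !a$ligand & a$element != "H"
  if (subset == "backbone")
    base & a$elety %in% c("N", "CA", "C", "O")
  else
    base
}
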