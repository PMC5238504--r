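#' Geometric criteria for ligand-receptor contact counting
#'
#' Defaults follow common practice for trajectory analysis: a hydrogen
#' bond requires donor-acceptor distance <= 3.5 Angstrom and a
#' donor-H-acceptor angle >= 120 degrees; a ring-stacking (pi-pi) contact
#' requires ring-centroid distance <= 5.5 Angstrom and interplanar angle
#' <= `stack_angle_deg` (set it to 90 to accept any mutual orientation,
#' including T-shaped).  All thresholds are configurable.
#'
#' @param hbond_dist_A donor-acceptor distance cutoff (Angstrom).
#' @param hbond_angle_deg minimum donor-H-acceptor angle (degrees).
#' @param stack_dist_A ring-centroid distance cutoff (Angstrom).
#' @param stack_angle_deg maximum interplanar angle (degrees).
#' @param ligand_rings optional list of character vectors of ligand atom
#'   names (`elety`), one vector per aromatic ring; when NULL, rings are
#'   detected from a distance-based bond graph.
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_dist_A = 3.5, hbond_angle_deg = 120,
                             stack_dist_A = 5.5, stack_angle_deg = 30,
                             ligand_rings = NULL) {
  if (hbond_dist_A < 0 || stack_dist_A < 0)
    stop_param("distance cutoffs must be non-negative")
  structure(list(hbond_dist_A = hbond_dist_A,
                 hbond_angle_deg = hbond_angle_deg,
                 stack_dist_A = stack_dist_A,
                 stack_angle_deg = stack_angle_deg,
                 ligand_rings = ligand_rings), class = "contact_criteria")
}

# ring atom names of aromatic residues (side-chain rings)
residue_ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

#' Per-residue ligand-contact frequencies over a trajectory
#'
#' For every frame, counts hydrogen bonds and ring-stacking contacts
#' between the ligand and each receptor residue, then normalises over the
#' trajectory: frequency = 100 x (total count) / (number of frames).
#' Because a ligand can make several simultaneous contacts with one
#' residue, frequencies above 100 are possible.
#'
#' Hydrogen-bond donors are N/O atoms with a covalently attached hydrogen
#' (H within 1.3 Angstrom in the same molecule); acceptors are any N/O
#' atoms.  Both directions (ligand donor to residue acceptor and residue
#' donor to ligand acceptor) are counted.
#'
#' @param traj an [md_trajectory()] whose atom table marks ligand atoms.
#' @param criteria a [contact_criteria()].
#' @return data frame of class `contact_profile` with columns `resno`,
#'   `resid`, `hbond_freq`, `stack_freq` (percent of frames; may exceed
#'   100).
#' @export
contact_frequency <- function(traj, criteria = contact_criteria()) {
  if (!inherits(traj, "md_trajectory"))
    stop_validation("traj must be an md_trajectory")
  if (!inherits(criteria, "contact_criteria"))
    stop_validation("criteria must be contact_criteria")
  a <- traj$atoms
  if (!any(a$ligand)) stop_validation("no ligand atoms defined")
  n_fr <- dim(traj$coords)[3]
  lig <- which(a$ligand)
  rec <- which(!a$ligand)
  residues <- unique(a$resno[rec])

  # covalent H attachment from the reference frame geometry
  ref <- traj$coords[, , 1]
  hydrogens <- which(a$element == "H")
  polar <- which(a$element %in% c("N", "O"))
  h_parent <- vapply(hydrogens, function(h) {
    cand <- polar[a$ligand[polar] == a$ligand[h]]
    if (!length(cand)) return(NA_integer_)
    d <- sqrt(colSums((t(ref[cand, , drop = FALSE]) - ref[h, ])^2))
    if (min(d) <= 1.3) cand[which.min(d)] else NA_integer_
  }, integer(1))
  donors <- data.frame(h = hydrogens, d = h_parent)
  donors <- donors[!is.na(donors$d), , drop = FALSE]

  lig_rings <- criteria$ligand_rings
  if (is.null(lig_rings)) lig_rings <- detect_rings(traj, lig)
  lig_ring_idx <- lapply(lig_rings, function(nm) {
    idx <- lig[match(nm, a$elety[lig])]
    if (any(is.na(idx))) stop_validation("unknown ligand ring atom name")
    idx
  })
  if (!length(lig_ring_idx) && criteria$stack_dist_A > 0)
    warning("no rings found in ligand: stacking frequencies are all zero")
  res_ring_idx <- lapply(residues, function(r) {
    at <- rec[a$resno[rec] == r]
    rings <- residue_ring_atoms[[a$resid[at[1]]]]
    if (is.null(rings)) return(list())
    out <- lapply(rings, function(nm) at[match(nm, a$elety[at])])
    Filter(function(x) !any(is.na(x)), out)
  })
  names(res_ring_idx) <- as.character(residues)

  deg <- function(x) x * 180 / pi
  hb_counts <- stats::setNames(numeric(length(residues)),
                               as.character(residues))
  st_counts <- hb_counts

  for (f in seq_len(n_fr)) {
    co <- traj$coords[, , f]
    # ---- hydrogen bonds ----
    if (nrow(donors) && criteria$hbond_dist_A > 0) {
      acceptors <- polar
      for (i in seq_len(nrow(donors))) {
        d_at <- donors$d[i]; h_at <- donors$h[i]
        # only ligand<->receptor pairs
        acc <- acceptors[a$ligand[acceptors] != a$ligand[d_at]]
        if (!length(acc)) next
        dv <- t(co[acc, , drop = FALSE]) - co[d_at, ]
        dist_da <- sqrt(colSums(dv^2))
        ok <- dist_da <= criteria$hbond_dist_A & dist_da > 0
        if (!any(ok)) next
        for (j in acc[ok]) {
          v1 <- co[d_at, ] - co[h_at, ]
          v2 <- co[j, ] - co[h_at, ]
          ang <- deg(acos(pmin(pmax(sum(v1 * v2) /
            (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)))
          if (ang >= criteria$hbond_angle_deg) {
            r <- if (a$ligand[d_at]) a$resno[j] else a$resno[d_at]
            hb_counts[as.character(r)] <- hb_counts[as.character(r)] + 1
          }
        }
      }
    }
    # ---- ring stacking ----
    if (length(lig_ring_idx) && criteria$stack_dist_A > 0) {
      lig_geo <- lapply(lig_ring_idx, ring_geometry, co = co)
      for (r in names(res_ring_idx)) {
        for (ring in res_ring_idx[[r]]) {
          g2 <- ring_geometry(ring, co)
          for (g1 in lig_geo) {
            dist <- sqrt(sum((g1$centroid - g2$centroid)^2))
            if (dist > criteria$stack_dist_A) next
            ang <- deg(acos(pmin(abs(sum(g1$normal * g2$normal)), 1)))
            if (ang <= criteria$stack_angle_deg)
              st_counts[r] <- st_counts[r] + 1
          }
        }
      }
    }
  }

  out <- data.frame(
    resno = residues,
    resid = vapply(residues, function(r) a$resid[rec[a$resno[rec] == r][1]],
                   character(1)),
    hbond_freq = 100 * unname(hb_counts) / n_fr,
    stack_freq = 100 * unname(st_counts) / n_fr)
  class(out) <- c("contact_profile", class(out))
  out
}

# centroid and unit normal of a ring (plane fit by SVD)
ring_geometry <- function(idx, co) {
  pts <- co[idx, , drop = FALSE]
  centroid <- colMeans(pts)
  sv <- svd(sweep(pts, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

# distance-based ring detection on the ligand heavy-atom bond graph
detect_rings <- function(traj, lig) {
  a <- traj$atoms
  heavy <- lig[a$element[lig] != "H"]
  if (length(heavy) < 5) return(list())
  co <- traj$coords[heavy, , 1, drop = TRUE]
  d <- as.matrix(stats::dist(co))
  adj <- d > 0 & d < 1.8
  if (!requireNamespace("igraph", quietly = TRUE)) {
    warning("igraph not available: supply criteria$ligand_rings explicitly")
    return(list())
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cyc <- igraph::simple_cycles(g, min = 5, max = 6)
  seen <- character(0)
  rings <- list()
  for (cy in cyc) {
    key <- paste(sort(as.integer(cy)), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- a$elety[heavy[as.integer(cy)]]
  }
  rings
}
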