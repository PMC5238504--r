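test_that("trajectory container validates its invariants", {
  fx <- static_ca_trajectory(10, 4)
  expect_s3_class(md_trajectory(fx$coords, fx$atoms), "md_trajectory")
  expect_error(md_trajectory(fx$coords[, , 1, drop = FALSE], fx$atoms),
               class = "tandemsite_validation_error")  # < 2 frames
  bad <- fx$coords; bad[1, 1, 1] <- NA
  expect_error(md_trajectory(bad, fx$atoms),
               class = "tandemsite_validation_error")
  expect_error(md_trajectory(fx$coords, fx$atoms[-1, ]),
               class = "tandemsite_validation_error")
})

test_that("a static trajectory has zero RMSF everywhere", {
  fx <- static_ca_trajectory(30, 8)
  prof <- rmsf_profile(md_trajectory(fx$coords, fx$atoms))
  expect_equal(prof$rmsf, rep(0, 30), tolerance = 1e-10)
  expect_equal(nrow(prof), length(unique(fx$atoms$resno)))
})

test_that("a sinusoidally oscillating atom has RMSF amplitude/sqrt(2)", {
  n_static <- 120; n_frames <- 64
  fx <- static_ca_trajectory(n_static, n_frames, seed = 2)
  # append one atom oscillating along x with amplitude 1 A over full
  # periods; the reference frame (t = 0) sits at the oscillation midpoint
  phases <- 2 * pi * (seq_len(n_frames) - 1) / n_frames
  all_coords <- array(NA_real_, c(n_static + 1, 3, n_frames))
  all_coords[1:n_static, , ] <- fx$coords
  for (f in seq_len(n_frames))
    all_coords[n_static + 1, , f] <- c(sin(phases[f]), 0, 0)
  atoms <- rbind(fx$atoms,
                 data.frame(elety = "CA", resno = n_static + 1,
                            resid = "GLY", element = "C"))
  prof <- rmsf_profile(md_trajectory(all_coords, atoms))
  expect_equal(prof$rmsf[prof$resno == n_static + 1], 1 / sqrt(2),
               tolerance = 0.02)
  expect_lt(max(prof$rmsf[prof$resno <= n_static]), 0.02)
})

test_that("RMSF is invariant to rigid rotation and translation of frames", {
  fx <- static_ca_trajectory(40, 10, seed = 3)
  coords <- fx$coords
  set.seed(4)
  for (f in 2:10) {
    R <- rot_z(runif(1, 0, 2 * pi))
    coords[, , f] <- fx$base %*% t(R) +
      matrix(runif(3, -5, 5), 40, 3, byrow = TRUE)
  }
  prof <- rmsf_profile(md_trajectory(coords, fx$atoms))
  expect_lt(max(prof$rmsf), 1e-8)
})

test_that("RMSF is unchanged when the trajectory is duplicated", {
  fx <- static_ca_trajectory(25, 6, seed = 5)
  coords <- fx$coords
  set.seed(6)
  coords <- coords + array(rnorm(length(coords), 0, 0.3), dim(coords))
  coords[, , 1] <- fx$coords[, , 1]
  tr1 <- md_trajectory(coords, fx$atoms)
  tr2 <- md_trajectory(array(c(coords, coords),
                             c(25, 3, 12)), fx$atoms)
  expect_equal(rmsf_profile(tr2)$rmsf, rmsf_profile(tr1)$rmsf,
               tolerance = 1e-10)
})

test_that("multi-model PDB round-trips through the reader", {
  fx <- static_ca_trajectory(12, 3, seed = 7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(path, fx$coords, fx$atoms)
  tr <- read_trajectory(path)
  expect_equal(dim(tr$coords), c(12, 3, 3))
  expect_equal(tr$coords[, , 2], fx$coords[, , 2], tolerance = 1e-3)
  expect_equal(tr$atoms$resno, fx$atoms$resno)
})

test_that("XYZ trajectories are read with per-atom pseudo-residues", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 1",
               "C 0.0 0.0 0.0", "O 1.2 0.0 0.0", "H 2.0 0.5 0.0",
               "3", "frame 2",
               "C 0.0 0.0 0.1", "O 1.2 0.0 0.1", "H 2.0 0.5 0.1"), path)
  tr <- read_trajectory(path)
  expect_equal(dim(tr$coords), c(3, 3, 2))
  expect_equal(tr$atoms$element, c("C", "O", "H"))
  expect_error(read_trajectory(withr::local_tempfile(fileext = ".dcd")),
               class = "tandemsite_validation_error")
})

test_that("hydrogen-bond frequency counts qualifying frames", {
  # ligand hydroxyl (O-H) near a serine-like acceptor O; geometry satisfied
  # in 5 of 10 frames (ligand moved away in the rest)
  n_frames <- 10
  atoms <- data.frame(
    elety = c("OG", "O1", "H1"),
    resno = c(1, 99, 99), resid = c("SER", "LIG", "LIG"),
    element = c("O", "O", "H"),
    ligand = c(FALSE, TRUE, TRUE))
  coords <- array(0, c(3, 3, n_frames))
  for (f in seq_len(n_frames)) {
    shift <- if (f <= 5) 0 else 10
    coords[1, , f] <- c(0, 0, 0)                 # acceptor
    coords[2, , f] <- c(2.8 + shift, 0, 0)       # donor O
    coords[3, , f] <- c(1.85 + shift, 0, 0)      # H between, angle 180
  }
  prof <- contact_frequency(md_trajectory(coords, atoms),
                            contact_criteria(stack_dist_A = 0))
  expect_equal(prof$hbond_freq[prof$resno == 1], 50)
})

test_that("two simultaneous hydrogen bonds give frequencies above 100", {
  n_frames <- 4
  atoms <- data.frame(
    elety = c("OD1", "OD2", "O1", "H1", "O2", "H2"),
    resno = c(1, 1, 99, 99, 99, 99),
    resid = c("ASP", "ASP", "LIG", "LIG", "LIG", "LIG"),
    element = c("O", "O", "O", "H", "O", "H"),
    ligand = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  coords <- array(0, c(6, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- c(0, 8, 0)
    coords[3, , f] <- c(2.8, 0, 0); coords[4, , f] <- c(1.85, 0, 0)
    coords[5, , f] <- c(2.8, 8, 0); coords[6, , f] <- c(1.85, 8, 0)
  }
  prof <- contact_frequency(md_trajectory(coords, atoms),
                            contact_criteria(stack_dist_A = 0))
  expect_equal(prof$hbond_freq[prof$resno == 1], 200)
})

test_that("ring stacking is detected and zero cutoffs silence everything", {
  n_frames <- 6
  ring_res <- hex_ring(z0 = 0)
  ring_lig <- hex_ring(z0 = 3.5)    # parallel ring 3.5 A above
  atoms <- data.frame(
    elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ",
              paste0("C", 1:6)),
    resno = c(rep(1, 6), rep(99, 6)),
    resid = c(rep("PHE", 6), rep("LIG", 6)),
    element = "C",
    ligand = c(rep(FALSE, 6), rep(TRUE, 6)))
  coords <- array(0, c(12, 3, n_frames))
  for (f in seq_len(n_frames)) {
    off <- if (f <= 3) 0 else 30    # stacked in half the frames
    coords[1:6, , f] <- ring_res
    coords[7:12, , f] <- ring_lig + cbind(rep(off, 6), 0, 0)
  }
  crit <- contact_criteria(ligand_rings = list(paste0("C", 1:6)))
  prof <- contact_frequency(md_trajectory(coords, atoms), crit)
  expect_equal(prof$stack_freq[prof$resno == 1], 50)
  # all-zero cutoffs give all-zero frequencies
  crit0 <- contact_criteria(hbond_dist_A = 0, stack_dist_A = 0,
                            ligand_rings = list(paste0("C", 1:6)))
  prof0 <- contact_frequency(md_trajectory(coords, atoms), crit0)
  expect_equal(prof0$hbond_freq, rep(0, nrow(prof0)))
  expect_equal(prof0$stack_freq, rep(0, nrow(prof0)))
})

test_that("contact frequencies are invariant to frame order", {
  n_frames <- 8
  atoms <- data.frame(
    elety = c("OG", "O1", "H1"),
    resno = c(1, 99, 99), resid = c("SER", "LIG", "LIG"),
    element = c("O", "O", "H"),
    ligand = c(FALSE, TRUE, TRUE))
  set.seed(11)
  coords <- array(0, c(3, 3, n_frames))
  for (f in seq_len(n_frames)) {
    shift <- runif(1, 0, 8)
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- c(2.8 + shift, 0, 0)
    coords[3, , f] <- c(1.85 + shift, 0, 0)
  }
  crit <- contact_criteria(stack_dist_A = 0)
  p1 <- contact_frequency(md_trajectory(coords, atoms), crit)
  p2 <- contact_frequency(md_trajectory(coords[, , n_frames:1], atoms), crit)
  expect_equal(p1$hbond_freq, p2$hbond_freq)
})

test_that("stacking request without ligand rings warns and yields zeros", {
  atoms <- data.frame(
    elety = c("OG", "O1", "H1"),
    resno = c(1, 99, 99), resid = c("SER", "LIG", "LIG"),
    element = c("O", "O", "H"),
    ligand = c(FALSE, TRUE, TRUE))
  coords <- array(rep(c(0, 0, 0, 12, 0, 0, 11, 0, 0), 2), c(3, 3, 2))
  expect_warning(
    prof <- contact_frequency(md_trajectory(coords, atoms),
                              contact_criteria(ligand_rings = list())),
    "no rings")
  expect_equal(prof$stack_freq, 0)
})
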