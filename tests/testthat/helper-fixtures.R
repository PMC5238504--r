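# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# reference rate set used for simulator oracle checks: vestibule exchange
# (1000/min) far faster than translocation (10, 0.3/min), vestibule
# affinity 1 mM, blocking affinity 0.24 mM
oracle_rate_set <- function(leak = 0) {
  rate_set(k_on_vest = 1e6, k_off_vest = 1000, k_in = 10, k_out = 0.3,
           k_on_block = 1e7, k_off_block = 2400, leak = leak)
}

# competitor-free observed rate of the two-step egress (vestibule
# quasi-steady-state closed form)
two_step_k0 <- function(rs) rs$k_out * rs$k_off_vest / (rs$k_off_vest + rs$k_in)

# noise-free mono-exponential time course at rate k
mono_tc <- function(k, t = seq(0, 3 * log(2) / k, length.out = 9)) {
  data.frame(time_min = t, bound_pct = 100 * exp(-k * t))
}

# trajectory of n_static scattered CA atoms (one residue each), well
# spread so rigid-body superposition is well conditioned
static_ca_trajectory <- function(n_static = 80, n_frames = 16, seed = 1) {
  set.seed(seed)
  base <- matrix(runif(n_static * 3, -20, 20), ncol = 3)
  coords <- array(rep(base, n_frames), c(n_static, 3, n_frames))
  atoms <- data.frame(elety = "CA", resno = seq_len(n_static),
                      resid = "ALA", element = "C")
  list(coords = coords, atoms = atoms, base = base)
}

# apply one rotation matrix about z by angle th
rot_z <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)

# minimal multi-model PDB text for read_trajectory tests
write_multimodel_pdb <- function(path, coords, atoms) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(coords)[3])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(nrow(atoms))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, atoms$elety[i], atoms$resid[i], atoms$resno[i],
        coords[i, 1, f], coords[i, 2, f], coords[i, 3, f],
        atoms$element[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# hexagonal ring coordinates (radius 1.39 A, benzene-like) in the z = z0
# plane, centred at (cx, cy)
hex_ring <- function(cx = 0, cy = 0, z0 = 0, r = 1.39) {
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(cx + r * cos(th), cy + r * sin(th), z0)
}
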