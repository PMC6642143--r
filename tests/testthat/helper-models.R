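# Builders for small deterministic fixtures used across the suite.

# one CA pseudo-atom per residue along +x, 1-letter sequence input
peptide_model <- function(seq1, chain = "A", start_number = 1L,
                          spacing = 0.38) {
  aa3 <- toupper(bio3d::aa123(strsplit(seq1, "")[[1]]))
  n <- length(aa3)
  residues <- data.frame(index = seq_len(n), name = aa3, chain = chain,
                         number = start_number + seq_len(n) - 1L,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      res_index = seq_len(n),
                      x = seq_len(n) * spacing, y = 0, z = 0,
                      stringsAsFactors = FALSE)
  structure_model(atoms, residues)
}

# arbitrary point-charge model: each atom its own residue
point_model <- function(positions, element = "C") {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  residues <- data.frame(index = seq_len(n), name = "GLY", chain = "A",
                         number = seq_len(n), stringsAsFactors = FALSE)
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = element,
                      res_index = seq_len(n),
                      x = positions[, 1], y = positions[, 2], z = positions[, 3],
                      stringsAsFactors = FALSE)
  structure_model(atoms, residues)
}

# anisotropic gaussian scaffold grouped into 10-atom residues, plus m
# two-atom dipolar residues (+q/-q separated `sep` nm along y) at given rows
# of `centers`
dipole_probe_model <- function(n_scaffold = 300, centers, q = 0.5, sep = 0.2,
                               seed = 42) {
  set.seed(seed)
  scaff <- cbind(rnorm(n_scaffold, sd = 1.0), rnorm(n_scaffold, sd = 1.6),
                 rnorm(n_scaffold, sd = 2.6))
  m <- nrow(centers)
  probe <- do.call(rbind, lapply(seq_len(m), function(i) {
    rbind(centers[i, ] + c(0, sep / 2, 0), centers[i, ] - c(0, sep / 2, 0))
  }))
  xyz <- rbind(scaff, probe)
  n_res_sc <- ceiling(n_scaffold / 10)
  res_index <- c(rep(seq_len(n_res_sc), each = 10, length.out = n_scaffold),
                 n_res_sc + rep(seq_len(m), each = 2))
  residues <- data.frame(index = seq_len(n_res_sc + m),
                         name = c(rep("ALA", n_res_sc), rep("GLY", m)),
                         chain = "A", number = seq_len(n_res_sc + m),
                         stringsAsFactors = FALSE)
  atoms <- data.frame(serial = seq_len(nrow(xyz)), name = "CA", element = "C",
                      res_index = res_index, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  model <- structure_model(atoms, residues)
  charges <- charge_assignment(c(rep(0, n_scaffold), rep(c(q, -q), m)),
                               mode = "partial")
  list(model = model, charges = charges,
       probe_res = n_res_sc + seq_len(m), n_scaffold = n_scaffold)
}

# rotation matrix about a given axis/angle (independent of package internals)
rot_matrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# small, fast synthetic spec for unit tests
tiny_spec <- function(seed = 1, duration_ns = 2, timestep_ps = 20, ...) {
  synthetic_spec(n_body_atoms = 400L, duration_ns = duration_ns,
                 timestep_ps = timestep_ps, seed = seed, ...)
}

DEBYE <- tubupol::tubupol_constants$debye_per_e_nm

# plain numeric 3-vector from a dipole_vector (drops class and attributes)
as_xyz <- function(mu) as.numeric(unclass(mu))
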