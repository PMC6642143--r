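# Synthetic rigid-rotor-plus-flexible-tail trajectory generator.
#
# The generator is a statistical stand-in for molecular dynamics, not an MD
# engine: a rigid, charged, ellipsoidal atom cloud undergoing overdamped
# rotational Langevin dynamics with field torque, plus a charged linear tail
# whose stretch along the body's medium axis produces a controllable,
# exactly known internal y' polarization with first-order relaxation.

#' Specification for a synthetic protein + trajectory
#'
#' Defaults emulate the tubulin exposure conditions analysed by the
#' pipeline: ellipsoid semi-axes (2.28, 2.65, 4.85) nm, a 30 ns run sampled
#' every 20 ps, a 100 MV/m field along lab z, a 20-residue acidic tail with
#' the beta-tubulin C-terminal sequence (net −11 e), a body charge layout
#' giving a net protein charge of −33 e and a multi-thousand-debye dipole,
#' and a saturating tail polarization calibrated so the imposed internal y'
#' dipolar shift has magnitude `tail_target_polarization_D` (default 40
#' debye) at 100 MV/m.
#'
#' @param semi_axes ellipsoid semi-axes (nm), ascending
#' @param n_body_atoms atoms sampled uniformly in the solid ellipsoid
#' @param atoms_per_residue body atoms grouped into pseudo-residues of this
#'   size
#' @param body_charges matrix with columns x, y, z, q: point charges (e)
#'   placed at the given coordinates *in the body's ellipsoid-axis frame*
#'   (on-axis positions keep the covariance eigenbasis exact)
#' @param tail_sequence one-letter tail sequence; per-residue charges follow
#'   the pH-7 formal rule
#' @param tail_rest_spacing_nm inter-residue spacing of the resting tail
#' @param tail_amplitude_nm maximal tail stretch; if NULL, calibrated so the
#'   imposed y' shift at 100 MV/m equals `tail_target_polarization_D`
#' @param tail_target_polarization_D magnitude (debye) of the imposed tail
#'   polarization at the 100 MV/m calibration field
#' @param tail_half_saturation_MV_m half-saturation field E0 of the
#'   saturating stretch response s_eq(E) = A E / (E + E0)
#' @param tail_relaxation_ns first-order relaxation time of the stretch
#' @param field_MV_m applied field strength (MV/m)
#' @param field_direction lab-frame field direction (default +z)
#' @param rot_diffusion_rad2_ns rotational diffusion coefficient (rad^2/ns)
#' @param temperature_K temperature (K), sets the torque mobility via
#'   Einstein's relation
#' @param duration_ns trajectory length (ns)
#' @param timestep_ps integration/output step (ps)
#' @param drift_nm_ns optional uniform translation drift (nm/ns)
#' @param rot_noise logical: include rotational diffusion noise
#' @param seed RNG seed, recorded in every output
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(semi_axes = c(2.28, 2.65, 4.85),
                           n_body_atoms = 2000L,
                           atoms_per_residue = 10L,
                           body_charges = rbind(c(0,  1.8, 0, -18),
                                                c(0, -1.8, 0,  +2),
                                                c(1.0,  0, 0,  -4),
                                                c(-1.0, 0, 0,  -2)),
                           tail_sequence = "QDATADEQGEFEEEGEEDEA",
                           tail_rest_spacing_nm = 0.15,
                           tail_amplitude_nm = NULL,
                           tail_target_polarization_D = 40,
                           tail_half_saturation_MV_m = 25,
                           tail_relaxation_ns = 1,
                           field_MV_m = 100,
                           field_direction = c(0, 0, 1),
                           rot_diffusion_rad2_ns = 0.02,
                           temperature_K = 300,
                           duration_ns = 30,
                           timestep_ps = 20,
                           drift_nm_ns = c(0, 0, 0),
                           rot_noise = TRUE,
                           seed = 1L) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (duration_ns <= 0 || timestep_ps <= 0) stop("durations must be positive")
  if (timestep_ps >= duration_ns * 1000) stop("timestep must be shorter than duration")
  if (field_MV_m < 0) stop("field magnitude must be non-negative")
  spec <- list(semi_axes = sort(semi_axes), n_body_atoms = as.integer(n_body_atoms),
               atoms_per_residue = as.integer(atoms_per_residue),
               body_charges = body_charges,
               tail_sequence = tail_sequence,
               tail_rest_spacing_nm = tail_rest_spacing_nm,
               tail_amplitude_nm = tail_amplitude_nm,
               tail_target_polarization_D = tail_target_polarization_D,
               tail_half_saturation_MV_m = tail_half_saturation_MV_m,
               tail_relaxation_ns = tail_relaxation_ns,
               field_MV_m = field_MV_m,
               field_direction = field_direction / sqrt(sum(field_direction^2)),
               rot_diffusion_rad2_ns = rot_diffusion_rad2_ns,
               temperature_K = temperature_K,
               duration_ns = duration_ns, timestep_ps = timestep_ps,
               drift_nm_ns = drift_nm_ns, rot_noise = isTRUE(rot_noise),
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# saturating equilibrium stretch (nm) at field E (MV/m)
.s_eq <- function(spec, amplitude, E) {
  if (E <= 0) return(0)
  amplitude * E / (E + spec$tail_half_saturation_MV_m)
}

#' Build a synthetic ellipsoidal protein with a charged tail
#'
#' Samples `n_body_atoms` uniformly in the solid ellipsoid, groups them into
#' pseudo-residues, places the body point charges on the ellipsoid axes of
#' the *sampled* cloud, and appends a linear tail (chain "B") of one atom
#' per residue along the sampled medium axis, anchored just beyond the body
#' surface. Because tail atoms and stretch displacements lie exactly on the
#' medium axis, the combined cloud's covariance eigenbasis equals the body
#' cloud's sample eigenbasis for any stretch, which makes the imposed y'
#' polarization exactly `k * s` with a closed-form coefficient `k` (recorded
#' in the ground truth).
#'
#' @param spec a `synthetic_spec`
#' @return object of class `synthetic_protein`: list with `model`
#'   (`structure_model`; body + charge sites = chain "A", tail = chain "B"),
#'   `charges` (per-atom `charge_assignment`), `truth` (ground-truth list:
#'   seed, body eigenbasis, tail direction/weights, polarization coefficient
#'   `k_D_per_nm`, calibrated amplitude, equilibrium stretch and imposed
#'   shift at the spec field), and `spec`
#' @export
make_ellipsoid_protein <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_body_atoms
  # uniform sampling in the solid ellipsoid
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- stats::runif(n)^(1 / 3)
  body <- sweep(u * rad, 2, spec$semi_axes, `*`)
  # sample eigenbasis of the body cloud (first-frame sign convention)
  bframe <- ellipsoid_frame(geometric_covariance(body))
  V <- bframe$vectors
  # body point charges at on-axis positions given in the eigenbasis
  bc <- spec$body_charges
  q_sites <- bc[, 4]
  site_pos <- bc[, 1:3, drop = FALSE] %*% t(V)
  # tail along the medium axis, one atom per residue
  aa1 <- strsplit(spec$tail_sequence, "")[[1]]
  n_tail <- length(aa1)
  aa3 <- toupper(bio3d::aa123(aa1))
  q_tail <- unname(.formal_rule[aa3])
  q_tail[is.na(q_tail)] <- 0
  w <- seq_len(n_tail) / n_tail
  anchor <- max(body %*% V[, 2]) + spec$tail_rest_spacing_nm
  tail_pos <- outer(anchor + seq_len(n_tail) * spec$tail_rest_spacing_nm,
                    V[, 2])
  # closed-form polarization coefficient: d(mu_y') / d(stretch), debye/nm
  Q_tail <- sum(q_tail)
  k <- (sum(q_tail * w) - Q_tail * mean(w)) * tubupol_constants$debye_per_e_nm
  amplitude <- spec$tail_amplitude_nm
  if (is.null(amplitude)) {
    if (abs(k) < 1e-12) stop("tail charge pattern has no polarization lever; ",
                             "set tail_amplitude_nm explicitly")
    # calibrate so |imposed shift| = target at the 100 MV/m reference field
    s_ref <- spec$tail_target_polarization_D / abs(k)
    amplitude <- s_ref * (100 + spec$tail_half_saturation_MV_m) / 100
  }

  n_sites <- nrow(bc)
  xyz <- rbind(body, site_pos, tail_pos)
  n_atoms <- nrow(xyz)
  n_body_res <- ceiling(n / spec$atoms_per_residue)
  body_res_index <- rep(seq_len(n_body_res), each = spec$atoms_per_residue,
                        length.out = n)
  res_index <- c(body_res_index,
                 n_body_res + seq_len(n_sites),
                 n_body_res + n_sites + seq_len(n_tail))
  residues <- data.frame(
    index = seq_len(n_body_res + n_sites + n_tail),
    name = c(rep("ALA", n_body_res), rep("CHG", n_sites), aa3),
    chain = c(rep("A", n_body_res + n_sites), rep("B", n_tail)),
    number = c(seq_len(n_body_res + n_sites), seq_len(n_tail)),
    stringsAsFactors = FALSE)
  atoms <- data.frame(serial = seq_len(n_atoms), name = "CA", element = "C",
                      res_index = res_index,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  model <- structure_model(atoms, residues)
  q_atom <- c(rep(0, n), q_sites, q_tail)
  charges <- charge_assignment(q_atom, mode = "partial")

  s_eq <- .s_eq(spec, amplitude, spec$field_MV_m)
  truth <- list(seed = spec$seed, body_eigenbasis = V,
                tail_direction = V[, 2], tail_weights = w,
                tail_atom_rows = n + n_sites + seq_len(n_tail),
                k_D_per_nm = k, amplitude_nm = amplitude,
                s_eq_nm = s_eq, imposed_shift_D = k * s_eq,
                total_charge_e = sum(q_atom),
                half_saturation_MV_m = spec$tail_half_saturation_MV_m)
  structure(list(model = model, charges = charges, truth = truth, spec = spec),
            class = "synthetic_protein")
}

#' @export
print.synthetic_protein <- function(x, ...) {
  cat(sprintf(paste0("synthetic_protein: %d atoms (%d tail), total charge ",
                     "%g e, imposed y' shift %.2f D at %g MV/m (seed %d)\n"),
              nrow(x$model$atoms), length(x$truth$tail_weights),
              x$truth$total_charge_e, x$truth$imposed_shift_D,
              x$spec$field_MV_m, x$truth$seed))
  invisible(x)
}

# rotation matrix for a rotation vector (axis * angle, rad)
.rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-15) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Simulate a synthetic trajectory
#'
#' Per-step update with the recorded seed driving all randomness:
#' (i) overdamped rigid-body rotation by the deterministic field torque
#' mu x E (mobility D_r / k_B T via Einstein's relation) plus, optionally,
#' isotropic rotational diffusion noise; (ii) tail stretch s relaxing toward
#' s_eq(E) = A E / (E + E0) with first-order kinetics (integrated exactly
#' over each step); (iii) optional uniform translation drift. The dipole
#' driving the torque is recomputed from the current coordinates about the
#' center of mass each step.
#'
#' @param protein a `synthetic_protein`
#' @param field_MV_m optional field-strength override (MV/m); direction and
#'   all other parameters come from the protein's spec. Use 0 for a
#'   reference (unexposed) run.
#' @param seed optional RNG seed override (defaults to the spec seed)
#' @return object of class `synthetic_simulation`: list with `trajectory`
#'   (a [trajectory()]), `s_trace` (per-frame stretch, nm),
#'   `angle_deg_trace` (angle between the instantaneous dipole and the
#'   field; NA for zero field), `s_eq_nm`, `imposed_shift_D` (= k * mean
#'   last-window s minus 0 for this run), `field_MV_m`, `seed`
#' @export
simulate_trajectory <- function(protein, field_MV_m = NULL, seed = NULL) {
  stopifnot(inherits(protein, "synthetic_protein"))
  spec <- protein$spec
  E_mag <- if (is.null(field_MV_m)) spec$field_MV_m else field_MV_m
  if (E_mag < 0) stop("field magnitude must be non-negative")
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  set.seed(seed)

  X0 <- coords(protein$model)                       # rest coordinates (body frame)
  q <- protein$charges$charges
  m <- .atom_masses(protein$model)
  w_atom <- numeric(nrow(X0))
  w_atom[protein$truth$tail_atom_rows] <- protein$truth$tail_weights
  d_body <- protein$truth$tail_direction
  amplitude <- protein$truth$amplitude_nm
  s_eq <- .s_eq(spec, amplitude, E_mag)

  dt_ns <- spec$timestep_ps / 1000
  n_steps <- round(spec$duration_ns / dt_ns)
  E_lab <- E_mag * spec$field_direction             # MV/m
  kT <- tubupol_constants$boltzmann_J_per_K * spec$temperature_K
  Dr <- spec$rot_diffusion_rad2_ns
  torque_scale <- tubupol_constants$coulomb_m_per_debye * 1e6  # D * MV/m -> J
  decay <- exp(-dt_ns / spec$tail_relaxation_ns)
  sig_noise <- if (spec$rot_noise) sqrt(2 * Dr * dt_ns) else 0

  R <- diag(3); s <- 0; shift <- c(0, 0, 0)
  frames <- vector("list", n_steps + 1L)
  times <- (0:n_steps) * spec$timestep_ps
  s_trace <- numeric(n_steps + 1L)
  angle_trace <- rep(NA_real_, n_steps + 1L)

  lab_frame <- function() {
    body <- X0 + outer(s * w_atom, d_body)
    sweep(body %*% t(R), 2, shift, `+`)
  }
  dipole_lab <- function(lab) {
    com <- drop(crossprod(m, lab)) / sum(m)
    drop(crossprod(q, sweep(lab, 2, com))) * tubupol_constants$debye_per_e_nm
  }

  for (i in 0:n_steps) {
    lab <- lab_frame()
    mu <- dipole_lab(lab)
    if (E_mag > 0)
      angle_trace[i + 1L] <- acos(min(1, max(-1,
        sum(mu * spec$field_direction) / sqrt(sum(mu^2))))) * 180 / pi
    s_trace[i + 1L] <- s
    frames[[i + 1L]] <- lab
    if (i == n_steps) break
    # deterministic torque rotation (overdamped): dtheta = (mu x E) Dr/kT dt
    dth <- c(mu[2] * E_lab[3] - mu[3] * E_lab[2],
             mu[3] * E_lab[1] - mu[1] * E_lab[3],
             mu[1] * E_lab[2] - mu[2] * E_lab[1]) *
           torque_scale * Dr / kT * dt_ns
    if (sqrt(sum(dth^2)) > 0.5)
      stop("unstable step: rotation per step exceeds 0.5 rad; ",
           "reduce timestep_ps or the field strength")
    if (sig_noise > 0) dth <- dth + stats::rnorm(3, sd = sig_noise)
    R <- .rotvec_to_matrix(dth) %*% R
    s <- s_eq + (s - s_eq) * decay
    shift <- shift + spec$drift_nm_ns * dt_ns
  }

  traj <- trajectory(frames, times)
  k <- protein$truth$k_D_per_nm
  idx <- .last_window_frames(traj, min(5, spec$duration_ns / 2))
  structure(list(trajectory = traj, s_trace = s_trace,
                 angle_deg_trace = angle_trace, s_eq_nm = s_eq,
                 imposed_shift_D = k * mean(s_trace[idx]),
                 field_MV_m = E_mag, seed = seed),
            class = "synthetic_simulation")
}

#' @export
print.synthetic_simulation <- function(x, ...) {
  cat(sprintf(paste0("synthetic_simulation: %d frames at %g MV/m, s_eq = %.3f nm,",
                     " imposed y' shift %.2f D (seed %d)\n"),
              n_frames(x$trajectory), x$field_MV_m, x$s_eq_nm,
              x$imposed_shift_D, x$seed))
  invisible(x)
}

#' Write synthetic fixtures to disk
#'
#' Emits a PDB topology, a multi-frame XYZ trajectory, a per-atom charge CSV
#' (`atom_serial,charge`) and a ground-truth JSON holding the full spec, the
#' seed, the polarization coefficient and the per-frame stretch trace —
#' everything needed to re-run the pipeline on files and compare against
#' known truth.
#'
#' @param protein a `synthetic_protein`
#' @param sim a `synthetic_simulation`
#' @param out_dir output directory (created if missing)
#' @return named character vector of the four file paths
#' @export
write_fixtures <- function(protein, sim, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(pdb = file.path(out_dir, "model.pdb"),
             xyz = file.path(out_dir, "trajectory.xyz"),
             charges = file.path(out_dir, "charges.csv"),
             truth = file.path(out_dir, "ground_truth.json"))
  write_structure_pdb(protein$model, paths[["pdb"]])
  write_trajectory_xyz(sim$trajectory, protein$model, paths[["xyz"]])
  utils::write.csv(data.frame(atom_serial = protein$model$atoms$serial,
                              charge = protein$charges$charges),
                   paths[["charges"]], row.names = FALSE)
  spec <- protein$spec
  truth <- protein$truth
  jsonlite::write_json(
    list(seed = truth$seed,
         spec = spec[setdiff(names(spec), "body_charges")],
         body_charges = as.data.frame(spec$body_charges),
         k_D_per_nm = truth$k_D_per_nm,
         amplitude_nm = truth$amplitude_nm,
         field_MV_m = sim$field_MV_m,
         s_eq_nm = sim$s_eq_nm,
         imposed_shift_D = sim$imposed_shift_D,
         s_trace_nm = sim$s_trace,
         time_ps = sim$trajectory$time_ps),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  for (p in paths) if (!file.exists(p) || file.size(p) == 0)
    stop("fixture write failed or produced empty file: ", p)
  paths
}
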