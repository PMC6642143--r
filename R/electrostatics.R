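#' Electric field specification
#'
#' @param field 3-vector in MV/m (lab Cartesian frame), or a scalar magnitude
#'   combined with `direction`.
#' @param direction unit direction (normalised internally) when `field` is a
#'   scalar; default +z, the field axis used in the simulated exposures.
#' @param duration_ns pulse/exposure duration in ns (recorded).
#' @param label run label.
#' @return object of class `field_spec` with `vector` (MV/m), `magnitude`,
#'   `duration_ns`, `label`.
#' @export
field_spec <- function(field, direction = c(0, 0, 1), duration_ns = 30,
                       label = "") {
  if (length(field) == 1L) {
    d <- direction / sqrt(sum(direction^2))
    vec <- as.numeric(field) * d
  } else if (length(field) == 3L) {
    vec <- as.numeric(field)
  } else stop("field must be a magnitude or a 3-vector")
  mag <- sqrt(sum(vec^2))
  if (!is.finite(mag) || mag < 0) stop("invalid field magnitude")
  structure(list(vector = vec, magnitude = mag,
                 duration_ns = duration_ns, label = label),
            class = "field_spec")
}

# mass vector per atom
.atom_masses <- function(model) .element_mass(model$atoms$element)

#' Center of mass of a selection
#' @param model a `structure_model`
#' @param selection a `residue_selection` or NULL (whole model)
#' @return 3-vector in nm
#' @export
center_of_mass <- function(model, selection = NULL) {
  ai <- selection_atom_indices(model, selection)
  m <- .atom_masses(model)[ai]
  drop(crossprod(m, coords(model)[ai, , drop = FALSE])) / sum(m)
}

# charge positions for a selection: per-atom charges at atom coordinates, or
# formal per-residue charges placed at each residue's center of mass
.charge_cloud <- function(model, charges, selection = NULL) {
  if (charges$mode == "partial") {
    if (length(charges$charges) != nrow(model$atoms))
      stop("partial charges not aligned to model atoms")
    ai <- selection_atom_indices(model, selection)
    list(q = charges$charges[ai], r = coords(model)[ai, , drop = FALSE])
  } else {
    if (length(charges$charges) != nrow(model$residues))
      stop("formal charges not aligned to model residues")
    ri <- selection_residue_indices(model, selection)
    xyz <- coords(model)
    m <- .atom_masses(model)
    pos <- t(vapply(ri, function(i) {
      ai <- which(model$atoms$res_index == i)
      drop(crossprod(m[ai], xyz[ai, , drop = FALSE])) / sum(m[ai])
    }, numeric(3)))
    list(q = charges$charges[ri], r = pos)
  }
}

#' Electric dipole moment of a selection
#'
#' Computes mu = sum q_i (r_i − O) over the selection and converts from e.nm
#' to debye (48.0321 D per e.nm). For net-charged selections the dipole is
#' origin-dependent; the origin convention is therefore recorded on the
#' result. Default origin: the selection's center of mass.
#'
#' @param model a `structure_model`
#' @param charges a `charge_assignment`
#' @param selection a `residue_selection` or NULL for the whole model
#' @param origin "com" (center of mass, default), "cog" (center of
#'   geometry) or "fixed"
#' @param origin_point 3-vector in nm, required when `origin = "fixed"`
#' @return object of class `dipole_vector`: named numeric 3-vector (debye)
#'   with attributes `origin_mode`, `origin` (nm) and `label`
#' @export
dipole_moment <- function(model, charges, selection = NULL,
                          origin = c("com", "cog", "fixed"),
                          origin_point = NULL) {
  origin <- match.arg(origin)
  ai <- selection_atom_indices(model, selection)
  if (length(ai) == 0L) stop("empty selection")
  O <- switch(origin,
    com = center_of_mass(model, selection),
    cog = colMeans(coords(model)[ai, , drop = FALSE]),
    fixed = {
      if (is.null(origin_point) || length(origin_point) != 3L)
        stop("origin = 'fixed' requires a 3-vector origin_point")
      as.numeric(origin_point)
    })
  cl <- .charge_cloud(model, charges, selection)
  mu_enm <- drop(crossprod(cl$q, sweep(cl$r, 2, O)))
  mu <- mu_enm * tubupol_constants$debye_per_e_nm
  names(mu) <- c("x", "y", "z")
  structure(mu, class = "dipole_vector", origin_mode = origin, origin = O,
            label = if (is.null(selection)) "all" else attr(selection, "label"))
}

#' Magnitude of a dipole vector
#' @param mu a `dipole_vector` or numeric 3-vector (debye)
#' @return Euclidean norm in debye
#' @export
dipole_magnitude <- function(mu) sqrt(sum(unclass(mu)^2))

#' @export
print.dipole_vector <- function(x, ...) {
  cat(sprintf("dipole_vector [%s, origin=%s]: (%.2f, %.2f, %.2f) D, |mu| = %.2f D\n",
              attr(x, "label"), attr(x, "origin_mode"),
              x[1], x[2], x[3], dipole_magnitude(x)))
  invisible(x)
}

#' Per-residue dipole moments
#'
#' One dipole per residue, each about that residue's own center of mass.
#' This local-origin convention makes dipoles of charged residues
#' well-defined and invariant under translation of the whole structure.
#' Requires per-atom (partial) charges: a residue collapsed to a single
#' formal point charge has no internal dipole.
#'
#' @param model a `structure_model`
#' @param charges a `charge_assignment` with `mode = "partial"`
#' @return data.frame with columns chain, number, resname, mux, muy, muz,
#'   mu (debye, lab frame, local origins)
#' @export
per_residue_dipoles <- function(model, charges) {
  if (charges$mode != "partial")
    stop("per-residue dipoles require per-atom (partial) charges")
  if (length(charges$charges) != nrow(model$atoms))
    stop("charges not aligned to model atoms")
  xyz <- coords(model)
  m <- .atom_masses(model)
  q <- charges$charges
  res <- model$residues
  k <- tubupol_constants$debye_per_e_nm
  out <- t(vapply(res$index, function(i) {
    ai <- which(model$atoms$res_index == i)
    com <- drop(crossprod(m[ai], xyz[ai, , drop = FALSE])) / sum(m[ai])
    drop(crossprod(q[ai], sweep(xyz[ai, , drop = FALSE], 2, com))) * k
  }, numeric(3)))
  data.frame(chain = res$chain, number = res$number, resname = res$name,
             mux = out[, 1], muy = out[, 2], muz = out[, 3],
             mu = sqrt(rowSums(out^2)), stringsAsFactors = FALSE)
}

#' Dipole-field interaction energy
#'
#' U = mu . E, with mu in debye and E in MV/m, returned in joule together
#' with its ratio to thermal energy k_B T. For the tubulin-scale dipole of
#' roughly 2000 debye this ratio crosses 1 just below 1 MV/m at 300 K, which
#' is why fields in the MV/m range and above can beat thermal noise.
#'
#' @param dipole `dipole_vector` or numeric 3-vector (debye)
#' @param field `field_spec` or numeric 3-vector (MV/m)
#' @param temperature_K temperature in kelvin (default 300)
#' @return list with `energy_J` (signed), `kT_J`, and `ratio_kT` =
#'   |U| / (k_B T)
#' @export
field_interaction_energy <- function(dipole, field, temperature_K = 300) {
  if (temperature_K <= 0) stop("temperature must be positive")
  if (inherits(field, "field_spec")) field <- field$vector
  mu_Cm <- unclass(dipole) * tubupol_constants$coulomb_m_per_debye
  E_Vm <- as.numeric(field) * 1e6
  U <- sum(mu_Cm * E_Vm)
  kT <- tubupol_constants$boltzmann_J_per_K * temperature_K
  list(energy_J = U, kT_J = kT, ratio_kT = abs(U) / kT)
}

#' Net charge of a selection
#' @param model a `structure_model`
#' @param charges a `charge_assignment`
#' @param selection a `residue_selection` or NULL (whole model); an empty
#'   selection is allowed and sums to 0
#' @return total charge in e
#' @export
net_charge <- function(model, charges, selection = NULL) {
  if (charges$mode == "partial") {
    ai <- selection_atom_indices(model, selection)
    sum(charges$charges[ai])
  } else {
    ri <- selection_residue_indices(model, selection)
    sum(charges$charges[ri])
  }
}
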