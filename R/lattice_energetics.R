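#' Microtubule-lattice dipole-dipole energy model
#'
#' Energy bookkeeping for a closed (B-type, seam-containing) microtubule
#' lattice: the inter-dimer dipole-dipole contribution is destabilizing and
#' scales with the square of the dimer dipole moment, while all other
#' contributions (solvent-accessible surface area, van der Waals,
#' generalized-Born electrostatics) are lumped into a dipole-independent
#' baseline B. The default calibration — 27 kcal/mol of dipole-dipole energy
#' and a net free energy of −9 kcal/mol at a 4,500 debye dimer dipole —
#' fixes B = −36 kcal/mol.
#'
#' @param mu_ref reference dimer dipole (debye, default 4500)
#' @param e_ref dipole-dipole energy at `mu_ref` (kcal/mol, default 27)
#' @param g_ref net lattice free energy at `mu_ref` (kcal/mol, default −9)
#' @return object of class `lattice_energy_model` with fields `mu_ref`,
#'   `e_ref`, `g_ref`, `baseline` (= g_ref − e_ref)
#' @export
lattice_energy_model <- function(mu_ref = 4500, e_ref = 27, g_ref = -9) {
  if (mu_ref <= 0) stop("mu_ref must be positive")
  structure(list(mu_ref = mu_ref, e_ref = e_ref, g_ref = g_ref,
                 baseline = g_ref - e_ref),
            class = "lattice_energy_model")
}

#' @export
print.lattice_energy_model <- function(x, ...) {
  cat(sprintf(paste0("lattice_energy_model: E_dd(%g D) = %g kcal/mol, ",
                     "G(%g D) = %g kcal/mol (baseline %g)\n"),
              x$mu_ref, x$e_ref, x$mu_ref, x$g_ref, x$baseline))
  invisible(x)
}

#' Dipole-dipole lattice energy at a given dimer dipole
#'
#' E_dd(mu) = e_ref * (mu / mu_ref)^2, i.e. exact quadratic rescaling of the
#' reference calculation.
#'
#' @param model a `lattice_energy_model`
#' @param mu dimer dipole moment(s) in debye, >= 0
#' @return energy in kcal/mol (vectorised over `mu`)
#' @export
dipole_dipole_energy <- function(model, mu) {
  if (any(mu < 0)) stop("dipole magnitude must be non-negative")
  model$e_ref * (mu / model$mu_ref)^2
}

#' Net lattice free energy at a given dimer dipole
#'
#' G(mu) = baseline + E_dd(mu). Negative G classifies the lattice as stable,
#' positive as unstable.
#'
#' @inheritParams dipole_dipole_energy
#' @return numeric vector of free energies (kcal/mol) with attribute
#'   `classification` ("stable"/"unstable"/"marginal")
#' @export
net_free_energy <- function(model, mu) {
  g <- model$baseline + dipole_dipole_energy(model, mu)
  attr(g, "classification") <-
    ifelse(g < 0, "stable", ifelse(g > 0, "unstable", "marginal"))
  g
}

#' Dipole magnitude at which the lattice becomes unstable
#'
#' Solves G(mu*) = 0: mu* = mu_ref * sqrt(−baseline / e_ref). Only defined
#' when the baseline is stabilizing (B < 0) and the dipole term
#' destabilizing (e_ref > 0); with the default calibration mu* is about
#' 5,196 debye.
#'
#' @param model a `lattice_energy_model`
#' @return threshold dipole in debye
#' @export
stability_threshold <- function(model) {
  if (model$baseline > 0)
    stop("no stability root: baseline is already destabilizing (B > 0)")
  if (model$e_ref <= 0 && model$baseline < 0)
    stop("no stability root: dipole term is not destabilizing")
  if (model$baseline == 0) return(0)
  model$mu_ref * sqrt(-model$baseline / model$e_ref)
}
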