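#' Physical constants and unit conversions
#'
#' Conversion factors used throughout the package. All coordinates are stored
#' in nanometres and charges in elementary charges; dipole moments are
#' reported in debye.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{debye_per_e_nm}{48.0321 D per e.nm (CODATA-derived, fixed so
#'     outputs are bit-stable).}
#'   \item{coulomb_per_e}{1.602177e-19 C.}
#'   \item{coulomb_m_per_debye}{3.33564e-30 C.m.}
#'   \item{boltzmann_J_per_K}{1.380649e-23 J/K.}
#' }
#' @export
tubupol_constants <- list(
  debye_per_e_nm     = 48.0321,
  coulomb_per_e      = 1.602177e-19,
  coulomb_m_per_debye = 3.33564e-30,
  boltzmann_J_per_K  = 1.380649e-23
)

# Atomic masses (u) for center-of-mass computations; unknown elements fall
# back to carbon so pseudo-atom models behave as equal-mass clouds.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.990, K = 39.098
)

.element_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- .atomic_masses[["C"]]
  unname(m)
}
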