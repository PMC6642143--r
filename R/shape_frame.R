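#' Geometric covariance matrix of an atom cloud
#'
#' The 3x3 positional covariance C = (1/N) sum (r_l − <r>)(r_l − <r>)^T over
#' the selected atoms, unweighted. Its eigenvectors are the axes of the
#' ellipsoid best fitting the cloud; its eigenvalues are the mean square
#' fluctuations along those axes.
#'
#' @param positions N x 3 matrix of coordinates (nm), or a `structure_model`
#' @param selection optional `residue_selection` when a model is given
#' @return object of class `covariance_matrix`: list with `matrix` (nm^2),
#'   `n`, `center` (mean position, nm)
#' @export
geometric_covariance <- function(positions, selection = NULL) {
  if (inherits(positions, "structure_model"))
    positions <- coords(positions)[selection_atom_indices(positions, selection), ,
                                   drop = FALSE]
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 4L) stop("degenerate geometry: need at least 4 points")
  ctr <- colMeans(positions)
  d <- sweep(positions, 2, ctr)
  C <- crossprod(d) / n
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev, 1e-30))
    stop("degenerate geometry: rank-deficient atom cloud")
  structure(list(matrix = C, n = n, center = ctr), class = "covariance_matrix")
}

#' Ellipsoid frame from a covariance matrix
#'
#' Diagonalises the covariance matrix and returns an orthonormal,
#' right-handed body frame: eigenvectors c1, c2, c3 ordered by ascending
#' eigenvalue, so the internal axes are x' = minor, y' = medium, z' = major.
#' Eigenvector signs are inherently arbitrary; to obtain a frame that evolves
#' continuously along a trajectory, each eigenvector's sign is chosen to
#' maximise its dot product with the corresponding vector of
#' `previous_frame`. For the first frame, signs are fixed so each eigenvector
#' has a positive dot product with the matching lab axis (x, y, z), ties
#' broken toward +z. Handedness is then enforced by flipping the minor axis
#' if det = −1.
#'
#' @param cov a `covariance_matrix` (or plain symmetric 3x3 matrix)
#' @param previous_frame the preceding frame's `ellipsoid_frame`, or NULL
#' @param degeneracy_tol eigenvalue-gap tolerance (nm^2) below which the
#'   frame is ill-conditioned; without a previous frame this triggers a
#'   warning and an arbitrary (but deterministic) split
#' @return object of class `ellipsoid_frame`: `vectors` (3x3, columns
#'   c1..c3), `values` (ascending eigenvalues, nm^2), `center`, `n`
#' @export
ellipsoid_frame <- function(cov, previous_frame = NULL, degeneracy_tol = 1e-6) {
  if (inherits(cov, "covariance_matrix")) {
    C <- cov$matrix; ctr <- cov$center; n <- cov$n
  } else {
    C <- as.matrix(cov); ctr <- c(NA_real_, NA_real_, NA_real_); n <- NA_integer_
  }
  e <- eigen(C, symmetric = TRUE)
  ord <- order(e$values)            # ascending: minor, medium, major
  vals <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  if (min(diff(vals)) < degeneracy_tol && is.null(previous_frame))
    warning("near-degenerate ellipsoid spectrum; frame orientation within ",
            "the degenerate subspace is arbitrary")
  if (!is.null(previous_frame)) {
    P <- previous_frame$vectors
    for (i in 1:3) if (sum(V[, i] * P[, i]) < 0) V[, i] <- -V[, i]
  } else {
    for (i in 1:3) {
      d <- V[i, i]                  # dot with matching lab axis
      if (d < 0) V[, i] <- -V[, i]
      else if (d == 0 && V[3, i] < 0) V[, i] <- -V[, i]  # tie -> +z
    }
  }
  if (det(V) < 0) V[, 1] <- -V[, 1]
  structure(list(vectors = V, values = vals, center = ctr, n = n),
            class = "ellipsoid_frame")
}

#' @export
print.ellipsoid_frame <- function(x, ...) {
  cat(sprintf("ellipsoid_frame: eigenvalues (%.4g, %.4g, %.4g) nm^2\n",
              x$values[1], x$values[2], x$values[3]))
  invisible(x)
}

#' Ellipsoid axis lengths from eigenvalues
#'
#' Maps covariance eigenvalues to ellipsoid dimensions. For points uniformly
#' filling a solid ellipsoid with semi-axis a along an axis, the positional
#' variance along that axis is a^2/5, so the default "uniform-solid"
#' convention reports semi-axes a_i = sqrt(5 lambda_i). Alternatives:
#' "uniform-solid-full" reports full axes 2 a_i, and "shell" reports
#' sqrt(3 lambda_i) (uniform surface shell). The convention used is stamped
#' on the result, since reported protein dimensions depend on it.
#'
#' @param frame an `ellipsoid_frame` (or ascending eigenvalue 3-vector)
#' @param convention one of "uniform-solid", "uniform-solid-full", "shell"
#' @return named numeric (minor, medium, major) in nm with attribute
#'   `convention`
#' @export
axis_lengths <- function(frame, convention = "uniform-solid") {
  vals <- if (inherits(frame, "ellipsoid_frame")) frame$values else sort(as.numeric(frame))
  len <- switch(convention,
    "uniform-solid"      = sqrt(5 * vals),
    "uniform-solid-full" = 2 * sqrt(5 * vals),
    "shell"              = sqrt(3 * vals),
    stop("unknown axis-length convention: ", convention))
  names(len) <- c("minor", "medium", "major")
  attr(len, "convention") <- convention
  len
}

#' Express a lab-frame vector in the internal (body) frame
#'
#' Projects onto the ellipsoid axes: x' = minor-axis component, y' =
#' medium-axis component, z' = major-axis component. Expressing the dipole
#' moment here removes rigid roto-translational motion, leaving genuine
#' internal polarization; the y' component is the one most affected by an
#' applied field in the tubulin system.
#'
#' @param v numeric 3-vector, or an N x 3 matrix of row vectors
#' @param frame an `ellipsoid_frame`
#' @return same shape as `v`, components named/columned x, y, z (primed axes)
#' @export
to_internal <- function(v, frame) {
  V <- frame$vectors
  if (is.matrix(v) && ncol(v) == 3L) {
    out <- v %*% V
    colnames(out) <- c("x", "y", "z")
    return(out)
  }
  out <- drop(crossprod(V, as.numeric(unclass(v))))
  names(out) <- c("x", "y", "z")
  out
}
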