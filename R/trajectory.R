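#' Construct a trajectory
#'
#' A `trajectory` is a sequence of coordinate frames (each an N x 3 matrix in
#' nm) with strictly increasing times in ps. Frames are expected to be
#' whole-molecule (no periodic-boundary wrapping); a guard flags atom jumps
#' larger than `jump_tol` nm between consecutive frames as likely wrapping
#' artifacts.
#'
#' @param frames list of N x 3 coordinate matrices (nm)
#' @param time_ps numeric vector of frame times (ps), strictly increasing
#' @param jump_tol inter-frame displacement (nm) above which a warning is
#'   issued (default 3)
#' @return object of class `trajectory`
#' @export
trajectory <- function(frames, time_ps, jump_tol = 3) {
  if (length(frames) != length(time_ps))
    stop("frames and time_ps lengths differ")
  if (length(frames) == 0L) stop("empty trajectory")
  if (any(diff(time_ps) <= 0)) stop("frame times must be strictly increasing")
  n <- nrow(frames[[1L]])
  for (i in seq_along(frames)) {
    if (!is.matrix(frames[[i]]) || ncol(frames[[i]]) != 3L)
      stop("frame ", i, " is not an N x 3 matrix")
    if (nrow(frames[[i]]) != n)
      stop("atom count changes at frame ", i, " (", nrow(frames[[i]]),
           " vs ", n, ")")
  }
  if (length(frames) > 1L) {
    jump <- vapply(2:length(frames), function(i) {
      sqrt(max(rowSums((frames[[i]] - frames[[i - 1L]])^2)))
    }, 0)
    if (any(jump > jump_tol))
      warning("inter-frame atom jumps up to ", format(max(jump)),
              " nm detected; frames may be PBC-wrapped")
  }
  structure(list(frames = frames, time_ps = as.numeric(time_ps), n_atoms = n),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              length(x$frames), x$n_atoms, x$time_ps[1],
              x$time_ps[length(x$time_ps)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$frames)

#' Replace model coordinates with a trajectory frame
#' @param model a `structure_model`
#' @param frame_coords N x 3 matrix (nm) matching the model's atom count
#' @return the model with updated coordinates
#' @export
set_coords <- function(model, frame_coords) {
  if (nrow(frame_coords) != nrow(model$atoms))
    stop("coordinate frame does not match model atom count")
  model$atoms$x <- frame_coords[, 1]
  model$atoms$y <- frame_coords[, 2]
  model$atoms$z <- frame_coords[, 3]
  model
}

#' Write a trajectory as multi-frame XYZ
#'
#' Plain-text multi-frame XYZ with coordinates in nm; the comment line of
#' each frame records `time_ps= <t> units= nm`. Element symbols are taken
#' from the model.
#'
#' @param traj a `trajectory`
#' @param model the matching `structure_model` (for element symbols)
#' @param path output file
#' @return the path, invisibly
#' @export
write_trajectory_xyz <- function(traj, model, path) {
  el <- model$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame %d time_ps= %.6g units= nm", i, traj$time_ps[i]), con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f",
                       el, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Coordinates are assumed to be in nm unless the comment line carries
#' `units= angstrom`, in which case they are converted. Frame times are read
#' from a `time_ps= <t>` tag on the comment line; without it, frames are
#' numbered 0, 1, 2, ... ps.
#'
#' @param path multi-frame XYZ file
#' @return a `trajectory`
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || i + 1L + n > length(lines))
      stop("unparseable XYZ file at line ", i)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("unparseable XYZ coordinates near line ", i)
    if (grepl("units=\\s*angstrom", comment, ignore.case = TRUE))
      xyz <- xyz / 10
    tm <- regmatches(comment, regexec("time_ps=\\s*([0-9.eE+-]+)", comment))[[1L]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2L]) else length(frames))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames in XYZ file")
  trajectory(frames, times)
}
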