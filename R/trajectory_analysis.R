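# Per-frame pipeline: covariance -> sign-continuous ellipsoid frame ->
# axis lengths and internal-frame dipole components.

# Precompute per-residue atom index lists once per analysis.
.residue_atom_index <- function(model) {
  split(seq_len(nrow(model$atoms)), model$atoms$res_index)
}

# Sign-continuous ellipsoid frames along a trajectory, computed from the
# atoms in `frame_atom_idx` (default: all).
.frame_series <- function(traj, frame_atom_idx = NULL) {
  if (is.null(frame_atom_idx)) frame_atom_idx <- seq_len(traj$n_atoms)
  out <- vector("list", n_frames(traj))
  prev <- NULL
  for (i in seq_len(n_frames(traj))) {
    cov <- geometric_covariance(traj$frames[[i]][frame_atom_idx, , drop = FALSE])
    prev <- ellipsoid_frame(cov, previous_frame = prev)
    out[[i]] <- prev
  }
  out
}

# lab-frame dipole of a fixed atom/charge cloud about its own COM
.cloud_dipole <- function(xyz, q, m) {
  com <- drop(crossprod(m, xyz)) / sum(m)
  drop(crossprod(q, sweep(xyz, 2, com))) * tubupol_constants$debye_per_e_nm
}

#' Shape and dipole observables along a trajectory
#'
#' Runs the full per-frame pipeline: geometric covariance of the protein
#' atom cloud, sign-continuous ellipsoid frame, axis lengths under the
#' requested convention, and the dipole moment of `selection` (about its own
#' center of mass) expressed both in the lab frame and in the internal
#' (body) frame. Expressing the dipole in the internal frame removes rigid
#' roto-translational motion so that the remaining variation is genuine
#' internal polarization.
#'
#' @param traj a `trajectory`
#' @param model the matching `structure_model` (topology/elements)
#' @param charges a `charge_assignment`
#' @param selection `residue_selection` whose dipole is tracked (NULL = whole
#'   model)
#' @param frame_selection `residue_selection` defining the atoms used for the
#'   ellipsoid frame (NULL = all atoms)
#' @param convention axis-length convention, see [axis_lengths()]
#' @return data.frame with one row per frame: `frame`, `time_ps`,
#'   eigenvalues `lambda1..3` (nm^2), axis lengths `minor`, `medium`,
#'   `major` (nm), lab dipole `mux_lab/muy_lab/muz_lab`, internal dipole
#'   `mux/muy/muz`, and `mu_mag` (debye). Attributes record the axis-length
#'   convention and the dipole origin convention.
#' @export
observable_series <- function(traj, model, charges, selection = NULL,
                              frame_selection = NULL,
                              convention = "uniform-solid") {
  if (traj$n_atoms != nrow(model$atoms))
    stop("trajectory does not match model atom count")
  frame_ai <- selection_atom_indices(model, frame_selection)
  frames <- .frame_series(traj, frame_ai)
  m <- .atom_masses(model)
  nf <- n_frames(traj)

  if (charges$mode == "partial") {
    ai <- selection_atom_indices(model, selection)
    q_sel <- charges$charges[ai]
    m_sel <- m[ai]
    dip_of_frame <- function(xyz) .cloud_dipole(xyz[ai, , drop = FALSE], q_sel, m_sel)
  } else {
    ri <- selection_residue_indices(model, selection)
    res_idx <- .residue_atom_index(model)[as.character(ri)]
    q_res <- charges$charges[ri]
    m_res <- lapply(res_idx, function(a) m[a])
    dip_of_frame <- function(xyz) {
      pos <- t(mapply(function(a, mm) drop(crossprod(mm, xyz[a, , drop = FALSE])) / sum(mm),
                      res_idx, m_res))
      mw <- vapply(m_res, sum, 0)
      com <- drop(crossprod(mw, pos)) / sum(mw)
      drop(crossprod(q_res, sweep(pos, 2, com))) * tubupol_constants$debye_per_e_nm
    }
  }

  out <- data.frame(frame = seq_len(nf), time_ps = traj$time_ps,
                    lambda1 = 0, lambda2 = 0, lambda3 = 0,
                    minor = 0, medium = 0, major = 0,
                    mux_lab = 0, muy_lab = 0, muz_lab = 0,
                    mux = 0, muy = 0, muz = 0, mu_mag = 0)
  for (i in seq_len(nf)) {
    fr <- frames[[i]]
    len <- axis_lengths(fr, convention)
    mu_lab <- dip_of_frame(traj$frames[[i]])
    mu_int <- to_internal(mu_lab, fr)
    out[i, 3:5] <- fr$values
    out[i, 6:8] <- len
    out[i, 9:11] <- mu_lab
    out[i, 12:14] <- mu_int
    out$mu_mag[i] <- sqrt(sum(mu_lab^2))
  }
  attr(out, "convention") <- convention
  attr(out, "dipole_origin") <- "com"
  attr(out, "selection") <- if (is.null(selection)) "all" else attr(selection, "label")
  out
}

#' Segment statistics over the last window of a time series
#'
#' Splits the final `window_ns` of a series into `n_segments` equal,
#' non-overlapping segments, reports per-segment means, their grand mean and
#' the sample standard deviation across segment means — the summary used for
#' tabulating mean axis lengths with an uncertainty (default: 5 segments of
#' 1 ns from the last 5 ns). The per-frame standard deviation over the
#' window is also reported for transparency.
#'
#' @param time_ps frame times (ps)
#' @param values observable values, same length
#' @param window_ns analysis window ending at the last frame (default 5)
#' @param n_segments number of segments tiling the window (default 5)
#' @return object of class `segment_stats`: list with `segment_means`,
#'   `mean`, `sd` (across segment means), `sd_frames`, `n_segments`,
#'   `window_ns`
#' @export
segment_stats <- function(time_ps, values, window_ns = 5, n_segments = 5) {
  stopifnot(length(time_ps) == length(values), n_segments >= 2)
  window_ps <- window_ns * 1000
  span <- time_ps[length(time_ps)] - time_ps[1L]
  if (span < window_ps - 1e-9)
    stop("series (", span / 1000, " ns) shorter than requested window (",
         window_ns, " ns)")
  t0 <- time_ps[length(time_ps)] - window_ps
  keep <- time_ps > t0 + 1e-9
  tt <- time_ps[keep]; vv <- values[keep]
  seg <- pmin(pmax(ceiling((tt - t0) / (window_ps / n_segments)), 1L), n_segments)
  seg_means <- as.numeric(tapply(vv, factor(seg, levels = seq_len(n_segments)), mean))
  if (anyNA(seg_means)) stop("a segment contains no frames; series too sparse")
  structure(list(segment_means = seg_means, mean = mean(seg_means),
                 sd = stats::sd(seg_means), sd_frames = stats::sd(vv),
                 n_segments = n_segments, window_ns = window_ns),
            class = "segment_stats")
}

#' @export
print.segment_stats <- function(x, ...) {
  cat(sprintf("segment_stats: mean %.4g +/- %.2g (N = %d segments, %g ns window)\n",
              x$mean, x$sd, x$n_segments, x$window_ns))
  invisible(x)
}

#' Evenly strided samples from the last window of a series
#'
#' Returns exactly `window_ns * 1000 / sampling_ps` samples (250 for the
#' defaults: last 5 ns at 20 ps), taken at the requested stride and ending at
#' the final frame — the sampling used for last-window histograms.
#'
#' @param time_ps frame times (ps), uniformly spaced
#' @param values observable values
#' @param window_ns window length in ns (default 5)
#' @param sampling_ps stride in ps (default 20); must be >= the series' own
#'   sampling interval
#' @return data.frame (time_ps, value) with `window_ns * 1000 / sampling_ps`
#'   rows
#' @export
last_window_samples <- function(time_ps, values, window_ns = 5, sampling_ps = 20) {
  stopifnot(length(time_ps) == length(values))
  n_out <- window_ns * 1000 / sampling_ps
  if (abs(n_out - round(n_out)) > 1e-9)
    stop("window is not an integer multiple of the sampling interval")
  n_out <- as.integer(round(n_out))
  dt <- diff(time_ps)
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    stop("series is not uniformly sampled")
  dt <- dt[1L]
  if (dt > sampling_ps + 1e-9)
    stop("series sampling (", dt, " ps) coarser than requested rate (",
         sampling_ps, " ps)")
  stride <- round(sampling_ps / dt)
  if (abs(stride - sampling_ps / dt) > 1e-6)
    stop("requested sampling is not a multiple of the series interval")
  idx <- seq(length(values), by = -stride, length.out = n_out)
  if (min(idx) < 1L)
    stop("series too short: need ", n_out, " samples at ", sampling_ps,
         " ps ending at the last frame")
  idx <- rev(idx)
  data.frame(time_ps = time_ps[idx], value = values[idx])
}

# per-frame y' internal dipoles for every residue (about each residue's own
# COM), averaged over the frames in `frame_idx`
.mean_residue_yprime <- function(traj, model, charges, frames, frame_idx) {
  if (charges$mode != "partial")
    stop("per-residue dipole analysis requires per-atom (partial) charges")
  res_idx <- .residue_atom_index(model)
  m <- .atom_masses(model)
  q <- charges$charges
  nres <- nrow(model$residues)
  acc <- numeric(nres)
  for (i in frame_idx) {
    xyz <- traj$frames[[i]]
    V <- frames[[i]]$vectors
    y_ax <- V[, 2]                             # medium axis
    for (r in seq_len(nres)) {
      a <- res_idx[[r]]
      com <- drop(crossprod(m[a], xyz[a, , drop = FALSE])) / sum(m[a])
      mu <- drop(crossprod(q[a], sweep(xyz[a, , drop = FALSE], 2, com)))
      acc[r] <- acc[r] + sum(mu * y_ax)
    }
  }
  acc / length(frame_idx) * tubupol_constants$debye_per_e_nm
}

.last_window_frames <- function(traj, window_ns) {
  t_end <- traj$time_ps[n_frames(traj)]
  idx <- which(traj$time_ps > t_end - window_ns * 1000 + 1e-9)
  if (length(idx) < 2L)
    stop("trajectory shorter than the ", window_ns, " ns analysis window")
  idx
}

#' Per-residue dipolar shift between exposed and reference runs
#'
#' For each residue, the mean internal-frame y' dipole component (about the
#' residue's own center of mass) over the last `window_ns` of a field-exposed
#' trajectory minus the same quantity in a reference (unexposed) trajectory.
#' This is the per-residue map used to locate field-sensitive residues.
#'
#' @param traj_exposed,traj_reference `trajectory` objects sharing the
#'   model's topology
#' @param model the `structure_model`
#' @param charges per-atom `charge_assignment`
#' @param window_ns averaging window at the end of each run (default 5)
#' @return data.frame (chain, number, resname, mean_exposed, mean_reference,
#'   shift), shifts in debye
#' @export
residue_dipole_shift <- function(traj_exposed, traj_reference, model, charges,
                                 window_ns = 5) {
  if (traj_exposed$n_atoms != nrow(model$atoms) ||
      traj_reference$n_atoms != nrow(model$atoms))
    stop("topology mismatch between trajectories and model")
  mean_y <- function(traj) {
    frames <- .frame_series(traj)
    idx <- .last_window_frames(traj, window_ns)
    .mean_residue_yprime(traj, model, charges, frames, idx)
  }
  ye <- mean_y(traj_exposed)
  yr <- mean_y(traj_reference)
  res <- model$residues
  data.frame(chain = res$chain, number = res$number, resname = res$name,
             mean_exposed = ye, mean_reference = yr, shift = ye - yr,
             stringsAsFactors = FALSE)
}

#' Residues whose dipolar shift exceeds a threshold
#'
#' @param shift_table output of [residue_dipole_shift()]
#' @param threshold_D absolute shift threshold in debye (default 5)
#' @return list with `count` (total), `per_chain` (named counts) and
#'   `residues` (the exceeding rows)
#' @export
count_exceeding <- function(shift_table, threshold_D = 5) {
  if (nrow(shift_table) == 0L) stop("empty shift table")
  hit <- abs(shift_table$shift) > threshold_D
  rows <- shift_table[hit, , drop = FALSE]
  per_chain <- table(factor(rows$chain, levels = unique(shift_table$chain)))
  list(count = sum(hit), per_chain = c(per_chain), residues = rows)
}

#' Coil counts of a selection along a trajectory
#'
#' Consumes an externally produced per-frame secondary-structure label table
#' (DSSP-style letters; "C" = coil) and counts, per frame, how many residues
#' of the selection are in coil. Optionally applies a centered moving
#' average for plotting (smoothing width in frames).
#'
#' @param ss_labels data.frame with columns `frame`, `chain`, `resnum`,
#'   `label`
#' @param selection a `residue_selection` (plain chain/number data.frame
#'   accepted)
#' @param smooth_width moving-average width in frames (NULL = none)
#' @param coil_labels labels counted as coil (default "C")
#' @return data.frame (frame, count[, smoothed])
#' @export
coil_count_series <- function(ss_labels, selection, smooth_width = NULL,
                              coil_labels = "C") {
  need <- c("frame", "chain", "resnum", "label")
  if (!all(need %in% names(ss_labels)))
    stop("ss_labels must have columns: ", paste(need, collapse = ", "))
  sel_key <- paste(selection$chain, selection$number)
  lab_key <- paste(ss_labels$chain, ss_labels$resnum)
  missing <- setdiff(sel_key, lab_key)
  if (length(missing) > 0L)
    stop("selection residues absent from label table: ",
         paste(missing, collapse = ", "))
  keep <- lab_key %in% sel_key
  sub <- ss_labels[keep, , drop = FALSE]
  frames <- sort(unique(ss_labels$frame))
  is_coil <- sub$label %in% coil_labels
  cnt <- vapply(frames, function(f) sum(is_coil[sub$frame == f]), 0L)
  out <- data.frame(frame = frames, count = cnt)
  if (!is.null(smooth_width)) {
    w <- as.integer(smooth_width)
    out$smoothed <- as.numeric(stats::filter(out$count, rep(1 / w, w), sides = 2))
  }
  out
}

#' Last-window dipole report for named sites
#'
#' For each site (a `residue_selection`), collects the last-window
#' distribution of the internal-frame y' dipole component for every member
#' residue (about its own center of mass) and for the site selection as a
#' whole (about the site's center of mass).
#'
#' @param traj a `trajectory`
#' @param model the `structure_model`
#' @param charges per-atom `charge_assignment`
#' @param sites named list of `residue_selection`s (e.g. from
#'   [load_site_definitions()])
#' @param window_ns analysis window (default 5)
#' @param run_label label stamped on every row (e.g. "E=100 MV/m")
#' @return data.frame (run, site, unit, chain, number, mean_y, sd_y, n);
#'   `unit` is "residue" or "site". The raw per-frame samples are attached
#'   as attribute `samples` (a named list of numeric vectors) for histogram
#'   plotting.
#' @export
site_dipole_report <- function(traj, model, charges, sites, window_ns = 5,
                               run_label = "") {
  if (charges$mode != "partial")
    stop("site dipole report requires per-atom (partial) charges")
  frames <- .frame_series(traj)
  idx <- .last_window_frames(traj, window_ns)
  m <- .atom_masses(model)
  q <- charges$charges
  res_idx <- .residue_atom_index(model)
  rows <- list(); samples <- list()
  for (site_name in names(sites)) {
    site <- sites[[site_name]]
    ri <- selection_residue_indices(model, site)
    ai <- selection_atom_indices(model, site)
    # member residues
    for (k in seq_along(ri)) {
      a <- res_idx[[as.character(ri[k])]]
      ys <- vapply(idx, function(i) {
        mu <- .cloud_dipole(traj$frames[[i]][a, , drop = FALSE], q[a], m[a])
        sum(mu * frames[[i]]$vectors[, 2])
      }, 0)
      key <- paste0(site_name, "/", site$chain[k], site$number[k])
      samples[[key]] <- ys
      rows[[length(rows) + 1L]] <- data.frame(
        run = run_label, site = site_name, unit = "residue",
        chain = site$chain[k], number = site$number[k],
        mean_y = mean(ys), sd_y = stats::sd(ys), n = length(ys),
        stringsAsFactors = FALSE)
    }
    # whole site
    ys <- vapply(idx, function(i) {
      mu <- .cloud_dipole(traj$frames[[i]][ai, , drop = FALSE], q[ai], m[ai])
      sum(mu * frames[[i]]$vectors[, 2])
    }, 0)
    samples[[paste0(site_name, "/site")]] <- ys
    rows[[length(rows) + 1L]] <- data.frame(
      run = run_label, site = site_name, unit = "site", chain = NA,
      number = NA, mean_y = mean(ys), sd_y = stats::sd(ys), n = length(ys),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "samples") <- samples
  out
}
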