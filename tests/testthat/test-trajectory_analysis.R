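test_that("a repeated static frame yields a constant series", {
  p <- make_ellipsoid_protein(tiny_spec(seed = 4))
  fr <- coords(p$model)
  tr <- trajectory(replicate(10, fr, simplify = FALSE), (0:9) * 20)
  s <- observable_series(tr, p$model, p$charges)
  for (col in c("lambda2", "medium", "mux", "muy", "muz"))
    expect_equal(diff(range(s[[col]])), 0)
  expect_equal(attr(s, "convention"), "uniform-solid")
  expect_equal(attr(s, "dipole_origin"), "com")
})

test_that("rigid rotational diffusion leaves internal dipole components constant", {
  # lab dipole must vary while the internal components stay fixed: the
  # defining property of the body-frame transformation
  p <- make_ellipsoid_protein(tiny_spec(seed = 5, duration_ns = 2))
  sim <- simulate_trajectory(p, field_MV_m = 0)   # noise on, no field, no stretch
  s <- observable_series(sim$trajectory, p$model, p$charges)
  expect_gt(diff(range(s$muz_lab)), 1)            # body tumbles in the lab
  expect_lt(diff(range(s$mux)), 1e-6)
  expect_lt(diff(range(s$muy)), 1e-6)
  expect_lt(diff(range(s$muz)), 1e-6)
})

test_that("a slow polarization ramp is recovered with its imposed slope", {
  # relaxation much longer than the run: s(t) ~ s_eq * t / tau, so the y'
  # series is a ramp of slope k * s_eq / tau
  p <- make_ellipsoid_protein(tiny_spec(seed = 6, duration_ns = 2,
                                        tail_relaxation_ns = 100,
                                        rot_noise = FALSE))
  sim <- simulate_trajectory(p)
  ctt <- select_ctt(p$model, "B")
  s <- observable_series(sim$trajectory, p$model, p$charges, selection = ctt)
  fit <- stats::lm(muy ~ time_ps, data = s)
  slope_ns <- unname(stats::coef(fit)[2]) * 1000
  expected <- p$truth$k_D_per_nm * sim$s_eq_nm / 100
  expect_equal(slope_ns, expected, tolerance = 0.02)
})

test_that("segment statistics reproduce hand-computed means and handle errors", {
  # 5 segments with means 1..5 -> mean 3, sample sd sqrt(2.5)
  t_ps <- seq(20, 5000, by = 20)
  v <- rep(1:5, each = 50)
  st <- segment_stats(c(0, t_ps), c(1, v))
  expect_equal(st$segment_means, 1:5)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sqrt(2.5), tolerance = 1e-12)
  # constant series
  stc <- segment_stats(c(0, t_ps), rep(7, 251))
  expect_equal(stc$mean, 7)
  expect_equal(stc$sd, 0)
  expect_error(segment_stats((0:50) * 20, rnorm(51)), "shorter")
  # linearity under scaling
  st2 <- segment_stats(c(0, t_ps), 3 * c(1, v))
  expect_equal(st2$mean, 3 * st$mean)
  expect_equal(st2$sd, 3 * st$sd)
})

test_that("last-window sampling returns exactly window/stride samples", {
  t30 <- seq(0, 30000, by = 20)                    # 30 ns at 20 ps
  s <- last_window_samples(t30, seq_along(t30))
  expect_equal(nrow(s), 250L)
  expect_equal(s$time_ps[250], 30000)
  expect_equal(diff(s$time_ps)[1], 20)
  t5 <- seq(0, 5000, by = 20)                      # whole 5 ns series
  expect_equal(nrow(last_window_samples(t5, seq_along(t5))), 250L)
  t1 <- seq(0, 1000, by = 20)
  expect_error(last_window_samples(t1, seq_along(t1)), "too short")
  # finer series is re-strided
  t_fine <- seq(0, 30000, by = 10)
  sf <- last_window_samples(t_fine, seq_along(t_fine))
  expect_equal(nrow(sf), 250L)
  expect_equal(diff(sf$time_ps)[1], 20)
})

test_that("per-residue dipolar shifts localize an imposed offset", {
  set.seed(20)
  centers <- matrix(rnorm(30, sd = 2), ncol = 3)   # 10 probe residues
  pm <- dipole_probe_model(n_scaffold = 300, centers = centers)
  ref <- coords(pm$model)
  fr <- ellipsoid_frame(geometric_covariance(ref))
  y_ax <- fr$vectors[, 2]
  tagged <- pm$probe_res[1:5]
  dd <- 7 / (0.5 * DEBYE)                          # displacement for +7 D
  exposed <- ref
  for (r in tagged) {
    plus_atom <- which(pm$model$atoms$res_index == r)[1]   # the +q atom
    exposed[plus_atom, ] <- exposed[plus_atom, ] + dd * y_ax
  }
  times <- c(0, 2500, 5000)
  tr_ref <- trajectory(list(ref, ref, ref), times)
  tr_exp <- trajectory(list(exposed, exposed, exposed), times)
  tab <- residue_dipole_shift(tr_exp, tr_ref, pm$model, pm$charges)
  tag_rows <- match(tagged, seq_len(nrow(tab)))
  expect_equal(tab$shift[tag_rows], rep(7, 5), tolerance = 0.03)
  expect_lt(max(abs(tab$shift[-tag_rows])), 0.2)
  # antisymmetry under swapping the runs
  tab_swap <- residue_dipole_shift(tr_ref, tr_exp, pm$model, pm$charges)
  expect_equal(tab_swap$shift, -tab$shift, tolerance = 1e-9)
  # identical runs -> all zero
  tab0 <- residue_dipole_shift(tr_ref, tr_ref, pm$model, pm$charges)
  expect_equal(max(abs(tab0$shift)), 0)
  # exceedance bookkeeping
  exc <- count_exceeding(tab, threshold_D = 5)
  expect_equal(exc$count, 5L)
  expect_equal(nrow(exc$residues), 5L)
  expect_equal(count_exceeding(tab0)$count, 0L)
  all_nonzero <- count_exceeding(tab, threshold_D = 0)
  expect_gte(all_nonzero$count, 5L)
})

test_that("coil counts follow the label table and smoothing midpoints", {
  sel <- data.frame(chain = "B", number = 1:3)
  grid <- expand.grid(frame = 1:4, resnum = 1:3)
  labs <- data.frame(frame = grid$frame, chain = "B", resnum = grid$resnum,
                     label = ifelse(grid$frame %% 2 == 1, "C", "H"))
  cc <- coil_count_series(labs, sel)
  expect_equal(cc$count, c(3L, 0L, 3L, 0L))
  sm <- coil_count_series(labs, sel, smooth_width = 2)
  expect_equal(sm$smoothed[1:3], rep(1.5, 3))
  all_coil <- transform(labs, label = "C")
  expect_equal(coil_count_series(all_coil, sel)$count, rep(3L, 4))
  no_coil <- transform(labs, label = "H")
  expect_equal(coil_count_series(no_coil, sel)$count, rep(0L, 4))
  bad_sel <- data.frame(chain = "B", number = 99)
  expect_error(coil_count_series(labs, bad_sel), "absent")
})

test_that("site dipole reports match single-residue statistics and offsets", {
  set.seed(21)
  centers <- matrix(rnorm(12, sd = 2), ncol = 3)
  pm <- dipole_probe_model(n_scaffold = 300, centers = centers)
  ref <- coords(pm$model)
  fr <- ellipsoid_frame(geometric_covariance(ref))
  y_ax <- fr$vectors[, 2]
  target_res <- pm$probe_res[1]
  dd <- 7 / (0.5 * DEBYE)
  exposed <- ref
  plus_atom <- which(pm$model$atoms$res_index == target_res)[1]
  exposed[plus_atom, ] <- exposed[plus_atom, ] + dd * y_ax
  times <- c(0, 2500, 5000)
  tr_ref <- trajectory(list(ref, ref, ref), times)
  tr_exp <- trajectory(list(exposed, exposed, exposed), times)
  num <- pm$model$residues$number[target_res]
  sites <- list(
    target = residue_selection(pm$model, "A", num, label = "target"),
    other = residue_selection(pm$model, "A",
                              pm$model$residues$number[pm$probe_res[3:4]],
                              label = "other"))
  rep_ref <- site_dipole_report(tr_ref, pm$model, pm$charges, sites,
                                run_label = "E=0")
  rep_exp <- site_dipole_report(tr_exp, pm$model, pm$charges, sites,
                                run_label = "E=100")
  # single-residue site: the "site" row equals the residue row
  tgt_ref <- rep_ref[rep_ref$site == "target", ]
  expect_equal(tgt_ref$mean_y[tgt_ref$unit == "site"],
               tgt_ref$mean_y[tgt_ref$unit == "residue"], tolerance = 1e-9)
  # imposed offset appears in the report within 5%
  tgt_exp <- rep_exp[rep_exp$site == "target" & rep_exp$unit == "site", ]
  shift <- tgt_exp$mean_y - tgt_ref$mean_y[tgt_ref$unit == "site"][1]
  expect_equal(shift, 7, tolerance = 0.05)
  # disjoint sites are unaffected
  oth <- rep_exp[rep_exp$site == "other" & rep_exp$unit == "site", "mean_y"] -
         rep_ref[rep_ref$site == "other" & rep_ref$unit == "site", "mean_y"]
  expect_lt(abs(oth), 0.2)
  expect_true(all(c("samples") %in% names(attributes(rep_ref))))
})
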