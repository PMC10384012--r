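test_that("solver agrees with the dense-sampling oracle on random probes", {
  geom <- default_geom()
  proc <- default_proc()
  T_rev <- 2 * pi / proc$omega
  set.seed(101)
  for (vib in list(conv_vib(), osc_vib())) {
    tq <- runif(15, 1.2 * T_rev, 3 * T_rev)
    jq <- sample(0:1, 15, replace = TRUE)
    for (i in seq_along(tq)) {
      hs <- chip_thickness_at(tq[i], jq[i], geom, vib, proc)$h
      ho <- oracle_thickness(tq[i], jq[i], geom, vib, proc)
      if (is.na(ho)) ho <- 0
      expect_lt(abs(hs - ho), 1e-4 * proc$fz)
    }
  }
})

test_that("collinearity residual vanishes at the matched prior point", {
  geom <- cutter_geometry(runout_um = 0)
  vib <- conv_vib()
  proc <- default_proc()
  T_rev <- 2 * pi / proc$omega
  t <- 1.25 * T_rev # theta = pi/2 for tooth 0
  expect_equal(collinearity_residual(t, t, 0, 0, geom, vib, proc), 0)

  ts <- solve_previous_time(t, 0, "previous-tooth", geom, vib, proc)
  expect_false(is.na(ts))
  expect_lt(abs(collinearity_residual(t, ts, 0, -1, geom, vib, proc)), 1e-9)
  # residual changes sign across the root
  eps <- 1e-5
  r1 <- collinearity_residual(t, ts - eps, 0, -1, geom, vib, proc)
  r2 <- collinearity_residual(t, ts + eps, 0, -1, geom, vib, proc)
  expect_lt(r1 * r2, 0)
  # matched time sits near one tooth period earlier
  T_tooth <- T_rev / geom$n_flutes
  expect_lt(abs((t - ts) - T_tooth), 0.05 * T_tooth)
})

test_that("conventional milling recovers the classical thickness law", {
  geom <- cutter_geometry(runout_um = 0)
  proc <- default_proc()
  prof <- thickness_profile(geom, conv_vib(), proc, n_revolutions = 3, dt = 2e-5)
  ss <- prof[prof$revolution >= 2 & prof$case_tag != "not-engaged", ]
  h_classical <- proc$fz * sin(ss$theta %% (2 * pi))
  # the exact trochoid exceeds the sinusoid by up to ~1.1 fz^2/(2r)
  # (the successive-pass correction, largest towards the arc ends)
  expect_lt(max(abs(ss$h - h_classical)), 1.25 * proc$fz^2 / (2 * geom$r))
  # at the thickest point the classical law holds to better than 1 %
  mid <- abs((ss$theta %% (2 * pi)) - pi / 2) < 0.1
  expect_lt(max(abs(ss$h[mid] - h_classical[mid])), 0.01 * proc$fz)
  # entry limit: negligible thickness as theta -> 0
  entry <- ss[(ss$theta %% (2 * pi)) < 0.02, ]
  expect_true(all(entry$h <= 0.05 * proc$fz))
  # a zero-feed cut removes nothing
  proc0 <- process_params(feed_per_tooth_um = 0)
  prof0 <- thickness_profile(geom, conv_vib(), proc0, n_revolutions = 2, dt = 1e-4)
  expect_true(all(prof0$h[prof0$revolution >= 2] < 1e-12))
})

test_that("vibration produces intermittent cutting with ~30 thickness cycles", {
  geom <- default_geom()
  proc <- default_proc()
  prof <- thickness_profile(geom, osc_vib(), proc, n_revolutions = 3)
  ss <- prof[prof$revolution == 2 & prof$tooth == 0, ]
  arc <- ss[(ss$theta %% (2 * pi)) <= pi, ]
  # separation: some engaged samples carry zero thickness
  expect_gt(sum(arc$h == 0), 0)
  expect_true(any(arc$case_tag %in% c("empty-different-tooth", "empty-same-tooth")))
  # oscillation at the vibration/tooth-passing ratio: 3000 Hz over a
  # 0.01 s engagement arc = 30 cycles; count interior local maxima
  h <- arc$h
  n <- length(h)
  peaks <- which(h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n] &
                   h[2:(n - 1)] > 0)
  expect_gte(length(peaks), 20)
})

test_that("runout splits the teeth into long and short cutters", {
  proc <- default_proc()
  vib <- conv_vib()
  geom_r <- cutter_geometry(runout_um = 2)
  prof <- thickness_profile(geom_r, vib, proc, n_revolutions = 3, dt = 5e-5)
  ss <- prof[prof$revolution >= 2, ]
  pk <- tapply(ss$h, ss$tooth, max)
  expect_gt(abs(pk[["0"]] - pk[["1"]]), 1e-7) # > 0.1 um split
  # the long-tooth peak matches the oracle at the observed peak instant
  i_pk <- which.max(ss$h)
  ho <- oracle_thickness(ss$t[i_pk], ss$tooth[i_pk], geom_r, vib, proc)
  expect_lt(abs(ss$h[i_pk] - ho), 0.01 * max(ss$h))

  geom_0 <- cutter_geometry(runout_um = 0)
  prof0 <- thickness_profile(geom_0, vib, proc, n_revolutions = 3, dt = 5e-5)
  s0 <- prof0[prof0$revolution >= 2 & prof0$tooth == 0, ]
  s1 <- prof0[prof0$revolution >= 2 & prof0$tooth == 1, ]
  # without runout the teeth are interchangeable: peaks agree to solver
  # precision, and the half-revolution-aligned profiles match away from the
  # engagement boundary (where a one-ulp angle difference can flip the
  # engaged classification of a single sample)
  expect_lt(abs(max(s0$h) - max(s1$h)), 1e-10)
  T_tooth <- 2 * pi / (proc$omega * geom_0$n_flutes)
  h1 <- stats::approx(s1$t, s1$h, xout = s0$t + T_tooth)$y
  thm0 <- s0$theta %% (2 * pi)
  keep <- !is.na(h1) & thm0 > 1e-3 & thm0 < pi - 1e-3
  expect_lt(max(abs(s0$h[keep] - h1[keep])), 1e-10)
})

test_that("thickness samples are nonnegative, bounded and well-tagged", {
  geom <- default_geom()
  proc <- default_proc()
  prof <- thickness_profile(geom, osc_vib(), proc, n_revolutions = 3)
  expect_true(all(prof$h >= 0))
  bound <- 2 * proc$fz + 2 * max(2e-6, 2e-6) + 2 * geom$r0 + 1e-6
  expect_true(all(prof$h <= bound))
  expect_true(all(prof$case_tag %in% c(
    "chip-different-tooth", "empty-different-tooth",
    "chip-same-tooth", "empty-same-tooth", "not-engaged"
  )))
  expect_true(all(prof$h[prof$case_tag %in%
    c("empty-different-tooth", "empty-same-tooth", "not-engaged")] == 0))
  # both the different-tooth and same-tooth chip cases occur under vibration
  expect_gt(sum(prof$case_tag == "chip-different-tooth"), 0)
  expect_error(thickness_profile(geom, conv_vib(), proc, n_revolutions = 1),
               class = "osteomill_invalid_input")
})

test_that("removed cross-section balances the feed, vibration on or off", {
  geom <- default_geom()
  proc <- default_proc()
  target <- geom$n_flutes * proc$fz * 2 * geom$r
  prof_c <- thickness_profile(geom, conv_vib(), proc, n_revolutions = 6, dt = 5e-5)
  expect_equal(removed_area_per_rev(prof_c, geom, proc) / target, 1, tolerance = 0.02)
  prof_v <- thickness_profile(geom, osc_vib(), proc, n_revolutions = 6)
  expect_equal(removed_area_per_rev(prof_v, geom, proc) / target, 1, tolerance = 0.02)
})

test_that("thickness CSV export is in display units", {
  geom <- default_geom()
  proc <- default_proc()
  prof <- thickness_profile(geom, conv_vib(), proc, n_revolutions = 2, dt = 2e-4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thickness_csv(prof, path)
  back <- utils::read.csv(path)
  expect_named(back, c("t_s_s", "tooth", "theta_deg", "h_um", "case_tag",
                       "t_match_s"))
  expect_equal(max(back$h_um), max(prof$h) * 1e6, tolerance = 1e-9)
})
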