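test_that("shear angle follows the Merchant-type relation", {
  g5 <- 5 * pi / 180
  expect_equal(shear_angle(g5, g5), pi / 4)
  # from the default friction coefficients (direct arithmetic oracle)
  expect_equal(shear_angle(friction_angle(0.82), g5), 27.8241 * pi / 180, tolerance = 1e-5)
  expect_equal(shear_angle(friction_angle(0.98), g5), 25.2894 * pi / 180, tolerance = 1e-5)
  expect_equal(shear_angle(friction_angle(0.82), g5),
               pi / 4 - (atan(0.82) - g5) / 2, tolerance = 1e-14)
  expect_error(shear_angle(1.8, 0), class = "osteomill_invalid_input")
})

test_that("shear coefficients match a term-by-term reference evaluation", {
  mat <- bone_material()
  geom <- default_geom()
  for (i in 1:3) {
    for (with_sqrt in c(TRUE, FALSE)) {
      got <- shear_coefficients(mat, geom, i, armarego_sqrt = with_sqrt)
      want <- oracle_shear_coeffs(shear_strength(mat, i), friction_coefficient(mat, i),
                                  geom$gamma_n, geom$lambda, with_sqrt = with_sqrt)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # the two denominator conventions genuinely differ
  expect_false(isTRUE(all.equal(
    shear_coefficients(mat, geom, 1, armarego_sqrt = TRUE),
    shear_coefficients(mat, geom, 1, armarego_sqrt = FALSE)
  )))
  # vertical-to-parallel ratio reproduced by the independent evaluation
  # (friction differs per direction, so this is not just the strength ratio)
  r_pkg <- shear_coefficients(mat, geom, 3)[["Ktc"]] /
    shear_coefficients(mat, geom, 1)[["Ktc"]]
  r_ora <- oracle_shear_coeffs(180.12e6, 0.85, geom$gamma_n, geom$lambda)[["Ktc"]] /
    oracle_shear_coeffs(81.03e6, 0.82, geom$gamma_n, geom$lambda)[["Ktc"]]
  expect_equal(r_pkg, r_ora, tolerance = 1e-12)
})

test_that("zero-inclination limit reduces to orthogonal cutting", {
  mat <- bone_material()
  geom <- cutter_geometry(helix_deg = 1e-9 * 180 / pi)
  k <- shear_coefficients(mat, geom, 1)
  tau <- shear_strength(mat, 1)
  beta <- friction_angle(friction_coefficient(mat, 1))
  phi <- shear_angle(beta, geom$gamma_n)
  ktc_ortho <- tau * cos(beta - geom$gamma_n) / (sin(phi) * cos(phi + beta - geom$gamma_n))
  expect_equal(k[["Ktc"]], ktc_ortho, tolerance = 1e-6)
  expect_lt(abs(k[["Kac"]]) / k[["Ktc"]], 1e-6)
})

test_that("all coefficients are homogeneous of degree one in shear strength", {
  geom <- default_geom()
  m1 <- bone_material()
  m2 <- bone_material(tau_s_MPa = 2 * c(81.03, 94.48, 180.12))
  expect_equal(shear_coefficients(m2, geom, 2), 2 * shear_coefficients(m1, geom, 2),
               tolerance = 1e-14)
  h <- c(1e-6, 5e-6, 2e-5)
  p1 <- ploughing_coefficients(m1, geom, 2, h)
  p2 <- ploughing_coefficients(m2, geom, 2, h)
  expect_equal(p2$Ktp, 2 * p1$Ktp, tolerance = 1e-14)
  expect_equal(p2$Krp, 2 * p1$Krp, tolerance = 1e-14)
})

test_that("equivalent rake angle hits its exact anchors and is continuous", {
  geom <- default_geom()
  re <- geom$re
  expect_equal(equivalent_rake_angle(0, geom), -pi / 2)
  expect_equal(equivalent_rake_angle(re, geom), 0)
  h_star <- re * (1 + sin(geom$gamma_n))
  # both branches agree at the changeover: acos(-sin g) - pi/2 == g
  expect_equal(equivalent_rake_angle(h_star, geom), geom$gamma_n, tolerance = 1e-12)
  expect_equal(equivalent_rake_angle(h_star * (1 + 1e-12), geom), geom$gamma_n)

  # continuity: arccos has a square-root modulus at h = 0, so the grid jump
  # is bounded by sqrt(2 dh / re) there; no other discontinuity exists
  h <- seq(0, 2 * h_star, length.out = 4001)
  ge <- equivalent_rake_angle(h, geom)
  dh <- h[2] - h[1]
  expect_lt(max(abs(diff(ge))), 1.2 * sqrt(2 * dh / re))
  # branch point itself is smooth: the arccos form equals the nominal rake
  # exactly at the changeover, and an infinitesimal step leaves no jump
  eps <- 1e-15
  expect_lt(abs(equivalent_rake_angle(h_star - eps, geom) -
                  equivalent_rake_angle(h_star + eps, geom)), 1e-9)
  expect_error(equivalent_rake_angle(-1e-9, geom), class = "osteomill_invalid_input")
})

test_that("ploughing coefficients match the slip-line reference evaluation", {
  mat <- bone_material()
  geom <- default_geom()
  h <- c(0, 1e-6, 3e-6, 5e-6, 5.4358e-6, 1e-5)
  for (i in 1:3) {
    got <- ploughing_coefficients(mat, geom, i, h)
    want <- vapply(h, function(hh) {
      oracle_plough_coeffs(shear_strength(mat, i), friction_coefficient(mat, i),
                           geom$re, geom$gamma_n, hh)
    }, numeric(2))
    expect_equal(got$Ktp, unname(want["Ktp", ]), tolerance = 1e-12)
    expect_equal(got$Krp, unname(want["Krp", ]), tolerance = 1e-12)
  }
  # above the blunt-circle regime the rake is nominal: gamma_e = 5 deg
  expect_equal(equivalent_rake_angle(1e-5, geom), geom$gamma_n)
})

test_that("near-degenerate frictions collapse the ploughing force", {
  geom <- default_geom()
  # mu -> 1: slip-line angle -> 0, contact length -> 0
  m_hi <- bone_material(mu = c(1 - 1e-12, 0.5, 0.5))
  p_hi <- ploughing_coefficients(m_hi, geom, 1, 5e-6)
  expect_lt(p_hi$Ktp, 1e-3)
  expect_lt(p_hi$Krp, 1e-3)
  # mu -> 0: cos(2 eta) -> 0
  m_lo <- bone_material(mu = c(1e-9, 0.5, 0.5))
  p_lo <- ploughing_coefficients(m_lo, geom, 1, 5e-6)
  expect_lt(p_lo$Ktp, 1e-3)
  expect_lt(p_lo$Krp, 1e-3)
})

test_that("ploughing components are continuous in h and cross at the slip angle", {
  mat <- bone_material()
  geom <- default_geom()
  re <- geom$re
  h <- seq(0, 2 * re * (1 + sin(geom$gamma_n)), length.out = 8001)
  p <- ploughing_coefficients(mat, geom, 1, h)
  scale <- max(p$Krp, p$Ktp)
  # continuity up to the sqrt modulus the rake-angle arccos imposes at h = 0
  dh <- h[2] - h[1]
  mod_bound <- 1.2 * sqrt(2 * dh / re) * scale
  expect_lt(max(abs(diff(p$Ktp))), mod_bound)
  expect_lt(max(abs(diff(p$Krp))), mod_bound)
  # and to 1e-9 of scale across the rake-angle branch point itself
  h_star <- re * (1 + sin(geom$gamma_n))
  lo <- ploughing_coefficients(mat, geom, 1, h_star * (1 - 1e-12))
  hi2 <- ploughing_coefficients(mat, geom, 1, h_star * (1 + 1e-12))
  expect_lt(abs(lo$Ktp - hi2$Ktp), 1e-9 * scale)
  expect_lt(abs(lo$Krp - hi2$Krp), 1e-9 * scale)

  # |gamma_e| = pi/4 at h = re (1 - sqrt(2)/2): tangential dominates below,
  # radial above (the literal formula ordering, confirmed by the oracle)
  h_cross <- re * (1 - sqrt(2) / 2)
  below <- ploughing_coefficients(mat, geom, 1, h_cross * 0.5)
  above <- ploughing_coefficients(mat, geom, 1, (h_cross + re) / 2)
  expect_gt(below$Ktp, below$Krp)
  expect_gt(above$Krp, above$Ktp)
  at <- ploughing_coefficients(mat, geom, 1, h_cross)
  expect_equal(at$Ktp, at$Krp, tolerance = 1e-9)
})

test_that("coefficient_set bundles shear and ploughing per thickness", {
  mat <- bone_material()
  geom <- default_geom()
  cs <- coefficient_set(mat, geom, 1, c(2e-6, 8e-6))
  expect_equal(nrow(cs), 2)
  expect_equal(cs$Ktc, rep(shear_coefficients(mat, geom, 1)[["Ktc"]], 2))
  expect_equal(cs$Ktp, ploughing_coefficients(mat, geom, 1, c(2e-6, 8e-6))$Ktp)
})
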