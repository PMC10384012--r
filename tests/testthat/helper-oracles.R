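# Shared fixtures and independent reference computations used across tests.
# The oracles here deliberately avoid the package's solver path: thickness is
# recovered by dense sampling of the prior trajectories plus local refinement,
# and the cutting coefficients are re-evaluated term by term from the model
# formulas with standalone arithmetic.

default_geom <- function(...) cutter_geometry(...)
default_proc <- function(...) process_params(...)
conv_vib <- function() vibration_params()
osc_vib <- function() vibration_params(2, 2, 3000, 3000, phase = "sin-cos")

# Brute-force chip thickness: densely sample both candidate prior
# trajectories, locate ray crossings by linear interpolation, polish with a
# few secant steps, keep crossings on the workpiece side, and take the
# innermost surface. Independent of .window_candidates' scan+bisection.
oracle_thickness <- function(t, j, geom, vib, proc, n_dense = 1e5) {
  N <- geom$n_flutes
  omega <- proc$omega
  T_tooth <- 2 * pi / (omega * N)
  T_rev <- 2 * pi / omega
  th <- omega * t - 2 * pi * j / N
  if ((th %% (2 * pi)) > pi) return(0) # outside the slot-milling arc
  ctr <- center_position(t, geom, vib, proc)
  sn <- sin(th)
  cs <- cos(th)
  best <- Inf
  for (w in 1:2) {
    jp <- (((if (w == 1) j - 1L else j) %% N) + N) %% N
    lo <- if (w == 1) max(0, t - 1.5 * T_tooth) else max(0, t - T_rev - 0.5 * T_tooth)
    hi <- if (w == 1) t else max(0, t - T_tooth)
    if (hi <= lo) next
    ts <- seq(lo, hi, length.out = n_dense)
    ps <- tip_position(ts, jp, geom, vib, proc)
    dx <- ps$x - ctr$x
    dy <- ps$y - ctr$y
    res <- sn * dy - cs * dx
    sgn <- sign(res)
    cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                     (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
    for (k in cross) {
      f1 <- res[k]; f2 <- res[k + 1]
      tsr <- ts[k] - f1 * (ts[k + 1] - ts[k]) / (f2 - f1)
      for (it in 1:3) {
        eps <- (ts[2] - ts[1]) * 1e-3
        pa <- tip_position(c(tsr - eps, tsr, tsr + eps), jp, geom, vib, proc)
        rr <- sn * (pa$y - ctr$y) - cs * (pa$x - ctr$x)
        d1 <- (rr[3] - rr[1]) / (2 * eps)
        if (is.finite(d1) && abs(d1) > 0) tsr <- tsr - rr[2] / d1
      }
      pa <- tip_position(tsr, jp, geom, vib, proc)
      ddx <- pa$x - ctr$x
      ddy <- pa$y - ctr$y
      uu <- (ddx * sn + ddy * cs) / geom$r
      if (uu > 1e-3) best <- min(best, geom$r - sqrt(ddx^2 + ddy^2))
    }
  }
  if (!is.finite(best)) return(NA_real_)
  max(0, best)
}

# Term-by-term re-evaluation of the oblique-cutting shear coefficients.
oracle_shear_coeffs <- function(tau, mu, gamma_n, lambda, with_sqrt = TRUE) {
  beta <- atan(mu)
  phi <- pi / 4 - (beta - gamma_n) / 2
  eta_c <- lambda
  d2 <- (cos(phi + beta - gamma_n))^2 + (tan(eta_c))^2 * (sin(beta))^2
  D <- if (with_sqrt) sqrt(d2) else d2
  ktc <- tau * (cos(beta - gamma_n) + tan(eta_c) * sin(beta) * tan(lambda)) / (sin(phi) * D)
  krc <- tau * sin(beta - gamma_n) / (sin(phi) * cos(lambda) * D)
  kac <- tau * (cos(beta - gamma_n) * tan(lambda) - tan(eta_c) * sin(beta)) / (sin(phi) * D)
  c(Ktc = ktc, Krc = krc, Kac = kac)
}

# Term-by-term re-evaluation of the slip-line ploughing coefficients.
oracle_plough_coeffs <- function(tau, mu, re, gamma_n, h) {
  eta <- 0.5 * acos(mu)
  l_mn <- re * sin(eta)
  fp_b <- tau * cos(2 * eta) * l_mn
  ge <- if (h <= re * (1 + sin(gamma_n))) acos((re - h) / re) - pi / 2 else gamma_n
  c(Ktp = fp_b * abs(sin(ge)), Krp = fp_b * cos(ge))
}

# Removed cross-section area per revolution from a thickness profile,
# rectangle rule over the post-transient revolutions.
removed_area_per_rev <- function(profile, geom, proc) {
  ss <- profile[profile$revolution >= 2L, ]
  dth <- proc$omega * attr(profile, "params")$dt
  sum(ss$h * geom$r * dth) / length(unique(ss$revolution))
}
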