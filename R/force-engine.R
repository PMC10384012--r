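#' Micro-element cutting forces
#'
#' Tangential/radial/axial force on one flute micro-element of height `dz`
#' cutting chip thickness `h`:
#' \deqn{dF_t = K_{tc} h\, dz + K_{tp} dz,\quad dF_r = K_{rc} h\, dz + K_{rp} dz,\quad
#'       dF_a = K_{ac} h\, dz + K_{ap} dz.}
#' An element with `h = 0` is separated from the material and transmits no
#' force -- the ploughing terms apply only while the edge is engaged. The
#' axial ploughing coefficient K_ap has no first-principles closed form in
#' this model and defaults to zero.
#'
#' @param h uncut chip thickness (m), vectorised.
#' @param dz axial element height (m), > 0.
#' @param coeffs a list or tibble with `Ktc`, `Krc`, `Kac`, `Ktp`, `Krp`
#'   (e.g. from [coefficient_set()]); ploughing entries may be vectors
#'   matching `h`.
#' @param Kap axial ploughing coefficient (N/m), default 0.
#' @return tibble with columns `dFt`, `dFr`, `dFa` (N).
#' @export
elemental_forces <- function(h, dz, coeffs, Kap = 0) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0)) {
    stop_input("`h` must be nonnegative")
  }
  check_number(dz, "dz", lower = 0, strict_lower = TRUE)
  cutting <- h > 0
  tibble::tibble(
    dFt = ifelse(cutting, coeffs$Ktc * h * dz + coeffs$Ktp * dz, 0),
    dFr = ifelse(cutting, coeffs$Krc * h * dz + coeffs$Krp * dz, 0),
    dFa = ifelse(cutting, coeffs$Kac * h * dz + Kap * dz, 0)
  )
}

#' Assemble workpiece-frame force traces from a thickness profile
#'
#' Discretises each flute into `n_slices` axial micro-elements of height
#' `dz = H / n_slices`. The element at height z cuts at the lagged tooth
#' angle `theta - theta_z(z)` (helix lag), so its chip thickness is the
#' bottom-edge thickness evaluated one lag time earlier (linear
#' interpolation on the profile grid). Engaged elements (slot-milling arc,
#' h > 0) contribute
#' \deqn{dF_x = dF_t\cos\theta + dF_r\sin\theta,\quad
#'       dF_y = -dF_t\sin\theta + dF_r\cos\theta,\quad dF_z = -dF_a,}
#' summed over elements and flutes.
#'
#' @param profile a [thickness_profile()].
#' @param geom,proc,mat parameter objects (direction is read from `proc`).
#' @param n_slices number of axial micro-elements per flute.
#' @param armarego_sqrt,slipline_length passed to the coefficient models.
#' @param ploughing logical; include the edge (ploughing) force.
#' @param Kap axial ploughing coefficient (N/m), default 0.
#' @param flip_y logical; negate Fy for dynamometer frames with an inverted
#'   Y axis.
#' @return a `mill_force_trace` tibble: `t` (s), `theta_deg` (tooth-0 angle,
#'   unwrapped, deg), `revolution`, `Fx`, `Fy`, `Fz` (N); generating
#'   parameters in `attr(, "params")`.
#' @export
assemble_forces <- function(profile, geom, proc, mat, n_slices = 20,
                            armarego_sqrt = TRUE, slipline_length = "product",
                            ploughing = TRUE, Kap = 0, flip_y = FALSE) {
  if (!inherits(profile, "mill_thickness_profile")) {
    stop_input("`profile` must come from thickness_profile()")
  }
  if (n_slices < 1 || n_slices != as.integer(n_slices)) {
    stop_input("`n_slices` must be a positive integer")
  }
  pp <- attr(profile, "params")
  vib <- pp$vib
  t_grid <- sort(unique(profile$t))
  n_t <- length(t_grid)
  teeth <- sort(unique(profile$tooth))
  if (!all(diff(t_grid) > 0)) stop_input("profile time grid is inconsistent")

  dz <- proc$H / n_slices
  z_k <- (seq_len(n_slices) - 0.5) * dz
  theta_z <- lag_angle(geom, z_k)
  tau_k <- theta_z / proc$omega

  ks <- shear_coefficients(mat, geom, proc$direction, armarego_sqrt = armarego_sqrt)
  Ktc <- ks[["Ktc"]]; Krc <- ks[["Krc"]]; Kac <- ks[["Kac"]]

  Fx <- numeric(n_t); Fy <- numeric(n_t); Fz <- numeric(n_t)
  for (j in teeth) {
    pj <- profile[profile$tooth == j, ]
    pj <- pj[order(pj$t), ]
    if (!isTRUE(all.equal(pj$t, t_grid))) stop_input("profile time grid is inconsistent")
    th_j <- tooth_angle(t_grid, j, geom, proc)
    for (k in seq_len(n_slices)) {
      t_lag <- t_grid - tau_k[k]
      h_k <- stats::approx(t_grid, pj$h, xout = t_lag, rule = 2)$y
      h_k[t_lag < t_grid[1]] <- 0
      th_k <- th_j - theta_z[k]
      engaged <- (th_k %% (2 * pi)) <= pi & h_k > 0
      if (!any(engaged)) next
      h_e <- h_k[engaged]
      if (ploughing) {
        kp <- ploughing_coefficients(mat, geom, proc$direction, h_e,
                                     slipline_length = slipline_length)
        Ktp <- kp$Ktp; Krp <- kp$Krp
      } else {
        Ktp <- 0; Krp <- 0
      }
      dFt <- (Ktc * h_e + Ktp) * dz
      dFr <- (Krc * h_e + Krp) * dz
      dFa <- (Kac * h_e + Kap) * dz
      ct <- cos(th_k[engaged]); st <- sin(th_k[engaged])
      Fx[engaged] <- Fx[engaged] + dFt * ct + dFr * st
      Fy[engaged] <- Fy[engaged] + (-dFt * st + dFr * ct)
      Fz[engaged] <- Fz[engaged] - dFa
    }
  }
  if (flip_y) Fy <- -Fy

  T_rev <- 2 * pi / proc$omega
  params <- list(
    mat = mat, geom = geom, vib = vib, proc = proc, dt = pp$dt,
    n_revolutions = pp$n_revolutions, n_slices = n_slices,
    total_flute_wrap = lag_angle(geom, proc$H),
    armarego_sqrt = armarego_sqrt, slipline_length = slipline_length,
    ploughing = ploughing, Kap = Kap, flip_y = flip_y
  )
  tibble::new_tibble(
    tibble::tibble(
      t = t_grid,
      theta_deg = rad2deg(tooth_angle(t_grid, 0L, geom, proc)),
      revolution = as.integer(ceiling(t_grid / T_rev - 1e-12)),
      Fx = Fx, Fy = Fy, Fz = Fz
    ),
    params = params,
    class = c("mill_force_trace", "tbl_df")
  )
}

#' Simulate a vibration-assisted micro-milling force trace
#'
#' End-to-end driver: kinematics -> chip-thickness solve -> axial force
#' integration. The first spindle revolution (start-up transient, no prior
#' machined surface) is discarded from the returned trace. The computation
#' is deterministic: identical configurations give bit-identical traces.
#'
#' @param mat a [bone_material()].
#' @param geom a [cutter_geometry()].
#' @param vib a [vibration_params()].
#' @param proc a [process_params()].
#' @param n_revolutions revolutions to simulate, >= 2 (revolution 1 is
#'   dropped).
#' @param dt time step (s); defaults to [default_dt()].
#' @param n_scan chip-solver bracketing resolution.
#' @param ... passed to [assemble_forces()] (`n_slices`, `armarego_sqrt`,
#'   `slipline_length`, `ploughing`, `Kap`, `flip_y`).
#' @return a `mill_force_trace` tibble (see [assemble_forces()]).
#' @examples
#' \donttest{
#' trace <- simulate_milling(n_revolutions = 2)
#' range(trace$Fx)
#' }
#' @export
simulate_milling <- function(mat = bone_material(), geom = cutter_geometry(),
                             vib = vibration_params(), proc = process_params(),
                             n_revolutions = 3, dt = NULL, n_scan = 200, ...) {
  profile <- thickness_profile(geom, vib, proc, n_revolutions = n_revolutions,
                               dt = dt, n_scan = n_scan)
  trace <- assemble_forces(profile, geom, proc, mat, ...)
  out <- trace[trace$revolution >= 2L, ]
  tibble::new_tibble(out, params = attr(trace, "params"),
                     class = c("mill_force_trace", "tbl_df"))
}

#' Export a force trace as CSV with a JSON config sidecar
#'
#' Writes `t_s`, `theta_deg`, `Fx_N`, `Fy_N`, `Fz_N` to `path` and the full
#' generating configuration to `<path>.json` so a run can be replayed
#' bit-exactly.
#'
#' @param trace a `mill_force_trace`.
#' @param path output CSV path.
#' @return the written tibble, invisibly.
#' @export
write_force_csv <- function(trace, path) {
  df <- tibble::tibble(
    t_s = trace$t, theta_deg = trace$theta_deg,
    Fx_N = trace$Fx, Fy_N = trace$Fy, Fz_N = trace$Fz
  )
  utils::write.csv(df, path, row.names = FALSE)
  p <- attr(trace, "params")
  if (!is.null(p)) {
    cfg <- list(
      material = list(tau_s_MPa = unname(p$mat$tau_s) / 1e6, mu = unname(p$mat$mu)),
      cutter = list(
        diameter_um = 2 * m2um(p$geom$r), rake_deg = rad2deg(p$geom$gamma_n),
        clearance_deg = rad2deg(p$geom$alpha_n), helix_deg = rad2deg(p$geom$lambda),
        edge_radius_um = m2um(p$geom$re), runout_um = m2um(p$geom$r0),
        runout_angle_deg = rad2deg(p$geom$psi), n_flutes = p$geom$n_flutes
      ),
      vibration = list(
        Ax_um = m2um(p$vib$Ax), Ay_um = m2um(p$vib$Ay),
        fx_Hz = p$vib$fx, fy_Hz = p$vib$fy,
        phix_deg = rad2deg(p$vib$phix), phiy_deg = rad2deg(p$vib$phiy)
      ),
      process = list(
        spindle_rpm = p$proc$rpm, feed_per_tooth_um = m2um(p$proc$fz),
        axial_depth_um = m2um(p$proc$H), direction = p$proc$direction
      ),
      options = list(
        dt = p$dt, n_revolutions = p$n_revolutions, n_slices = p$n_slices,
        armarego_sqrt = p$armarego_sqrt, slipline_length = p$slipline_length,
        ploughing = p$ploughing, Kap = p$Kap, flip_y = p$flip_y
      )
    )
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(df)
}
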