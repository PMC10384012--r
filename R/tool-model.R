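#' Micro end-mill geometry
#'
#' Geometry of a helical flat-end micro-mill. Constructor arguments use
#' workshop units (micrometres and degrees); the stored fields are SI
#' (metres, radians). The edge inclination angle of an end mill is taken
#' equal to its helix angle, so `helix_deg` doubles as the oblique-cutting
#' inclination used by the chip-flow rule.
#'
#' Defaults describe a two-flute 0.8 mm coated tungsten-carbide micro-mill:
#' diameter 800 um, rake 5 deg, clearance 10 deg, helix 35 deg, edge (blunt
#' circle) radius 5 um, runout 2 um.
#'
#' @param diameter_um tool diameter (um).
#' @param rake_deg nominal rake angle gamma_n (deg).
#' @param clearance_deg clearance (back) angle alpha_n (deg).
#' @param helix_deg helix angle lambda (deg), in (0, 90).
#' @param edge_radius_um cutting-edge blunt-circle radius re (um).
#' @param runout_um radial runout (eccentricity) r0 (um).
#' @param runout_angle_deg runout orientation angle psi (deg); unreported for
#'   most setups, so it defaults to 0.
#' @param n_flutes number of cutting edges N.
#'
#' @return object of class `cutter_geometry` with SI fields `r`, `gamma_n`,
#'   `alpha_n`, `lambda`, `re`, `r0`, `psi`, `n_flutes`.
#' @examples
#' geom <- cutter_geometry()
#' geom$re * 1e6 # 5
#' @export
cutter_geometry <- function(diameter_um = 800, rake_deg = 5, clearance_deg = 10,
                            helix_deg = 35, edge_radius_um = 5, runout_um = 2,
                            runout_angle_deg = 0, n_flutes = 2) {
  check_number(diameter_um, "diameter_um", lower = 0, strict_lower = TRUE)
  check_number(edge_radius_um, "edge_radius_um", lower = 0, strict_lower = TRUE)
  check_number(runout_um, "runout_um", lower = 0)
  check_number(helix_deg, "helix_deg", lower = 0, upper = 90,
               strict_lower = TRUE, strict_upper = TRUE)
  if (!is.numeric(n_flutes) || n_flutes < 1 || n_flutes != as.integer(n_flutes)) {
    stop_input("`n_flutes` must be a positive integer")
  }
  r <- um2m(diameter_um) / 2
  re <- um2m(edge_radius_um)
  if (re >= r) stop_input("edge radius must be smaller than the tool radius")
  structure(
    list(
      r = r,
      gamma_n = deg2rad(rake_deg),
      alpha_n = deg2rad(clearance_deg),
      lambda = deg2rad(helix_deg),
      re = re,
      r0 = um2m(runout_um),
      psi = deg2rad(runout_angle_deg),
      n_flutes = as.integer(n_flutes)
    ),
    class = "cutter_geometry"
  )
}

#' @export
print.cutter_geometry <- function(x, ...) {
  cat("<cutter_geometry>\n")
  cat(sprintf("  d = %g um, rake %g deg, clearance %g deg, helix %g deg\n",
              2 * m2um(x$r), rad2deg(x$gamma_n), rad2deg(x$alpha_n), rad2deg(x$lambda)))
  cat(sprintf("  edge radius %g um, runout %g um @ %g deg, %d flutes\n",
              m2um(x$re), m2um(x$r0), rad2deg(x$psi), x$n_flutes))
  invisible(x)
}

#' Default micro end-mill
#'
#' The package default cutter (see [cutter_geometry()] argument defaults).
#' @return a `cutter_geometry`.
#' @export
default_cutter <- function() cutter_geometry()

#' Helix lag angle at axial height z
#'
#' A point of the flute at axial height z lags the bottom of the cutting edge
#' by \eqn{\theta_z = z \tan\lambda / r}; linear in z.
#'
#' @param geom a [cutter_geometry()].
#' @param z axial height in m (>= 0). Vectorised.
#' @return lag angle(s) in radians.
#' @examples
#' lag_angle(default_cutter(), 100e-6) # 0.175 rad
#' @export
lag_angle <- function(geom, z) {
  if (!is.numeric(z) || any(!is.finite(z)) || any(z < 0)) {
    stop_input("axial height `z` must be nonnegative")
  }
  tan(geom$lambda) * z / geom$r
}

#' Angular integration limits for a helical flute in slot milling
#'
#' For a flute whose bottom edge sits at tooth angle `theta` and which wraps
#' `theta_z` radians of lag over the axial depth of cut, the portion of the
#' flute inside the material spans the angle interval returned here. Slot
#' milling engages each tooth over half a revolution, so the radial exit
#' angle is `theta_d = pi` for a two-flute cutter. Three zones arise: entry
#' (the flute is growing into the cut), continuous cutting, and exit (the
#' bottom has left the cut but the upper flute is still engaged); outside
#' those the flute is free.
#'
#' `theta` is interpreted modulo 2*pi, so unwrapped angles may be passed.
#'
#' @param theta bottom-edge tooth position angle (rad).
#' @param theta_z total lag angle over the axial depth (rad, >= 0).
#' @param theta_d radial exit angle (rad); `pi` for slot milling.
#' @return a list with `engaged` (logical), `theta_st`, `theta_ex` (NA when
#'   not engaged).
#' @export
engagement_limits <- function(theta, theta_z, theta_d = pi) {
  check_number(theta_z, "theta_z", lower = 0)
  check_number(theta_d, "theta_d", lower = 0, strict_lower = TRUE)
  th <- theta %% (2 * pi)
  if (th >= 0 && th <= theta_z) {
    list(engaged = TRUE, theta_st = 0, theta_ex = th)
  } else if (th > theta_z && th <= theta_d) {
    list(engaged = TRUE, theta_st = th - theta_z, theta_ex = th)
  } else if (th > theta_d && th <= theta_d + theta_z) {
    list(engaged = TRUE, theta_st = th - theta_z, theta_ex = theta_d)
  } else {
    list(engaged = FALSE, theta_st = NA_real_, theta_ex = NA_real_)
  }
}
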