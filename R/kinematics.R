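#' 2D platform vibration parameters
#'
#' The workpiece sits on a piezo vibration stage that oscillates in X and Y.
#' In the workpiece frame the vibration is folded into the tool-tip
#' trajectory, so both axes are written as sines with an initial phase:
#' X gets `Ax*sin(2*pi*fx*t + phix)` and Y gets `Ay*sin(2*pi*fy*t + phiy)`.
#' The named presets are `"sin-cos"` (Y leads by 90 deg, i.e. phiy = pi/2,
#' giving a circular/elliptical platform path when amplitudes and frequencies
#' match) and `"sin-sin"` (in phase).
#'
#' @param Ax_um,Ay_um amplitudes in um (>= 0).
#' @param fx_Hz,fy_Hz frequencies in Hz (>= 0).
#' @param phase either a preset name ("sin-cos", "sin-sin") or a numeric
#'   length-2 vector of phases in degrees `c(phix, phiy)`.
#' @return object of class `vibration_params` with SI fields `Ax`, `Ay`,
#'   `fx`, `fy`, `phix`, `phiy`.
#' @examples
#' vibration_params(2, 2, 3000, 3000, phase = "sin-cos")
#' @export
vibration_params <- function(Ax_um = 0, Ay_um = 0, fx_Hz = 0, fy_Hz = 0,
                             phase = "sin-cos") {
  check_number(Ax_um, "Ax_um", lower = 0)
  check_number(Ay_um, "Ay_um", lower = 0)
  check_number(fx_Hz, "fx_Hz", lower = 0)
  check_number(fy_Hz, "fy_Hz", lower = 0)
  if (is.character(phase)) {
    ph <- phase_preset(phase)
  } else {
    if (!is.numeric(phase) || length(phase) != 2L) {
      stop_input("`phase` must be a preset name or c(phix_deg, phiy_deg)")
    }
    ph <- deg2rad(phase)
  }
  structure(
    list(Ax = um2m(Ax_um), Ay = um2m(Ay_um), fx = fx_Hz, fy = fy_Hz,
         phix = ph[[1]], phiy = ph[[2]]),
    class = "vibration_params"
  )
}

#' @export
print.vibration_params <- function(x, ...) {
  cat(sprintf("<vibration_params> Ax=%g um @ %g Hz (phi=%g deg), Ay=%g um @ %g Hz (phi=%g deg)\n",
              m2um(x$Ax), x$fx, rad2deg(x$phix), m2um(x$Ay), x$fy, rad2deg(x$phiy)))
  invisible(x)
}

#' Initial-phase presets for the vibration signal source
#'
#' @param name `"sin-cos"` or `"sin-sin"`.
#' @return numeric `c(phix, phiy)` in radians: (0, pi/2) and (0, 0)
#'   respectively.
#' @export
phase_preset <- function(name) {
  switch(name,
    "sin-cos" = c(0, pi / 2),
    "sin-sin" = c(0, 0),
    stop_input("unknown phase preset '%s' (use 'sin-cos' or 'sin-sin')", name)
  )
}

#' Milling process parameters
#'
#' @param spindle_rpm spindle speed in rev/min (> 0).
#' @param feed_per_tooth_um feed per tooth fz in um (>= 0).
#' @param axial_depth_um axial depth of cut H in um (> 0).
#' @param direction cutting direction (1/2/3 or name) relative to the osteon
#'   axis.
#' @return object of class `process_params` with SI fields `rpm`, `fz`, `H`,
#'   `direction`, and the derived `omega` (rad/s). The feed speed
#'   `v = fz * N * rpm / 60` depends on the flute count and is computed by
#'   [feed_speed()].
#' @examples
#' process_params() # the default study conditions: 3000 rpm, 10 um, 100 um
#' @export
process_params <- function(spindle_rpm = 3000, feed_per_tooth_um = 10,
                           axial_depth_um = 100, direction = 1) {
  check_number(spindle_rpm, "spindle_rpm", lower = 0, strict_lower = TRUE)
  check_number(feed_per_tooth_um, "feed_per_tooth_um", lower = 0)
  check_number(axial_depth_um, "axial_depth_um", lower = 0, strict_lower = TRUE)
  structure(
    list(
      rpm = spindle_rpm,
      fz = um2m(feed_per_tooth_um),
      H = um2m(axial_depth_um),
      direction = as_direction(direction),
      omega = 2 * pi * spindle_rpm / 60
    ),
    class = "process_params"
  )
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("<process_params> n=%g rpm, fz=%g um, H=%g um, direction=%s\n",
              x$rpm, m2um(x$fz), m2um(x$H), direction_names()[x$direction]))
  invisible(x)
}

#' Feed speed of the workpiece
#'
#' `v = fz * N * n / 60` in m/s.
#' @param proc a [process_params()].
#' @param geom a [cutter_geometry()] (supplies the flute count N).
#' @return feed speed in m/s.
#' @export
feed_speed <- function(proc, geom) proc$fz * geom$n_flutes * proc$rpm / 60

#' Unwrapped tooth-position angle
#'
#' theta_j(t) = omega*t - 2*pi*j/N, measured in the rotation direction with
#' theta = 0 at the +Y axis. Unwrapped: it grows past 2*pi; reduce modulo
#' 2*pi for engagement tests.
#'
#' @param t time(s) in s.
#' @param j tooth index, 0-based.
#' @param geom,proc geometry and process parameter objects.
#' @return angle(s) in radians.
#' @export
tooth_angle <- function(t, j, geom, proc) {
  proc$omega * t - 2 * pi * j / geom$n_flutes
}

# Internal fast paths returning plain lists -------------------------------

.tip_xy <- function(t, j, geom, vib, proc, v = feed_speed(proc, geom)) {
  th <- proc$omega * t - 2 * pi * j / geom$n_flutes
  list(
    x = v * t + geom$r * sin(th) + geom$r0 * sin(proc$omega * t + geom$psi) +
      vib$Ax * sin(2 * pi * vib$fx * t + vib$phix),
    y = geom$r * cos(th) + geom$r0 * cos(proc$omega * t + geom$psi) +
      vib$Ay * sin(2 * pi * vib$fy * t + vib$phiy)
  )
}

.center_xy <- function(t, geom, vib, proc, v = feed_speed(proc, geom)) {
  list(
    x = v * t + geom$r0 * sin(proc$omega * t + geom$psi) +
      vib$Ax * sin(2 * pi * vib$fx * t + vib$phix),
    y = geom$r0 * cos(proc$omega * t + geom$psi) +
      vib$Ay * sin(2 * pi * vib$fy * t + vib$phiy)
  )
}

#' Tool-tip trajectory in the workpiece frame
#'
#' Position of tooth `j`'s tip relative to the workpiece: superposition of
#' workpiece feed, tool rotation, tool runout, and the 2D platform vibration
#' (folded into the relative trajectory):
#' \deqn{x = vt + r\sin(\omega t - 2\pi j/N) + r_0\sin(\omega t+\psi) + A_x\sin(2\pi f_x t + \varphi_x)}
#' \deqn{y = r\cos(\omega t - 2\pi j/N) + r_0\cos(\omega t+\psi) + A_y\sin(2\pi f_y t + \varphi_y)}
#'
#' @param t time(s) in s (vectorised).
#' @param j tooth index in `0:(N-1)`.
#' @param geom a [cutter_geometry()].
#' @param vib a [vibration_params()].
#' @param proc a [process_params()].
#' @return tibble with columns `t`, `x`, `y` (m).
#' @export
tip_position <- function(t, j, geom, vib, proc) {
  if (j < 0 || j >= geom$n_flutes) stop_input("tooth index out of range")
  p <- .tip_xy(t, j, geom, vib, proc)
  tibble::tibble(t = t, x = p$x, y = p$y)
}

#' Tool-centre trajectory in the workpiece frame
#'
#' Same superposition as [tip_position()] without the rotation term.
#' @inheritParams tip_position
#' @return tibble with columns `t`, `x`, `y` (m).
#' @export
center_position <- function(t, geom, vib, proc) {
  p <- .center_xy(t, geom, vib, proc)
  tibble::tibble(t = t, x = p$x, y = p$y)
}

#' Default simulation time step
#'
#' dt = 1 / (K * f_max) with f_max the fastest process frequency: the larger
#' of the vibration frequencies and the tooth-passing frequency
#' N * rpm / 60. K = 50 samples per cycle resolves the oscillating chip
#' thickness; raise it for smoother thickness exports.
#'
#' @param geom,vib,proc parameter objects.
#' @param samples_per_cycle K, samples per fastest cycle.
#' @return time step in s.
#' @export
default_dt <- function(geom, vib, proc, samples_per_cycle = 50) {
  f_max <- max(vib$fx, vib$fy, geom$n_flutes * proc$rpm / 60)
  1 / (samples_per_cycle * f_max)
}
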