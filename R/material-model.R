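#' Anisotropic cortical-bone material properties
#'
#' Cortical bone behaves as a fibre-reinforced composite: osteons give it
#' direction-dependent shear strength and friction. The model indexes the
#' three canonical cutting directions relative to the osteon axis as
#' 1 = parallel, 2 = cross, 3 = vertical. A `bone_material` holds, per
#' direction, the shear strength \eqn{\tau_s} (stored in Pa) and the
#' tool-bone friction coefficient \eqn{\mu}, from which the friction angle
#' \eqn{\beta = \arctan\mu} and the slip-line angle
#' \eqn{\eta = \tfrac12\cos^{-1}\mu} are derived wherever a cutting
#' coefficient needs them.
#'
#' @param tau_s_MPa numeric length-3 vector of shear strengths in MPa, in
#'   direction order (parallel, cross, vertical). Defaults are bovine
#'   cortical-bone values measured by direct shear testing.
#' @param mu numeric length-3 vector of rake-face friction coefficients
#'   (dimensionless, in (0, 1)), same ordering.
#'
#' @return An object of class `bone_material`: a list with `tau_s` (Pa,
#'   named "1","2","3") and `mu` (named the same way).
#' @examples
#' mat <- bone_material()
#' shear_strength(mat, "vertical") / 1e6 # 180.12 MPa
#' @export
bone_material <- function(tau_s_MPa = c(81.03, 94.48, 180.12),
                          mu = c(0.82, 0.98, 0.85)) {
  if (length(tau_s_MPa) != 3L || length(mu) != 3L) {
    stop_input("`tau_s_MPa` and `mu` must each have one value per cutting direction (3)")
  }
  tau_s_MPa <- as.numeric(tau_s_MPa)
  mu <- as.numeric(mu)
  if (any(!is.finite(tau_s_MPa)) || any(tau_s_MPa <= 0)) {
    stop_input("shear strengths must be positive and finite")
  }
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop_input("friction coefficients must lie strictly in (0, 1)")
  }
  structure(
    list(
      tau_s = stats::setNames(MPa2Pa(tau_s_MPa), as.character(1:3)),
      mu = stats::setNames(mu, as.character(1:3))
    ),
    class = "bone_material"
  )
}

#' @export
print.bone_material <- function(x, ...) {
  cat("<bone_material>\n")
  df <- data.frame(
    direction = direction_names(),
    tau_s_MPa = unname(x$tau_s) / 1e6,
    mu = unname(x$mu)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

direction_names <- function() c("parallel", "cross", "vertical")

#' Resolve a cutting-direction index
#'
#' Accepts the numeric codes 1/2/3 or the names "parallel"/"cross"/"vertical"
#' and returns the integer code. Any other value is an error.
#'
#' @param direction a direction code or name.
#' @return integer in 1:3.
#' @export
as_direction <- function(direction) {
  if (is.character(direction)) {
    idx <- match(tolower(direction), direction_names())
    if (anyNA(idx)) stop_input("unknown cutting direction '%s'", direction[is.na(idx)][1])
    return(as.integer(idx))
  }
  if (!is.numeric(direction) || anyNA(direction) || any(direction != as.integer(direction)) ||
      any(direction < 1) || any(direction > 3)) {
    stop_input("cutting direction must be 1 (parallel), 2 (cross) or 3 (vertical)")
  }
  as.integer(direction)
}

#' Look up shear strength or friction coefficient for a direction
#'
#' @param mat a [bone_material()].
#' @param direction direction code or name.
#' @return scalar shear strength in Pa (`shear_strength`) or friction
#'   coefficient (`friction_coefficient`).
#' @export
shear_strength <- function(mat, direction) {
  unname(mat$tau_s[[as_direction(direction)]])
}

#' @rdname shear_strength
#' @export
friction_coefficient <- function(mat, direction) {
  unname(mat$mu[[as_direction(direction)]])
}

#' Shear strength from a direct shear test
#'
#' A bone coupon sheared to failure in a double-shear fixture fails across two
#' faces, so the strength is the peak load divided by twice the nominal shear
#' area: \eqn{\tau_s = F_{max} / (2S)}.
#'
#' @param max_load_N peak shear load in N (>= 0).
#' @param shear_area_m2 nominal cross-sectional area of one shear face in m^2
#'   (> 0).
#' @return shear strength in Pa.
#' @examples
#' shear_strength_from_test(2430.9, 15e-6) / 1e6 # 81.03 MPa
#' @export
shear_strength_from_test <- function(max_load_N, shear_area_m2) {
  if (!is.numeric(max_load_N) || any(!is.finite(max_load_N)) || any(max_load_N < 0)) {
    stop_input("`max_load_N` must be nonnegative and finite")
  }
  if (!is.numeric(shear_area_m2) || any(!is.finite(shear_area_m2)) || any(shear_area_m2 <= 0)) {
    stop_input("`shear_area_m2` must be positive")
  }
  max_load_N / (2 * shear_area_m2)
}

#' Read a displacement/load shear-test record
#'
#' Reads a two-column CSV (`displacement_mm`, `load_N`, header required) from a
#' shear test and returns it as a tibble; [shear_strength_from_test()] applied
#' to `max(load_N)` gives the strength. Curve morphology is not modelled --
#' only the peak load enters the material model.
#'
#' @param path path to the CSV file.
#' @return tibble with columns `displacement_mm`, `load_N`.
#' @export
read_shear_test <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("displacement_mm", "load_N")
  if (!all(need %in% names(df))) {
    stop_input("shear-test CSV must have columns displacement_mm, load_N")
  }
  tibble::as_tibble(df[need])
}

#' Friction and slip-line angles from a friction coefficient
#'
#' `friction_angle()` returns \eqn{\beta = \arctan\mu}, the rake-face friction
#' angle used by the oblique-cutting shear coefficients. `slip_line_angle()`
#' returns \eqn{\eta = \tfrac12 \cos^{-1}\mu}, the angle between the
#' dead-metal slip line under the rounded edge and the machined surface, used
#' by the ploughing model.
#'
#' @param mu friction coefficient; strictly positive for `friction_angle`,
#'   in \[0, 1\] for `slip_line_angle`. Vectorised.
#' @return angle(s) in radians.
#' @examples
#' friction_angle(0.82) # 0.6869 rad
#' slip_line_angle(0.82) # 0.3047 rad
#' @export
friction_angle <- function(mu) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu <= 0)) {
    stop_input("`mu` must be > 0 for the friction angle")
  }
  atan(mu)
}

#' @rdname friction_angle
#' @export
slip_line_angle <- function(mu) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu < 0) || any(mu > 1)) {
    stop_input("`mu` must lie in [0, 1] for the slip-line angle")
  }
  0.5 * acos(mu)
}

#' Default bovine cortical-bone material
#'
#' Shear strengths (MPa): parallel 81.03, cross 94.48, vertical 180.12;
#' friction coefficients: 0.82, 0.98, 0.85. These are the package defaults of
#' [bone_material()], exposed as a named constructor for readability.
#'
#' @return a [bone_material()].
#' @export
default_bone_material <- function() bone_material()
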