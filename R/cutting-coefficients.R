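#' Normal shear angle from friction and rake angles
#'
#' Merchant-type shear-angle relation for the oblique micro-element:
#' \eqn{\varphi = \pi/4 - (\beta - \gamma_n)/2}. The result must land in
#' (0, pi/2); a configuration pushing it outside is rejected.
#'
#' @param beta friction angle (rad).
#' @param gamma_n nominal rake angle (rad).
#' @return shear angle (rad). Vectorised.
#' @examples
#' shear_angle(friction_angle(0.82), 5 * pi / 180) # ~0.486 rad
#' @export
shear_angle <- function(beta, gamma_n) {
  phi <- pi / 4 - (beta - gamma_n) / 2
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi >= pi / 2)) {
    stop_input("shear angle outside (0, pi/2); check friction and rake angles")
  }
  phi
}

#' Oblique-cutting (Armarego) shear force coefficients
#'
#' Tangential/radial/axial shear coefficients (force per unit chip area) for
#' one cutting direction, from the oblique-cutting shear model with the
#' chip-flow rule \eqn{\eta_c = \lambda} (chip flow angle equals the edge
#' inclination = helix angle):
#' \deqn{K_{tc} = \frac{\tau\,[\cos(\beta-\gamma_n) + \tan\eta_c \tan\lambda \sin\beta]}{\sin\varphi\, D},\quad
#'       K_{rc} = \frac{\tau\,\sin(\beta-\gamma_n)}{\sin\varphi \cos\lambda\, D},\quad
#'       K_{ac} = \frac{\tau\,[\cos(\beta-\gamma_n)\tan\lambda - \tan\eta_c \sin\beta]}{\sin\varphi\, D}}
#' with shared denominator
#' \eqn{D = \sqrt{\cos^2(\varphi+\beta-\gamma_n) + \tan^2\eta_c \sin^2\beta}}.
#' `armarego_sqrt = FALSE` drops the radical on D (an alternative literal
#' reading of the model found in some transcriptions); the square-root form
#' is the published oblique-cutting original and the default.
#'
#' @param mat a [bone_material()].
#' @param geom a [cutter_geometry()].
#' @param direction cutting direction (1/2/3 or name).
#' @param armarego_sqrt logical; keep the radical in the denominator.
#' @return named numeric vector `c(Ktc =, Krc =, Kac =)` in Pa.
#' @export
shear_coefficients <- function(mat, geom, direction, armarego_sqrt = TRUE) {
  i <- as_direction(direction)
  tau <- shear_strength(mat, i)
  beta <- friction_angle(friction_coefficient(mat, i))
  gamma_n <- geom$gamma_n
  lambda <- geom$lambda
  eta_c <- lambda # chip-flow rule
  phi <- shear_angle(beta, gamma_n)

  D2 <- cos(phi + beta - gamma_n)^2 + tan(eta_c)^2 * sin(beta)^2
  D <- if (isTRUE(armarego_sqrt)) sqrt(D2) else D2
  if (!is.finite(D) || D < 1e-12) {
    stop_numeric("degenerate Armarego denominator (D = %g)", D)
  }
  c(
    Ktc = tau * (cos(beta - gamma_n) + tan(eta_c) * tan(lambda) * sin(beta)) / (sin(phi) * D),
    Krc = tau * sin(beta - gamma_n) / (sin(phi) * cos(lambda) * D),
    Kac = tau * (cos(beta - gamma_n) * tan(lambda) - tan(eta_c) * sin(beta)) / (sin(phi) * D)
  )
}

#' Equivalent rake angle of a rounded cutting edge
#'
#' When the uncut chip thickness h is comparable to the edge radius re, the
#' material meets the blunt circle rather than the nominal rake face, and the
#' edge presents a strongly negative effective rake:
#' \deqn{\gamma_e = \arccos\!\frac{r_e - h}{r_e} - \frac{\pi}{2}
#'       \quad (h \le r_e(1+\sin\gamma_n)), \qquad \gamma_e = \gamma_n
#'       \quad\text{otherwise.}}
#' The two branches agree at the changeover thickness, so gamma_e is
#' continuous in h; gamma_e(0) = -pi/2 and gamma_e(re) = 0 exactly.
#'
#' @param h uncut chip thickness in m (>= 0). Vectorised.
#' @param geom a [cutter_geometry()].
#' @return equivalent rake angle(s) in radians.
#' @export
equivalent_rake_angle <- function(h, geom) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0)) {
    stop_input("`h` must be nonnegative")
  }
  re <- geom$re
  gamma_n <- geom$gamma_n
  h_star <- re * (1 + sin(gamma_n))
  arg <- pmin(1, pmax(-1, (re - h) / re))
  ifelse(h <= h_star, acos(arg) - pi / 2, gamma_n)
}

#' Slip-line ploughing force coefficients
#'
#' Ploughing (edge) force per unit edge length from the slip-line model of a
#' rounded edge: the slip line leaves the edge at angle
#' \eqn{\eta = \tfrac12\cos^{-1}\mu} over a contact length
#' \eqn{l_{MN} = r_e \sin\eta}, giving a ploughing force per unit width
#' \eqn{F_p/b = \tau \cos(2\eta)\, l_{MN}}. Resolved on the equivalent rake
#' angle \eqn{\gamma_e(h)} of the blunt edge:
#' \eqn{K_{tp} = (F_p/b)\,|\sin\gamma_e|}, \eqn{K_{rp} = (F_p/b)\cos\gamma_e}.
#' Coefficients are stored as nonnegative magnitudes; the sense of the
#' ploughing force (always resisting the cut) is applied by the force
#' decomposition, not by the coefficient sign.
#'
#' @param mat a [bone_material()].
#' @param geom a [cutter_geometry()].
#' @param direction cutting direction (1/2/3 or name).
#' @param h uncut chip thickness in m (>= 0). Vectorised.
#' @param slipline_length `"product"` reads the contact length as
#'   `re * sin(eta)` (default); `"quotient"` as `re / sin(eta)`, an
#'   alternative typographic reading with a roughly two-orders-of-magnitude
#'   effect on ploughing magnitude.
#' @return list with numeric vectors `Ktp`, `Krp` (N per m of edge length).
#' @export
ploughing_coefficients <- function(mat, geom, direction, h,
                                   slipline_length = c("product", "quotient")) {
  slipline_length <- match.arg(slipline_length)
  i <- as_direction(direction)
  tau <- shear_strength(mat, i)
  mu <- friction_coefficient(mat, i)
  eta <- slip_line_angle(mu)
  l_MN <- if (slipline_length == "product") {
    geom$re * sin(eta)
  } else {
    if (sin(eta) == 0) stop_numeric("slip-line angle is zero; quotient length undefined")
    geom$re / sin(eta)
  }
  Fp_b <- tau * cos(2 * eta) * l_MN
  gamma_e <- equivalent_rake_angle(h, geom)
  list(Ktp = Fp_b * abs(sin(gamma_e)), Krp = Fp_b * cos(gamma_e))
}

#' Full coefficient set for one direction and chip thickness
#'
#' Convenience wrapper bundling [shear_coefficients()] (h-independent) and
#' [ploughing_coefficients()] (h-dependent) into the five-coefficient set the
#' force integration consumes.
#'
#' @inheritParams ploughing_coefficients
#' @inheritParams shear_coefficients
#' @return tibble with columns `h`, `Ktc`, `Krc`, `Kac`, `Ktp`, `Krp`.
#' @export
coefficient_set <- function(mat, geom, direction, h, armarego_sqrt = TRUE,
                            slipline_length = "product") {
  ks <- shear_coefficients(mat, geom, direction, armarego_sqrt = armarego_sqrt)
  kp <- ploughing_coefficients(mat, geom, direction, h, slipline_length = slipline_length)
  tibble::tibble(
    h = h,
    Ktc = ks[["Ktc"]], Krc = ks[["Krc"]], Kac = ks[["Kac"]],
    Ktp = kp$Ktp, Krp = kp$Krp
  )
}
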