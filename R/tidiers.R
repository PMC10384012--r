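#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a force trace into long format
#'
#' @param x a `mill_force_trace`.
#' @param ... unused.
#' @return tibble with columns `t`, `theta_deg`, `revolution`, `component`,
#'   `force_N`.
#' @export
tidy.mill_force_trace <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = c("Fx", "Fy", "Fz"),
    names_to = "component", values_to = "force_N"
  )
}

#' One-row summary of a force trace
#'
#' Steady-state (post revolution 1) peak and RMS forces plus grid metadata.
#' RMS here is unfiltered; see [rms_force()] for the filtered summary.
#'
#' @param x a `mill_force_trace`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.mill_force_trace <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_revolutions = length(unique(x$revolution)),
    dt = attr(x, "params")$dt,
    peak_fx = max(abs(x$Fx)), peak_fy = max(abs(x$Fy)), peak_fz = max(abs(x$Fz)),
    rms_fx = rms(x$Fx), rms_fy = rms(x$Fy), rms_fz = rms(x$Fz)
  )
}

#' Tidy a thickness profile
#'
#' @param x a `mill_thickness_profile`.
#' @param ... unused.
#' @return tibble in display units: `t`, `tooth`, `theta_deg`, `h_um`,
#'   `case_tag`, `revolution`.
#' @export
tidy.mill_thickness_profile <- function(x, ...) {
  tibble::tibble(
    t = x$t, tooth = x$tooth,
    theta_deg = rad2deg(x$theta), h_um = m2um(x$h),
    case_tag = x$case_tag, revolution = x$revolution
  )
}

#' One-row summary of a thickness profile
#'
#' Peak and mean engaged thickness per tooth and the share of empty-cutting
#' (separation) samples inside the engagement arc, after discarding
#' revolution 1.
#'
#' @param x a `mill_thickness_profile`.
#' @param ... unused.
#' @return tibble with one row per tooth.
#' @export
glance.mill_thickness_profile <- function(x, ...) {
  ss <- x[x$revolution >= 2L & x$case_tag != "not-engaged", ]
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ss), .data$tooth),
    peak_h_um = m2um(max(.data$h)),
    mean_h_um = m2um(mean(.data$h)),
    empty_fraction = mean(.data$h == 0),
    .groups = "drop"
  )
}

#' Tidy a sweep summary
#'
#' @param x a `mill_sweep`.
#' @param ... unused.
#' @return the sweep as a plain tibble.
#' @export
tidy.mill_sweep <- function(x, ...) tibble::as_tibble(x)
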