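#' Plot a force trace
#'
#' Feed-direction and normal-direction force against the unwrapped tooth
#' angle, one panel per component.
#'
#' @param object a `mill_force_trace`.
#' @param components which force components to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mill_force_trace <- function(object, components = c("Fx", "Fy"), ...) {
  df <- tidy(object)
  df <- df[df$component %in% components, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_deg, y = .data$force_N)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "tooth position angle (deg)", y = "force (N)") +
    ggplot2::theme_minimal()
}

#' Plot a chip-thickness profile
#'
#' Instantaneous uncut chip thickness against tooth angle, coloured by
#' tooth, showing the oscillation and tool-workpiece separation intervals
#' under vibration and the long/short-tooth split under runout.
#'
#' @param object a `mill_thickness_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mill_thickness_profile <- function(object, ...) {
  df <- tibble::tibble(
    theta_deg = rad2deg(object$theta),
    h_um = m2um(object$h),
    tooth = factor(object$tooth)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_deg, y = .data$h_um,
                                   colour = .data$tooth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "tooth position angle (deg)",
                  y = "cutting thickness (um)", colour = "tooth") +
    ggplot2::theme_minimal()
}

#' Plot a sweep summary
#'
#' Filtered RMS force against the swept factor (vibration amplitude,
#' frequency, or cutting direction).
#'
#' @param object a `mill_sweep` from [run_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mill_sweep <- function(object, ...) {
  axis <- attr(object, "axis")
  xvar <- switch(axis,
    direction = "direction",
    amplitude = "amplitude_um",
    frequency = "frequency_Hz"
  )
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c(xvar, "rms_fx", "rms_fy")],
    cols = c("rms_fx", "rms_fy"),
    names_to = "component", values_to = "rms_N"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$rms_N,
                                   colour = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = axis, y = "RMS force (N)", colour = NULL) +
    ggplot2::theme_minimal()
}
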