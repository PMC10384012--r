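#' Single-factor experiment grid
#'
#' The 14-run single-factor design used for the bone-milling study: fixed
#' process block (3000 rpm, fz = 10 um/tooth, H = 100 um, phase preset
#' sin-cos, equal X/Y amplitude and frequency), varying one factor at a
#' time. Groups 1-3 are conventional milling (A = 0, f = 0) in the three
#' cutting directions; 4-6 vibrate at A = 1 um, f = 3000 Hz across
#' directions; 7-11 sweep amplitude at f = 3000 Hz in the parallel
#' direction; 12-14 sweep frequency at A = 1.5 um.
#'
#' @return tibble with columns `group`, `direction`, `amplitude_um`,
#'   `frequency_Hz`.
#' @export
single_factor_grid <- function() {
  tibble::tibble(
    group = 1:14,
    direction = c(1L, 2L, 3L, 1L, 2L, 3L, rep(1L, 8)),
    amplitude_um = c(0, 0, 0, 1, 1, 1, 0.5, 1.5, 2, 2.5, 3, 1.5, 1.5, 1.5),
    frequency_Hz = c(0, 0, 0, 3000, 3000, 3000, rep(3000, 5), 1000, 2000, 4000)
  )
}

# Butterworth low-pass as second-order sections (analytic pole pairs put
# through the bilinear transform with prewarping). Direct high-order designs
# are ill-conditioned at the very low normalised cutoffs a fast simulation
# grid implies; sections stay stable.
butter_sos <- function(order, cutoff_hz, fs) {
  wc <- 2 * fs * tan(pi * cutoff_hz / fs) # prewarped analog cutoff (rad/s)
  k <- seq_len(order)
  poles <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  sections <- list()
  used <- rep(FALSE, order)
  for (m in seq_len(order)) {
    if (used[m]) next
    p <- poles[m]
    if (abs(Im(p)) < 1e-9 * abs(p)) {
      used[m] <- TRUE
      # first-order section: H(s) = wc' / (s + wc') with wc' = -Re(p)
      a0 <- -Re(p)
      # bilinear s = 2 fs (z-1)/(z+1)
      c <- 2 * fs
      b <- c(a0, a0) / (c + a0)
      a <- c(1, (a0 - c) / (c + a0))
      sections[[length(sections) + 1]] <- list(b = b, a = a)
    } else {
      conj_idx <- which(!used & abs(poles - Conj(p)) < 1e-6 * abs(p))
      used[m] <- TRUE
      used[conj_idx[1]] <- TRUE
      # H(s) = wn^2 / (s^2 + 2 zeta wn s + wn^2)
      wn2 <- Mod(p)^2
      two_zeta_wn <- -2 * Re(p)
      c <- 2 * fs
      den0 <- c^2 + two_zeta_wn * c + wn2
      b <- wn2 * c(1, 2, 1) / den0
      a <- c(1, (2 * wn2 - 2 * c^2) / den0, (c^2 - two_zeta_wn * c + wn2) / den0)
      sections[[length(sections) + 1]] <- list(b = b, a = a)
    }
  }
  sections
}

# Zero-phase pass through all sections. The ends are extended with an odd
# (point-symmetric) reflection long enough for the zero-state transient to
# die inside the padding, then trimmed; without this the start-up transient
# of the backward pass would leak into the steady-state window.
filtfilt_sos <- function(x, sections, padlen) {
  n <- length(x)
  p <- min(n - 1L, padlen)
  x_ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  for (s in sections) {
    x_ext <- signal::filtfilt(s$b, s$a, x_ext)
  }
  x_ext[(p + 1):(p + n)]
}

#' Zero-phase low-pass filtering of a force trace
#'
#' Butterworth low-pass (default 4th order at 120 Hz, the cutoff used to
#' strip spindle/vibration harmonics before RMS comparison), applied forward
#' and backward for zero phase, as cascaded second-order sections. DC gain
#' is exactly 1.
#'
#' @param trace a `mill_force_trace` (regular time grid required).
#' @param cutoff_hz cutoff frequency (Hz), must be below the trace Nyquist.
#' @param order filter order.
#' @return the trace with `Fx`, `Fy`, `Fz` replaced by their filtered
#'   versions.
#' @export
lowpass_filter <- function(trace, cutoff_hz = 120, order = 4) {
  dt <- unique(round(diff(trace$t), 12))
  if (length(dt) != 1L) stop_input("trace must be on a regular time grid")
  fs <- 1 / dt
  check_number(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE)
  if (cutoff_hz >= fs / 2) {
    stop_input("cutoff %g Hz is not below the trace Nyquist %g Hz", cutoff_hz, fs / 2)
  }
  sos <- butter_sos(order, cutoff_hz, fs)
  padlen <- as.integer(ceiling(6 * fs / cutoff_hz))
  out <- trace
  out$Fx <- filtfilt_sos(trace$Fx, sos, padlen)
  out$Fy <- filtfilt_sos(trace$Fy, sos, padlen)
  out$Fz <- filtfilt_sos(trace$Fz, sos, padlen)
  tibble::new_tibble(out, params = attr(trace, "params"),
                     class = c("mill_force_trace", "tbl_df"))
}

#' Root-mean-square of a signal
#'
#' @param values nonempty numeric vector.
#' @return `sqrt(mean(values^2))`.
#' @export
rms <- function(values) {
  if (!is.numeric(values) || !length(values)) stop_input("`values` must be a nonempty numeric vector")
  sqrt(mean(values^2))
}

#' RMS force summary over steady-state revolutions
#'
#' RMS of Fx and Fy over the last `floor(n_rev - 1)` full revolutions of the
#' trace (an integer number of revolutions, excluding the start-up
#' transient).
#'
#' @param trace a `mill_force_trace`.
#' @param cutoff_hz low-pass cutoff applied first (NULL to skip).
#' @param order filter order.
#' @return one-row tibble with `rms_fx`, `rms_fy`, `rms_fz`, `n_revolutions`.
#' @export
rms_force <- function(trace, cutoff_hz = 120, order = 4) {
  if (!is.null(cutoff_hz)) trace <- lowpass_filter(trace, cutoff_hz, order)
  revs <- sort(unique(trace$revolution))
  keep <- utils::tail(revs, max(1L, length(revs) - 1L))
  tr <- trace[trace$revolution %in% keep, ]
  tibble::tibble(
    rms_fx = rms(tr$Fx), rms_fy = rms(tr$Fy), rms_fz = rms(tr$Fz),
    n_revolutions = length(keep)
  )
}

#' Run a single-factor sweep of the experiment grid
#'
#' Simulates the relevant rows of [single_factor_grid()] for one sweep axis, then
#' reports filtered steady-state RMS forces and the percent change against
#' the conventional-milling baseline of the matching cutting direction
#' (groups 1-3). Axes: `"direction"` (groups 4-6 vs baselines 1-3),
#' `"amplitude"` (1, 4, 7-11), `"frequency"` (1, 8, 12-14).
#'
#' @param axis sweep axis.
#' @param mat a [bone_material()].
#' @param geom a [cutter_geometry()].
#' @param n_revolutions revolutions per simulation (>= 2).
#' @param cutoff_hz low-pass cutoff for the RMS summaries.
#' @param specs optional replacement grid (same columns as [single_factor_grid()]).
#' @param ... passed to [simulate_milling()].
#' @return a `mill_sweep` tibble: the grid columns plus `rms_fx`, `rms_fy`,
#'   `pct_fx`, `pct_fy` (percent change vs the matched baseline; NA for the
#'   baseline rows themselves).
#' @export
run_sweep <- function(axis = c("direction", "amplitude", "frequency"),
                      mat = bone_material(), geom = cutter_geometry(),
                      n_revolutions = 3, cutoff_hz = 120,
                      specs = single_factor_grid(), ...) {
  axis <- match.arg(axis)
  groups <- switch(axis,
    direction = c(1:3, 4:6),
    amplitude = c(1L, 4L, 7:11),
    frequency = c(1L, 8L, 12:14)
  )
  rows <- specs[specs$group %in% groups, ]
  sims <- purrr::pmap(rows, function(group, direction, amplitude_um, frequency_Hz) {
    vib <- vibration_params(amplitude_um, amplitude_um, frequency_Hz, frequency_Hz,
                            phase = "sin-cos")
    proc <- process_params(direction = direction)
    trace <- simulate_milling(mat, geom, vib, proc,
                              n_revolutions = n_revolutions, ...)
    rms_force(trace, cutoff_hz = cutoff_hz)
  })
  out <- dplyr::bind_cols(rows, dplyr::bind_rows(sims))
  base <- out[out$amplitude_um == 0 & out$frequency_Hz == 0, ]
  bi <- match(out$direction, base$direction)
  out$pct_fx <- (out$rms_fx - base$rms_fx[bi]) / base$rms_fx[bi] * 100
  out$pct_fy <- (out$rms_fy - base$rms_fy[bi]) / base$rms_fy[bi] * 100
  is_base <- out$amplitude_um == 0 & out$frequency_Hz == 0
  out$pct_fx[is_base] <- NA_real_
  out$pct_fy[is_base] <- NA_real_
  tibble::new_tibble(out, axis = axis,
                     class = c("mill_sweep", "tbl_df"))
}

#' Synthesise a dynamometer-like experimental trace
#'
#' Resamples a model trace to a stated acquisition rate and adds seeded
#' Gaussian noise, standing in for a dynamometer recording so the
#' model-vs-experiment comparison pipeline can run offline. Deterministic
#' for a given seed.
#'
#' @param trace a `mill_force_trace`.
#' @param noise_sd noise standard deviation (N), >= 0.
#' @param seed integer RNG seed.
#' @param rate_hz acquisition rate of the synthetic instrument (Hz).
#' @return tibble with columns `t`, `Fx`, `Fy`, `Fz`.
#' @export
synth_experimental_trace <- function(trace, noise_sd = 0.02, seed = 1,
                                     rate_hz = 10000) {
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  t_new <- seq(min(trace$t), max(trace$t), by = 1 / rate_hz)
  out <- tibble::tibble(
    t = t_new,
    Fx = stats::approx(trace$t, trace$Fx, xout = t_new)$y,
    Fy = stats::approx(trace$t, trace$Fy, xout = t_new)$y,
    Fz = stats::approx(trace$t, trace$Fz, xout = t_new)$y
  )
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    n <- nrow(out)
    out$Fx <- out$Fx + stats::rnorm(n, sd = noise_sd)
    out$Fy <- out$Fy + stats::rnorm(n, sd = noise_sd)
    out$Fz <- out$Fz + stats::rnorm(n, sd = noise_sd)
  }
  out
}

#' Compare a model trace against an experimental recording
#'
#' Interpolates the experimental record (columns `t`, `Fx`, `Fy`; `t_s`,
#' `Fx_N`, `Fy_N` also accepted) onto the model grid, low-pass filters both,
#' and reports RMS values and percent RMS error per component.
#'
#' @param model a `mill_force_trace`.
#' @param experiment a data frame with time and force columns.
#' @param cutoff_hz zero-phase low-pass cutoff (Hz).
#' @return one-row tibble: `rms_fx_model`, `rms_fx_exp`, `err_fx_pct`, and
#'   the same for Fy.
#' @export
compare_traces <- function(model, experiment, cutoff_hz = 120) {
  nm <- names(experiment)
  tcol <- if ("t" %in% nm) "t" else if ("t_s" %in% nm) "t_s" else
    stop_input("experiment needs a `t` (or `t_s`) column")
  fx <- if ("Fx" %in% nm) "Fx" else if ("Fx_N" %in% nm) "Fx_N" else
    stop_input("experiment needs an `Fx` (or `Fx_N`) column")
  fy <- if ("Fy" %in% nm) "Fy" else if ("Fy_N" %in% nm) "Fy_N" else
    stop_input("experiment needs an `Fy` (or `Fy_N`) column")
  exp_fx <- stats::approx(experiment[[tcol]], experiment[[fx]], xout = model$t, rule = 2)$y
  exp_fy <- stats::approx(experiment[[tcol]], experiment[[fy]], xout = model$t, rule = 2)$y
  exp_trace <- model
  exp_trace$Fx <- exp_fx; exp_trace$Fy <- exp_fy; exp_trace$Fz <- 0
  mod_f <- rms_force(model, cutoff_hz = cutoff_hz)
  exp_f <- rms_force(exp_trace, cutoff_hz = cutoff_hz)
  tibble::tibble(
    rms_fx_model = mod_f$rms_fx, rms_fx_exp = exp_f$rms_fx,
    err_fx_pct = abs(mod_f$rms_fx - exp_f$rms_fx) / exp_f$rms_fx * 100,
    rms_fy_model = mod_f$rms_fy, rms_fy_exp = exp_f$rms_fy,
    err_fy_pct = abs(mod_f$rms_fy - exp_f$rms_fy) / exp_f$rms_fy * 100
  )
}
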