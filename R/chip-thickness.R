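#' Collinearity residual between the tool-radius ray and a prior pass
#'
#' The instantaneous uncut chip thickness is measured along the ray from the
#' tool centre O(t) through the current tip B(t). A point P_s on an earlier
#' tip trajectory contributes material boundary where O, B and P_s are
#' collinear. This function returns the (dimensionless) cross-product form of
#' that condition,
#' \deqn{[(x_o-x)(y-y_s) - (y_o-y)(x-x_s)] / r^2,}
#' which is zero iff P_s(t_s) lies on the line through O and B.
#'
#' @param t query time (s), scalar.
#' @param t_s candidate earlier time(s) (s), vectorised.
#' @param j tooth index of the current tip.
#' @param j_prev tooth index of the earlier trajectory (`j - 1` for the
#'   preceding tooth, `j` for the same tooth one revolution earlier; indices
#'   outside `0:(N-1)` are interpreted modulo N by the trajectory equations).
#' @param geom,vib,proc parameter objects.
#' @return residual value(s), normalised by r^2.
#' @export
collinearity_residual <- function(t, t_s, j, j_prev, geom, vib, proc) {
  v <- feed_speed(proc, geom)
  th <- tooth_angle(t, j, geom, proc)
  tip <- .tip_xy(t, j, geom, vib, proc, v)
  ps <- .tip_xy(t_s, j_prev, geom, vib, proc, v)
  # (xo - x, yo - y) = -r (sin th, cos th) exactly, so the r^2-normalised
  # cross product collapses to this form.
  (cos(th) * (tip$x - ps$x) - sin(th) * (tip$y - ps$y)) / geom$r
}

# Find, for each query time, the governing candidate surface from ONE prior
# trajectory window. Returns per-query h of the ray/trajectory crossing with
# the smallest h (NA when no admissible crossing), plus its t_s.
#
# t, lo, hi: equal-length vectors; queries with hi <= lo are skipped.
.window_candidates <- function(t, j, j_prev, lo, hi, geom, vib, proc,
                               n_scan = 200, bisect_iter = 52) {
  n <- length(t)
  h_best <- rep(NA_real_, n)
  ts_best <- rep(NA_real_, n)
  ok <- which(hi > lo)
  if (!length(ok)) {
    return(list(h = h_best, t_s = ts_best))
  }

  v <- feed_speed(proc, geom)
  th <- tooth_angle(t, j, geom, proc)
  ctr <- .center_xy(t, geom, vib, proc, v)
  sin_th <- sin(th)
  cos_th <- cos(th)

  resid_at <- function(rows, ts) {
    ps <- .tip_xy(ts, j_prev, geom, vib, proc, v)
    # cross((sin,cos), P_s - O): zero iff P_s on the O->B line
    (sin_th[rows] * (ps$y - ctr$y[rows]) - cos_th[rows] * (ps$x - ctr$x[rows]))
  }

  # scan grid: rows = queries, cols = n_scan + 1 samples of the window
  s <- seq(0, 1, length.out = n_scan + 1)
  rows <- rep(ok, times = n_scan + 1)
  tsg <- rep(lo[ok], times = n_scan + 1) +
    rep(hi[ok] - lo[ok], times = n_scan + 1) * rep(s, each = length(ok))
  rg <- matrix(resid_at(rows, tsg), nrow = length(ok))
  tsg <- matrix(tsg, nrow = length(ok))

  sgn <- sign(rg)
  change <- sgn[, -1, drop = FALSE] * sgn[, -ncol(sgn), drop = FALSE] <= 0 &
    (sgn[, -1, drop = FALSE] != 0 | sgn[, -ncol(sgn), drop = FALSE] != 0)
  idx <- which(change, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(list(h = h_best, t_s = ts_best))
  }

  q <- ok[idx[, 1]] # query row of each bracketing interval
  a <- tsg[idx]
  b <- tsg[cbind(idx[, 1], idx[, 2] + 1L)]
  fa <- rg[idx]
  for (k in seq_len(bisect_iter)) {
    m <- 0.5 * (a + b)
    fm <- resid_at(q, m)
    left <- fa * fm > 0
    a <- ifelse(left, m, a)
    fa <- ifelse(left, fm, fa)
    b <- ifelse(left, b, m)
  }
  root <- 0.5 * (a + b)

  ps <- .tip_xy(root, j_prev, geom, vib, proc, v)
  dx <- ps$x - ctr$x[q]
  dy <- ps$y - ctr$y[q]
  # ray parameter: P_s must sit on the workpiece side of the centre
  u <- (dx * sin_th[q] + dy * cos_th[q]) / geom$r
  keep <- u > 1e-3
  if (!any(keep)) {
    return(list(h = h_best, t_s = ts_best))
  }
  q <- q[keep]
  root <- root[keep]
  h <- geom$r - sqrt(dx[keep]^2 + dy[keep]^2)

  # innermost prior contour governs: keep the minimum h per query
  o <- order(q, h)
  first <- !duplicated(q[o])
  qf <- q[o][first]
  h_best[qf] <- h[o][first]
  ts_best[qf] <- root[o][first]
  list(h = h_best, t_s = ts_best)
}

# Resolve thickness for one tooth at a vector of query times.
# Returns a data.frame-compatible list of columns.
.resolve_thickness <- function(t, j, geom, vib, proc, n_scan = 200,
                               chunk = 6000L) {
  n <- length(t)
  if (!n) {
    return(tibble::tibble(
      t = numeric(), tooth = integer(), theta = numeric(), h = numeric(),
      case_tag = character(), t_s = numeric()
    ))
  }
  omega <- proc$omega
  N <- geom$n_flutes
  T_tooth <- 2 * pi / (omega * N)
  T_rev <- 2 * pi / omega
  delta <- 0.5 * T_tooth
  theta <- tooth_angle(t, j, geom, proc)
  th_mod <- theta %% (2 * pi)
  engaged <- th_mod <= pi # slot milling: theta_d = pi

  h <- numeric(n)
  ts_out <- rep(NA_real_, n)
  tags <- rep("not-engaged", n)

  eng <- which(engaged)
  for (start in if (length(eng)) seq(1, length(eng), by = chunk) else integer()) {
    ii <- eng[start:min(start + chunk - 1L, length(eng))]
    ti <- t[ii]

    # previous tooth's pass
    prev <- .window_candidates(
      ti, j, j - 1L,
      lo = pmax(0, ti - T_tooth - delta), hi = ti,
      geom = geom, vib = vib, proc = proc, n_scan = n_scan
    )
    # same tooth, one revolution earlier
    same <- .window_candidates(
      ti, j, j,
      lo = pmax(0, ti - T_rev - delta), hi = pmax(0, ti - T_tooth),
      geom = geom, vib = vib, proc = proc, n_scan = n_scan
    )

    use_same <- !is.na(same$h) & (is.na(prev$h) | same$h < prev$h)
    hc <- ifelse(use_same, same$h, prev$h)
    tsc <- ifelse(use_same, same$t_s, prev$t_s)
    src <- ifelse(use_same, "same-tooth", "different-tooth")

    none <- is.na(hc)
    startup <- none & ti < T_rev
    # first pass: no prior surface yet -- cut against the ideal initial arc,
    # which the classical circular-tooth-path thickness approximates
    hc[startup] <- pmax(0, proc$fz * sin(th_mod[ii][startup]))
    src[startup] <- "different-tooth"
    hc[none & !startup] <- -Inf
    src[none & !startup] <- "different-tooth"

    hi_clamped <- pmax(0, hc)
    tag <- ifelse(hi_clamped > 0, paste0("chip-", src), paste0("empty-", src))
    h[ii] <- hi_clamped
    ts_out[ii] <- ifelse(hi_clamped > 0, tsc, NA_real_)
    tags[ii] <- tag
  }

  tibble::tibble(
    t = t, tooth = as.integer(j), theta = theta, h = h,
    case_tag = tags, t_s = ts_out
  )
}

#' Solve for the matching time on a prior tip trajectory
#'
#' Finds the earlier time t_s at which the previous tooth's trajectory
#' (`which = "previous-tooth"`) or the same tooth's previous revolution
#' (`which = "same-tooth"`) crosses the current tool-radius ray. The window
#' is scanned for sign changes of [collinearity_residual()] and each bracket
#' is bisected; among admissible crossings (positive ray parameter) the one
#' bounding the least material (smallest h) is returned.
#'
#' @param t query time (s), scalar.
#' @param j tooth index.
#' @param which `"previous-tooth"` or `"same-tooth"`.
#' @param geom,vib,proc parameter objects.
#' @param n_scan number of scan points used to bracket roots.
#' @return the matched time t_s (s), or `NA` when the window contains no
#'   admissible crossing.
#' @export
solve_previous_time <- function(t, j, which = c("previous-tooth", "same-tooth"),
                                geom, vib, proc, n_scan = 200) {
  which <- match.arg(which)
  check_number(t, "t", lower = 0)
  omega <- proc$omega
  N <- geom$n_flutes
  T_tooth <- 2 * pi / (omega * N)
  T_rev <- 2 * pi / omega
  delta <- 0.5 * T_tooth
  if (which == "previous-tooth") {
    res <- .window_candidates(t, j, j - 1L,
      lo = max(0, t - T_tooth - delta), hi = t,
      geom = geom, vib = vib, proc = proc, n_scan = n_scan
    )
  } else {
    res <- .window_candidates(t, j, j,
      lo = max(0, t - T_rev - delta), hi = max(0, t - T_tooth),
      geom = geom, vib = vib, proc = proc, n_scan = n_scan
    )
  }
  res$t_s[[1]]
}

#' Instantaneous uncut chip thickness at given times
#'
#' Resolves the chip thickness h(t, j) for tooth `j` at the query times `t`.
#' For each query the solver intersects the current tool-radius ray with the
#' two candidate prior surfaces (previous tooth's pass; same tooth one
#' revolution earlier), takes the innermost crossing (minimum h over all
#' admissible candidates -- the surface actually left in the material), and
#' clamps at zero when the tip lies inside an already-cleared region (empty
#' cutting). Four cutting cases are tagged: chip/empty formed against the
#' other tooth's trajectory or the same tooth's, plus `not-engaged` outside
#' the slot-milling arc.
#'
#' @param t query time(s) (s), vectorised.
#' @param j tooth index in `0:(N-1)`.
#' @param geom,vib,proc parameter objects.
#' @param n_scan scan resolution for root bracketing.
#' @return tibble with columns `t`, `tooth`, `theta` (rad, unwrapped), `h`
#'   (m), `case_tag`, `t_s` (s or NA).
#' @examples
#' geom <- cutter_geometry(runout_um = 0)
#' proc <- process_params()
#' vib <- vibration_params()
#' # near theta = pi/2 in steady state, h is close to the feed per tooth
#' t_q <- (2 * pi + pi / 2) / proc$omega
#' chip_thickness_at(t_q, 0, geom, vib, proc)
#' @export
chip_thickness_at <- function(t, j, geom, vib, proc, n_scan = 200) {
  if (j < 0 || j >= geom$n_flutes) stop_input("tooth index out of range")
  .resolve_thickness(t, j, geom, vib, proc, n_scan = n_scan)
}

#' Per-tooth chip-thickness profile over several revolutions
#'
#' Runs the chip-thickness solver for every tooth on a regular time grid and
#' returns the stacked samples, suitable for force integration and for
#' thickness-vs-tooth-angle plots. The first revolution contains the
#' start-up transient (no prior surface) and is retained here, flagged by
#' the `revolution` column; downstream force summaries discard it.
#'
#' @param geom,vib,proc parameter objects.
#' @param n_revolutions number of spindle revolutions to simulate (>= 2).
#' @param dt time step (s); defaults to [default_dt()].
#' @param n_scan scan resolution for root bracketing.
#' @return a `mill_thickness_profile` tibble with columns `t`, `tooth`,
#'   `theta` (rad), `h` (m), `case_tag`, `t_s`, `revolution`; the generating
#'   parameters are stored in `attr(, "params")`.
#' @export
thickness_profile <- function(geom, vib, proc, n_revolutions = 3, dt = NULL,
                              n_scan = 200) {
  if (n_revolutions < 2) stop_input("`n_revolutions` must be at least 2")
  if (is.null(dt)) dt <- default_dt(geom, vib, proc)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  T_rev <- 2 * pi / proc$omega
  t <- seq(dt, n_revolutions * T_rev, by = dt)
  out <- purrr::map(0:(geom$n_flutes - 1L), function(j) {
    .resolve_thickness(t, j, geom, vib, proc, n_scan = n_scan)
  })
  out <- dplyr::bind_rows(out)
  out$revolution <- as.integer(ceiling(out$t / T_rev - 1e-12))
  params <- list(geom = geom, vib = vib, proc = proc, dt = dt,
                 n_revolutions = n_revolutions, n_scan = n_scan)
  tibble::new_tibble(out, params = params,
                     class = c("mill_thickness_profile", "tbl_df"))
}

#' Export a thickness profile as CSV
#'
#' Writes the profile in display units (`t_s_s`, `tooth`, `theta_deg`,
#' `h_um`, `case_tag`, plus the matched prior-pass time `t_match_s`),
#' matching thickness-vs-tooth-angle plots.
#'
#' @param profile a [thickness_profile()].
#' @param path output CSV path.
#' @return the written tibble, invisibly.
#' @export
write_thickness_csv <- function(profile, path) {
  df <- tibble::tibble(
    t_s_s = profile$t,
    tooth = profile$tooth,
    theta_deg = rad2deg(profile$theta),
    h_um = m2um(profile$h),
    case_tag = profile$case_tag,
    t_match_s = profile$t_s
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
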