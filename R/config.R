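#' Read a simulation configuration file
#'
#' Reads a YAML (or JSON) configuration with optional blocks `material`,
#' `cutter`, `vibration`, `process`, `options`, in workshop units (MPa, um,
#' deg, Hz, rpm), and returns the corresponding parameter objects with
#' package defaults filling any missing entry.
#'
#' Block fields:
#' * `material`: `tau_s_MPa` (length 3), `mu` (length 3) -- or a per-direction
#'   mapping `{parallel: {tau_s_MPa:, mu:}, ...}`.
#' * `cutter`: [cutter_geometry()] arguments.
#' * `vibration`: `Ax_um`, `Ay_um`, `fx_Hz`, `fy_Hz`, and either
#'   `phase_preset` or `phix_deg`/`phiy_deg`.
#' * `process`: [process_params()] arguments (direction code or name).
#' * `options`: `n_revolutions`, `dt`, `n_slices`, `armarego_sqrt`,
#'   `slipline_length`, `ploughing`, `Kap`, `flip_y`, `cutoff_hz`.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return list with `mat`, `geom`, `vib`, `proc`, `options`.
#' @export
read_mill_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mill_config(cfg)
}

#' Build parameter objects from a configuration list
#'
#' @param cfg nested list as described in [read_mill_config()].
#' @return list with `mat`, `geom`, `vib`, `proc`, `options`.
#' @export
mill_config <- function(cfg = list()) {
  mb <- cfg$material
  mat <- if (is.null(mb)) {
    bone_material()
  } else if (!is.null(mb$tau_s_MPa)) {
    bone_material(tau_s_MPa = unlist(mb$tau_s_MPa), mu = unlist(mb$mu))
  } else {
    dirs <- direction_names()
    if (!all(dirs %in% names(mb))) {
      stop_input("material block needs tau_s_MPa/mu vectors or one entry per direction")
    }
    bone_material(
      tau_s_MPa = vapply(dirs, function(d) mb[[d]]$tau_s_MPa, numeric(1)),
      mu = vapply(dirs, function(d) mb[[d]]$mu, numeric(1))
    )
  }

  geom <- do.call(cutter_geometry, as.list(cfg$cutter %||% list()))

  vb <- cfg$vibration %||% list()
  phase <- if (!is.null(vb$phase_preset)) {
    vb$phase_preset
  } else if (!is.null(vb$phix_deg) || !is.null(vb$phiy_deg)) {
    c(vb$phix_deg %||% 0, vb$phiy_deg %||% 0)
  } else {
    "sin-cos"
  }
  vib <- vibration_params(
    Ax_um = vb$Ax_um %||% 0, Ay_um = vb$Ay_um %||% 0,
    fx_Hz = vb$fx_Hz %||% 0, fy_Hz = vb$fy_Hz %||% 0, phase = phase
  )

  proc <- do.call(process_params, as.list(cfg$process %||% list()))

  opts <- cfg$options %||% list()
  opts$n_revolutions <- opts$n_revolutions %||% 3
  opts$cutoff_hz <- opts$cutoff_hz %||% 120

  list(mat = mat, geom = geom, vib = vib, proc = proc, options = opts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
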