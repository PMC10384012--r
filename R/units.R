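# Internal unit helpers. Everything inside the package is SI (m, Pa, N, rad, s);
# user-facing constructors accept the workshop units (um, MPa, deg, rpm) and
# convert once at the boundary.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
um2m <- function(x) x * 1e-6
m2um <- function(x) x * 1e6
MPa2Pa <- function(x) x * 1e6

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "osteomill_invalid_input")
}

stop_numeric <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "osteomill_numerical_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_input("`%s` = %g is outside its valid range", name, x)
  }
  invisible(x)
}
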