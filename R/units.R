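# Unit registry: multiplicative factor taking a quantity in `unit` to SI.
# Temperatures are handled in degrees Celsius at all interfaces (converted to
# kelvin only inside the Arrhenius integrand), so "degC" is an identity unit.
.unit_factors <- c(
  # inverse length
  "m^-1" = 1, "1/m" = 1, "cm^-1" = 100, "1/cm" = 100, "mm^-1" = 1000,
  "1/mm" = 1000,
  # length
  "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6,
  # time and rate
  "s" = 1, "ms" = 1e-3, "min" = 60, "s^-1" = 1, "1/s" = 1, "1/min" = 1 / 60,
  # power
  "W" = 1, "mW" = 1e-3, "kW" = 1e3,
  # density
  "kg/m^3" = 1, "kg m^-3" = 1, "g/cm^3" = 1000,
  # specific heat / conductivity
  "J kg^-1 K^-1" = 1, "J/(kg K)" = 1, "J/(kg*K)" = 1,
  "W m^-1 K^-1" = 1, "W/(m K)" = 1, "W/(m*K)" = 1,
  # molar energy (Arrhenius activation energy)
  "J mol^-1" = 1, "J/mol" = 1, "kJ/mol" = 1e3, "J mol^-1 K^-1" = 1,
  # magnetic / thermometry
  "T" = 1, "MHz/T" = 1e6, "Hz/T" = 1, "ppm/degC" = 1e-6, "ppm/C" = 1e-6,
  # misc identities
  "degC" = 1, "C" = 1, "rad" = 1, "W/m^2" = 1, "W m^-2" = 1
)

#' Convert a physical quantity to or from SI units
#'
#' `to_si()` multiplies by the unit's SI factor, `from_si()` divides; the two
#' are exact inverses. Units are purely multiplicative (temperatures are kept
#' in degrees Celsius throughout and use the identity unit `"degC"`).
#'
#' @param value numeric vector.
#' @param unit unit string, e.g. `"cm^-1"`, `"mm"`, `"1/s"`.
#' @return numeric vector in SI units (`to_si`) or in `unit` (`from_si`).
#' @examples
#' to_si(0.5, "cm^-1") # 50 m^-1
#' from_si(to_si(57, "cm^-1"), "cm^-1") # 57, round trip is exact
#' @export
to_si <- function(value, unit) value * si_factor(unit)

#' @rdname to_si
#' @export
from_si <- function(value, unit) value / si_factor(unit)

#' @rdname to_si
#' @export
si_factor <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  if (!nzchar(unit)) return(1) # dimensionless
  f <- .unit_factors[unit]
  if (is.na(f)) {
    stop("unknown unit string: '", unit, "'", call. = FALSE)
  }
  unname(f)
}

# Parse a config quantity into an SI number. Accepts a bare numeric (already
# SI), a string "value unit" such as "0.5 cm^-1", or list(value=, unit=).
parse_quantity <- function(x, what = "quantity") {
  if (is.numeric(x) && length(x) == 1L) {
    return(as.numeric(x))
  }
  if (is.list(x) && !is.null(x$value)) {
    return(to_si(as.numeric(x$value), x$unit %||% ""))
  }
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    value <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(value)) {
      stop("cannot parse ", what, " from '", x, "'", call. = FALSE)
    }
    unit <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""
    return(to_si(value, unit))
  }
  stop("cannot parse ", what, ": expected a number, 'value unit' string, ",
       "or list(value=, unit=)", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_positive <- function(x, name, strict = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || (if (strict) x <= 0 else x < 0)) {
    stop(name, " must be a ", if (strict) "positive" else "non-negative",
         " finite number, got ", deparse(substitute(x)), " = ",
         paste(format(x), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
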