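# Unit conversion layer.
#
# Everything inside the package is strict SI (m, s, kg, W, V, K and their
# products).  Laser-dosimetry literature mixes mW, fs, ns, um, cm^-1,
# J cm^-3, W cm^-3, W cm^-2 and K/m freely; a single internal system avoids
# the 1e4-1e6 scale errors that this mixture invites, so user-facing
# constructors accept quantities with explicit unit strings and convert once
# at the boundary.

# Accepted unit string -> multiplier to SI.  Aliases cover both slash
# ("J/cm^3") and exponent ("J cm-3") spellings, plus the micro sign.
.unit_table <- c(
  # time
  "fs" = 1e-15, "ps" = 1e-12, "ns" = 1e-9, "us" = 1e-6, "µs" = 1e-6,
  "μs" = 1e-6, "ms" = 1e-3, "s" = 1, "min" = 60,
  # length
  "nm" = 1e-9, "um" = 1e-6, "µm" = 1e-6, "μm" = 1e-6,
  "mm" = 1e-3, "cm" = 1e-2, "m" = 1,
  # area
  "nm^2" = 1e-18, "um^2" = 1e-12, "cm^2" = 1e-4, "m^2" = 1,
  # volume
  "um^3" = 1e-18, "mm^3" = 1e-9, "cm^3" = 1e-6, "m^3" = 1, "L" = 1e-3,
  # power
  "nW" = 1e-9, "uW" = 1e-6, "µW" = 1e-6, "μW" = 1e-6,
  "mW" = 1e-3, "W" = 1, "kW" = 1e3,
  # energy
  "nJ" = 1e-9, "uJ" = 1e-6, "mJ" = 1e-3, "J" = 1,
  # voltage
  "mV" = 1e-3, "V" = 1,
  # temperature difference
  "K" = 1, "mK" = 1e-3,
  # mass density
  "kg/m^3" = 1, "kg m-3" = 1, "g/cm^3" = 1e3, "g cm-3" = 1e3,
  # specific heat
  "J/(kg K)" = 1, "J kg-1 K-1" = 1, "J/kg/K" = 1,
  # thermal conductivity
  "W/(m K)" = 1, "W m-1 K-1" = 1, "W/m/K" = 1,
  # inverse length (absorption coefficient)
  "1/m" = 1, "m-1" = 1, "1/cm" = 1e2, "cm-1" = 1e2, "1/mm" = 1e3, "mm-1" = 1e3,
  # energy density
  "J/m^3" = 1, "J m-3" = 1, "J/cm^3" = 1e6, "J cm-3" = 1e6,
  # power density (volumetric)
  "W/m^3" = 1, "W m-3" = 1, "W/cm^3" = 1e6, "W cm-3" = 1e6,
  # power density (areal)
  "W/m^2" = 1, "W m-2" = 1, "W/cm^2" = 1e4, "W cm-2" = 1e4,
  # temperature gradient
  "K/m" = 1, "K m-1" = 1, "K/cm" = 1e2, "K/um" = 1e6, "K/µm" = 1e6,
  "K/nm" = 1e9,
  # thermoelectric conversion factor
  "K/V" = 1, "K V-1" = 1
)

#' Convert a quantity to SI units
#'
#' Accepts either a bare numeric (assumed to already be in SI) or a string of
#' the form `"<value> <unit>"` (e.g. `"24 mW"`, `"1.5 um"`, `"0.22 J/cm^3"`,
#' `"10 cm-1"`).  The set of accepted unit strings covers the units customary
#' in laser-exposure dosimetry; see [si_units()] for the full list.
#'
#' @param x numeric scalar/vector (already SI) or character scalar/vector
#'   `"value unit"`.
#' @param unit optional unit string applied to a numeric `x` (so
#'   `as_si(24, "mW")` equals `as_si("24 mW")`).
#' @return numeric vector in SI units.
#' @examples
#' as_si("24 mW")          # 0.024 W
#' as_si("100 fs")         # 1e-13 s
#' as_si("0.22 J/cm^3")    # 2.2e5 J/m^3
#' as_si(1.5, "um")        # 1.5e-6 m
#' @export
as_si <- function(x, unit = NULL) {
  if (is.numeric(x)) {
    if (is.null(unit)) return(as.numeric(x))
    return(as.numeric(x) * .unit_factor(unit))
  }
  if (!is.character(x)) {
    stop("quantity must be numeric (SI) or a 'value unit' string", call. = FALSE)
  }
  vapply(x, .parse_quantity, numeric(1), USE.NAMES = FALSE)
}

.parse_quantity <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^([-+]?[0-9.]+(?:[eE][-+]?[0-9]+)?)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L || m[2] == "") {
    stop(sprintf("cannot parse quantity '%s'", s), call. = FALSE)
  }
  value <- as.numeric(m[2])
  unit <- trimws(m[3])
  if (unit == "") return(value)  # dimensionless / already SI
  value * .unit_factor(unit)
}

.unit_factor <- function(unit) {
  f <- .unit_table[unit]
  if (is.na(f)) {
    stop(sprintf("unknown unit '%s'; see si_units() for accepted units", unit),
         call. = FALSE)
  }
  unname(f)
}

#' Convert an SI value into a display unit
#'
#' Inverse of [as_si()]: `from_si(as_si("24 mW"), "mW")` returns 24 (to
#' floating-point round-off).
#'
#' @param value numeric, in SI units.
#' @param unit target unit string.
#' @return numeric in the requested unit.
#' @export
from_si <- function(value, unit) {
  as.numeric(value) / .unit_factor(unit)
}

#' List accepted unit strings
#'
#' @return named numeric vector mapping each accepted unit string to its
#'   multiplier into SI.
#' @export
si_units <- function() .unit_table

# internal: positivity guard used by every constructor/operation
.check_positive <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single finite positive number (got %s)",
                   nm[i], paste(format(v), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}
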