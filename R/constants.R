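#' Physical constants used throughout the package
#'
#' @description
#' `R_GAS` is the universal gas constant (J/mol/K), `KB` the Boltzmann
#' constant (J/K) and `AM_WATER` the surface area occupied by one sorbed
#' water molecule (m^2). These are the values conventionally used in
#' sorption thermodynamics of food materials.
#'
#' @name constants
#' @keywords internal
NULL

#' @rdname constants
#' @export
R_GAS <- 8.314

#' @rdname constants
#' @export
KB <- 1.38e-23

#' @rdname constants
#' @export
AM_WATER <- 1.06e-19

# absolute zero offset: degrees Celsius -> Kelvin
C_TO_K <- 273.15

#' Convert between Celsius and Kelvin
#'
#' @param x temperature(s)
#' @return converted temperature(s)
#' @export
celsius_to_kelvin <- function(x) x + C_TO_K

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - C_TO_K

# internal: stop with a classed condition so tests can match on class
st_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "sorptherm_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

st_warn <- function(class, fmt, ...) {
  warning(structure(
    class = c(class, "sorptherm_warning", "warning", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
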