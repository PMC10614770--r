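#' Reduced unit system of the nucleus model
#'
#' The model works in reduced units: one reduced length unit corresponds to
#' sigma = 385 nm, one reduced time unit (Brownian dynamics) to
#' tau = 0.65 s, and the reduced temperature is T = 1.  The 5-micron
#' nuclear radius is therefore 5000/385 ~= 12.987 reduced units.
#'
#' @param sigma_nm physical length of one reduced unit, in nanometres.
#' @param tau_s physical duration of one reduced Brownian time unit, in
#'   seconds.
#' @param temperature reduced temperature.
#' @return An object of class `unit_system` with conversion helpers.
#' @examples
#' u <- unit_system()
#' to_physical_length(u, 12.987013)   # ~5000 nm
#' to_reduced_length(u, 5000)         # ~12.987
#' @export
unit_system <- function(sigma_nm = 385, tau_s = 0.65, temperature = 1.0) {
  stopifnot(sigma_nm > 0, tau_s > 0, temperature > 0)
  structure(
    list(sigma_nm = sigma_nm, tau_s = tau_s, temperature = temperature),
    class = "unit_system"
  )
}

#' @rdname unit_system
#' @param u a `unit_system`.
#' @param x value(s) to convert.
#' @export
to_physical_length <- function(u, x) x * u$sigma_nm

#' @rdname unit_system
#' @export
to_reduced_length <- function(u, x) x / u$sigma_nm

#' @rdname unit_system
#' @export
to_physical_time <- function(u, x) x * u$tau_s

#' @rdname unit_system
#' @export
to_reduced_time <- function(u, x) x / u$tau_s

#' @rdname unit_system
#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf(
    "unit_system: sigma = %g nm, tau = %g s, T = %g\n",
    x$sigma_nm, x$tau_s, x$temperature
  ))
  invisible(x)
}

#' Default nuclear radius in reduced units (5 micron / 385 nm)
#' @export
NUCLEUS_RADIUS_REDUCED <- 5000 / 385
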