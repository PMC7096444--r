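#' Bragg-Kleeman range-energy model
#'
#' Analytic power-law relation between proton energy and range in tissue,
#' `R(E) = alpha * E^p / density`, with `alpha` the range coefficient for
#' water (cm MeV^-p) and `density` the tissue density (g/cm^3).  The defaults
#' (`alpha = 0.0022`, `p = 1.77`, soft tissue at 1.1 g/cm^3) reproduce the
#' clinical energy-depth pairings used for the two study tumors
#' (60 MeV -> ~3 cm, 130 MeV -> ~11.3 cm) within 10%.
#'
#' @param alpha range coefficient in water, cm MeV^-p; > 0.
#' @param p range exponent, dimensionless; > 1.
#' @param density tissue density, g/cm^3; > 0.
#' @param e_valid_max upper validity limit of the power law in MeV
#'   (therapeutic energies; the law degrades well above ~250 MeV).
#' @return object of class `range_energy_model`.
#' @examples
#' m <- range_energy_model()
#' range_from_energy(60, m)    # ~2.8 cm
#' energy_from_range(11.3, m)  # ~131 MeV
#' @export
range_energy_model <- function(alpha = 0.0022, p = 1.77, density = 1.1,
                               e_valid_max = 250) {
  stopifnot(alpha > 0, p > 1, density > 0, e_valid_max > 0)
  structure(list(alpha = alpha, p = p, density = density,
                 e_valid_max = e_valid_max),
            class = "range_energy_model")
}

#' Proton range from energy
#'
#' @param e proton kinetic energy, MeV (vectorized); must be >= 0.
#' @param model a [range_energy_model()].
#' @return range (depth to the Bragg end point) in cm; strictly increasing
#'   in `e`.
#' @export
range_from_energy <- function(e, model = range_energy_model()) {
  if (any(e < 0)) stop("energy must be >= 0")
  model$alpha * e ^ model$p / model$density
}

#' Proton energy from range (inverse of [range_from_energy()])
#'
#' @param depth range in cm (vectorized); must be >= 0.
#' @param model a [range_energy_model()].
#' @return proton energy in MeV.
#' @export
energy_from_range <- function(depth, model = range_energy_model()) {
  if (any(depth < 0)) stop("depth must be >= 0")
  (depth * model$density / model$alpha) ^ (1 / model$p)
}

#' Stopping power implied by the range model
#'
#' `S(E) = dE/dR = density / (alpha * p * E^(p-1))` in MeV/cm.  Diverges as
#' `E -> 0` like every continuous-slowing-down power law; callers integrate
#' residual-range differences rather than sampling S near zero.
#'
#' @param e proton energy, MeV; > 0.
#' @param model a [range_energy_model()].
#' @return stopping power, MeV/cm.
#' @export
stopping_power <- function(e, model = range_energy_model()) {
  if (any(e <= 0)) stop("energy must be > 0")
  model$density / (model$alpha * model$p * e ^ (model$p - 1))
}
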