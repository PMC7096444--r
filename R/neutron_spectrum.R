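#' Secondary-neutron field calibration
#'
#' Calibration of the three-group secondary-neutron field inside the tumor,
#' anchored at two Bragg-end depths (3 cm and 11.3 cm by default).  The
#' amplitudes are group-integrated fluxes in cm^-2 s^-1 per incident proton.
#' Two modes reproduce the two Monte Carlo transport codes the field levels
#' were read from:
#' \describe{
#'   \item{`"mcnpx-like"`}{thermal 1.5e-6 -> 1.8e-5 (depth ratio 12),
#'     epithermal 1e-5 -> 1e-4, fast ~1e-3 at both depths.}
#'   \item{`"geant4-like"`}{thermal 8e-7 -> 9e-6 (ratio 11.25), same
#'     epithermal and fast levels.}
#' }
#' Group boundaries follow the cadmium-cutoff convention: thermal < 0.4 eV,
#' epithermal 0.4 eV -- 100 keV, fast > 100 keV.
#'
#' @param mode `"mcnpx-like"` or `"geant4-like"`.
#' @param depths the two calibration depths, cm (distinct).
#' @param thermal,epithermal,fast length-2 amplitude vectors (shallow, deep),
#'   cm^-2 s^-1 per proton; all >= 0.
#' @param thermal_temperature Maxwellian temperature of the thermal group, K.
#' @param e_thermal_max,e_fast_min group boundaries in MeV (0.4 eV, 100 keV).
#' @param e_max upper energy of the fast group, MeV (secondary neutrons reach
#'   up to the incident proton energy).
#' @param fast_temperature evaporation temperature of the fast component, MeV.
#' @param cascade_fraction fraction of the fast group carried by the flat
#'   high-energy cascade tail (the remainder is the evaporation hump).
#' @return object of class `neutron_field_calibration`.
#' @export
neutron_field_calibration <- function(mode = c("mcnpx-like", "geant4-like"),
                                      depths = c(3, 11.3),
                                      thermal = NULL, epithermal = NULL,
                                      fast = NULL,
                                      thermal_temperature = 293,
                                      e_thermal_max = 0.4e-6,
                                      e_fast_min = 0.1,
                                      e_max = 130,
                                      fast_temperature = 2,
                                      cascade_fraction = 0.1) {
  mode <- match.arg(mode)
  if (is.null(thermal))
    thermal <- if (mode == "mcnpx-like") c(1.5e-6, 1.8e-5) else c(8e-7, 9e-6)
  if (is.null(epithermal)) epithermal <- c(1e-5, 1e-4)
  if (is.null(fast)) fast <- c(1e-3, 1e-3)
  stopifnot(length(depths) == 2L, depths[1] != depths[2],
            length(thermal) == 2L, length(epithermal) == 2L,
            length(fast) == 2L,
            all(c(thermal, epithermal, fast) >= 0),
            thermal_temperature > 0,
            0 < e_thermal_max, e_thermal_max < e_fast_min, e_fast_min < e_max,
            fast_temperature > 0,
            cascade_fraction >= 0, cascade_fraction <= 1)
  structure(list(mode = mode, depths = depths, thermal = thermal,
                 epithermal = epithermal, fast = fast,
                 thermal_temperature = thermal_temperature,
                 e_thermal_max = e_thermal_max, e_fast_min = e_fast_min,
                 e_max = e_max, fast_temperature = fast_temperature,
                 cascade_fraction = cascade_fraction),
            class = "neutron_field_calibration")
}

#' Default neutron energy grid for a calibration
#'
#' Piecewise log grid whose segment boundaries coincide with the calibration
#' group boundaries, from 1e-10 MeV (1e-4 eV, well below the thermal peak) up
#' to the fast-group maximum.
#'
#' @param calib a [neutron_field_calibration()].
#' @param bins_per_decade resolution of the log grid.
#' @return an [energy_grid()].
#' @export
neutron_grid <- function(calib, bins_per_decade = 16L) {
  log_energy_grid(c(1e-10, calib$e_thermal_max, calib$e_fast_min, calib$e_max),
                  bins_per_decade)
}

# log-linear interpolation of a group amplitude in depth, clamped outside
# the calibration interval; zero amplitudes interpolate to zero.
.interp_amplitude <- function(amps, depths, depth) {
  o <- order(depths)
  d <- depths[o]; a <- amps[o]
  x <- min(max(depth, d[1]), d[2])
  if (any(a == 0)) {            # log-space undefined; fall back to linear
    a[1] + (a[2] - a[1]) * (x - d[1]) / (d[2] - d[1])
  } else {
    exp(log(a[1]) + (log(a[2]) - log(a[1])) * (x - d[1]) / (d[2] - d[1]))
  }
}

#' Synthetic secondary-neutron spectrum at a depth
#'
#' Sum of three deterministic components, each confined to its energy group
#' and normalized so that the group-integrated flux equals the calibration
#' amplitude interpolated (log-linearly) to the requested depth:
#' \itemize{
#'   \item thermal: Maxwellian flux shape `E * exp(-E/kT)` at the calibration
#'     temperature;
#'   \item epithermal: `1/E` slowing-down shape;
#'   \item fast: evaporation hump `E * exp(-E/T_f)` plus a flat cascade tail
#'     extending to the incident proton energy, mixed by `cascade_fraction`.
#' }
#' At a calibration depth the three group-integrated fluxes equal the
#' calibration amplitudes exactly.  Depths outside the calibration interval
#' are clamped with a warning.  The generator contains no randomness.
#'
#' @param depth Bragg-end depth, cm; >= 0.
#' @param calib a [neutron_field_calibration()].
#' @param grid an [energy_grid()]; defaults to [neutron_grid()] of the
#'   calibration.
#' @return a neutron `particle_spectrum`.
#' @examples
#' cal <- neutron_field_calibration("mcnpx-like")
#' sp <- neutron_spectrum(11.3, cal)
#' group_flux(sp, 0, cal$e_thermal_max)   # 1.8e-5 exactly
#' @export
neutron_spectrum <- function(depth, calib, grid = neutron_grid(calib)) {
  stopifnot(inherits(calib, "neutron_field_calibration"),
            inherits(grid, "energy_grid"))
  if (depth < 0) stop("depth must be >= 0")
  dr <- range(calib$depths)
  if (depth < dr[1] - 1e-12 || depth > dr[2] + 1e-12)
    warning("depth ", depth, " cm outside calibration interval [", dr[1],
            ", ", dr[2], "] cm; amplitudes clamped to the nearest anchor")
  mid <- grid_midpoints(grid)
  dE <- grid_widths(grid)
  thermal_bins <- mid < calib$e_thermal_max
  epi_bins <- mid >= calib$e_thermal_max & mid < calib$e_fast_min
  fast_bins <- mid >= calib$e_fast_min

  # shape densities evaluated at midpoints, integrated per bin, then
  # renormalized per group so calibration amplitudes are met exactly
  kT <- 8.617333e-11 * calib$thermal_temperature   # MeV (Boltzmann k)
  shape_group <- function(bins, dens) {
    s <- numeric(length(mid))
    s[bins] <- dens(mid[bins]) * dE[bins]
    tot <- sum(s)
    if (tot > 0) s / tot else s
  }
  th <- shape_group(thermal_bins, function(e) e * exp(-e / kT))
  ep <- shape_group(epi_bins, function(e) 1 / e)
  Tf <- calib$fast_temperature
  fa_evap <- shape_group(fast_bins, function(e) e * exp(-e / Tf))
  fa_flat <- shape_group(fast_bins, function(e) rep(1, length(e)))
  fa <- (1 - calib$cascade_fraction) * fa_evap +
    calib$cascade_fraction * fa_flat

  a_th <- .interp_amplitude(calib$thermal, calib$depths, depth)
  a_ep <- .interp_amplitude(calib$epithermal, calib$depths, depth)
  a_fa <- .interp_amplitude(calib$fast, calib$depths, depth)
  particle_spectrum("neutron", grid, a_th * th + a_ep * ep + a_fa * fa)
}

#' Group-integrated fluxes of a neutron spectrum
#'
#' @param spectrum a neutron `particle_spectrum`.
#' @param calib the [neutron_field_calibration()] defining the boundaries.
#' @return named numeric vector `c(thermal, epithermal, fast)`.
#' @export
neutron_group_fluxes <- function(spectrum, calib) {
  c(thermal = group_flux(spectrum, 0, calib$e_thermal_max),
    epithermal = group_flux(spectrum, calib$e_thermal_max, calib$e_fast_min),
    fast = group_flux(spectrum, calib$e_fast_min, Inf))
}
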