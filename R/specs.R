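#' Tumor specification
#'
#' Spherical tumor with homogeneously distributed boron.  Defaults follow the
#' study setup: radius 0.71 cm (~1.5 cm^3), soft tissue at 1.1 g/cm^3,
#' 100 ppm (mass) of the loaded isotope.
#'
#' @param radius tumor radius, cm.
#' @param volume tumor volume, cm^3; must agree with `(4/3) pi r^3` within 2%.
#' @param density g/cm^3.
#' @param depth_interval proximal/distal depth of the tumor, cm.
#' @param boron_isotope `"10B"` (capture agent) or `"11B"` (fusion agent).
#' @param ppm mass ppm of boron (micrograms of agent per gram of tissue).
#' @return object of class `tumor_spec`; `mass_g` and `mass_kg` are derived.
#' @examples
#' t11 <- tumor_spec(boron_isotope = "11B", ppm = 100)
#' t11$mass_kg   # 1.65e-3 kg
#' @export
tumor_spec <- function(radius = 0.71, volume = 4 / 3 * pi * radius^3,
                       density = 1.1, depth_interval = c(1.6, 3.0),
                       boron_isotope = c("10B", "11B"), ppm = 100) {
  boron_isotope <- match.arg(boron_isotope)
  stopifnot(radius > 0, volume > 0, density > 0, ppm >= 0,
            length(depth_interval) == 2L,
            depth_interval[1] < depth_interval[2])
  v_sphere <- 4 / 3 * pi * radius^3
  if (abs(volume - v_sphere) / v_sphere > 0.02)
    stop("volume (", signif(volume, 4), " cm^3) inconsistent with radius (",
         "sphere volume ", signif(v_sphere, 4), " cm^3)")
  mass_g <- volume * density
  structure(list(radius = radius, volume = volume, density = density,
                 depth_interval = depth_interval,
                 boron_isotope = boron_isotope, ppm = ppm,
                 mass_g = mass_g, mass_kg = mass_g / 1000),
            class = "tumor_spec")
}

#' Phantom specification
#'
#' Spherical head phantom of homogeneous soft tissue.  Default composition
#' (mass fractions C 20%, H 10%, O 65%, N 5%) and geometry (radius 9 cm,
#' 1.1 g/cm^3) follow the study setup.
#'
#' @param radius phantom radius, cm.
#' @param density g/cm^3.
#' @param mass_fractions named numeric vector of elemental mass fractions;
#'   must sum to 1.
#' @return object of class `phantom_spec` with derived `mass_g`.
#' @export
phantom_spec <- function(radius = 9, density = 1.1,
                         mass_fractions = c(C = 0.20, H = 0.10,
                                            O = 0.65, N = 0.05)) {
  stopifnot(radius > 0, density > 0, !is.null(names(mass_fractions)))
  if (abs(sum(mass_fractions) - 1) > 1e-8)
    stop("mass fractions must sum to 1 (got ", sum(mass_fractions), ")")
  volume <- 4 / 3 * pi * radius^3
  structure(list(radius = radius, density = density,
                 mass_fractions = mass_fractions,
                 volume = volume, mass_g = volume * density),
            class = "phantom_spec")
}

# standard atomic masses (g/mol) used for atom inventories
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  "10B" = 10.013, "11B" = 11.009)
.avogadro <- 6.02214076e23
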