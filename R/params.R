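#' @useDynLib granusim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort
#' @importFrom stats quantile rnorm runif sd setNames
NULL

# Internal unit system: length um, time h, mass fg, concentration g/L.
# 1 g/L == 1 fg/um^3, so no conversion factor is needed between field
# concentrations and agent masses per volume.
M2_PER_DAY_TO_UM2_PER_H <- 1e12 / 24

#' Convert a diffusion coefficient from m^2/day to um^2/h
#'
#' @param d numeric, m^2/day.
#' @return numeric, um^2/h.
#' @export
convert_diffusivity <- function(d) d * M2_PER_DAY_TO_UM2_PER_H

#' Solute parameter set
#'
#' One row per solute. Diffusivities are stored internally in um^2/h;
#' protocol files carry them in m^2/day (the units of the literature values).
#' `boundary` is the far-field boundary condition: the fed solute (glucose)
#' is held at its bulk value on all four domain edges ("bulk"); the
#' volatile methane sees an absorbing zero-concentration far boundary
#' through which it leaves the system ("absorbing"); the non-volatile
#' metabolite acetate accumulates in the closed, well-mixed reactor
#' liquid and gets a zero-flux boundary ("noflux"), under which its
#' field is advanced by an implicit transient update rather than a
#' steady solve.
#'
#' @param name solute identifier.
#' @param D_liquid diffusion coefficient in liquid, um^2/h.
#' @param bulk_value boundary (bulk) concentration, g/L ("SBulk").
#' @param is_volatile logical; TRUE if the solute leaves the system as gas.
#' @param boundary "bulk" (Dirichlet at `bulk_value`), "absorbing"
#'   (Dirichlet at 0) or "noflux" (closed boundary, transient field).
#' @return a one-row tibble.
#' @export
solute_params <- function(name, D_liquid, bulk_value = 0,
                          is_volatile = FALSE,
                          boundary = c("bulk", "absorbing", "noflux")) {
  boundary <- match.arg(boundary)
  out <- tibble::tibble(
    name = as.character(name),
    D_liquid = as.numeric(D_liquid),
    bulk_value = as.numeric(bulk_value),
    is_volatile = isTRUE(is_volatile),
    boundary = boundary
  )
  validate_solutes(out)
  out
}

#' Default solute set: glucose, acetate, methane
#'
#' Literature diffusivities: glucose 5.8e-6, acetate 1.05e-4 and methane
#' 1.29e-4 m^2/day, converted to um^2/h at load. Glucose is supplied from
#' all sides at `sbulk`; acetate accumulates in the closed system
#' (zero-flux boundary); volatile methane is absorbed at the far
#' boundary, through which it diffuses out of the system.
#'
#' @param sbulk bulk glucose concentration, g/L.
#' @return tibble with one row per solute.
#' @export
default_solutes <- function(sbulk = 0.175) {
  dplyr::bind_rows(
    solute_params("glucose", convert_diffusivity(5.8e-6), bulk_value = sbulk,
                  is_volatile = FALSE, boundary = "bulk"),
    solute_params("acetate", convert_diffusivity(1.05e-4), bulk_value = 0,
                  is_volatile = FALSE, boundary = "noflux"),
    solute_params("methane", convert_diffusivity(1.29e-4), bulk_value = 0,
                  is_volatile = TRUE, boundary = "absorbing")
  )
}

validate_solutes <- function(solutes) {
  stopifnot(is.data.frame(solutes))
  if (any(solutes$D_liquid <= 0)) {
    abort(sprintf("solute '%s': D_liquid must be > 0",
                  solutes$name[solutes$D_liquid <= 0][1]),
          class = "granusim_validation_error")
  }
  if (any(solutes$bulk_value < 0)) {
    abort(sprintf("solute '%s': bulk_value must be >= 0",
                  solutes$name[solutes$bulk_value < 0][1]),
          class = "granusim_validation_error")
  }
  invisible(solutes)
}

#' Species parameter set
#'
#' One row per species. Masses in fg, rates in 1/h, concentrations in g/L,
#' lengths in um. `biomass_density` (fg/um^3) converts mass to radius; the
#' default 573 fg/um^3 gives a 300 fg acidogen a 3-D-equivalent radius of
#' 0.50 um. In the 2-D simulations a cell of mass m occupies a disc of area
#' m / (biomass_density * slice_thickness); see [agent_radius()].
#'
#' @param name "acidogen", "methanogen" or "dead".
#' @param cell_mass initial cell mass, fg.
#' @param eps_capsule_mass inert extracellular polymer capsule mass, fg
#'   (methanogens only); contributes to radius but not to kinetics.
#' @param division_radius radius triggering division, um.
#' @param mu_max maximum specific growth rate, 1/h.
#' @param Ks substrate half-saturation constant, g/L.
#' @param Ki product inhibition constant, g/L (NA = no inhibition).
#' @param yield_biomass g biomass per g substrate consumed.
#' @param yield_product g product per g substrate consumed.
#' @param death_delay h continuously below the death threshold before the
#'   cell turns into inert dead biomass.
#' @param death_threshold monitored-substrate concentration, g/L.
#' @param substrate,product solute names consumed/produced (NA for dead).
#' @param biomass_density fg/um^3.
#' @return a one-row tibble.
#' @export
species_params <- function(name, cell_mass, eps_capsule_mass = 0,
                           division_radius = 3, mu_max, Ks = NA_real_,
                           Ki = NA_real_, yield_biomass = NA_real_,
                           yield_product = NA_real_, death_delay = 48,
                           death_threshold = NA_real_,
                           substrate = NA_character_, product = NA_character_,
                           biomass_density = 573) {
  out <- tibble::tibble(
    name = as.character(name),
    cell_mass = as.numeric(cell_mass),
    eps_capsule_mass = as.numeric(eps_capsule_mass),
    division_radius = as.numeric(division_radius),
    mu_max = as.numeric(mu_max),
    Ks = as.numeric(Ks),
    Ki = as.numeric(Ki),
    yield_biomass = as.numeric(yield_biomass),
    yield_product = as.numeric(yield_product),
    death_delay = as.numeric(death_delay),
    death_threshold = as.numeric(death_threshold),
    substrate = as.character(substrate),
    product = as.character(product),
    biomass_density = as.numeric(biomass_density)
  )
  validate_species(out)
  out
}

#' Default species set (acidogens, methanogens, dead)
#'
#' Literature parameter values: acidogens ferment glucose to acetate
#' (mu_max 0.208/h, Ks 0.26 g/L, acetate inhibition Ki 0.1 g/L, yields
#' 0.3 g biomass and 0.82 g acetate per g glucose, 300 fg cells, death
#' below 0.02 g/L glucose); methanogens convert acetate to methane
#' (mu_max 0.1/h, Ks 0.005 g/L, yields 0.15 g biomass and 0.26 g methane
#' per g acetate, 1500 fg cells plus a 10 fg EPS capsule, death below
#' 1e-5 g/L of their substrate). Both die after 48 h of continuous
#' starvation; the inert "dead" species is always present and cannot grow.
#'
#' @param biomass_density fg/um^3, applied to all species.
#' @return tibble with one row per species.
#' @export
default_species <- function(biomass_density = 573) {
  dplyr::bind_rows(
    species_params("acidogen", cell_mass = 300, eps_capsule_mass = 0,
                   division_radius = 3, mu_max = 0.208, Ks = 0.26, Ki = 0.1,
                   yield_biomass = 0.3, yield_product = 0.82,
                   death_delay = 48, death_threshold = 0.02,
                   substrate = "glucose", product = "acetate",
                   biomass_density = biomass_density),
    species_params("methanogen", cell_mass = 1500, eps_capsule_mass = 10,
                   division_radius = 3, mu_max = 0.1, Ks = 0.005,
                   Ki = NA_real_,
                   yield_biomass = 0.15, yield_product = 0.26,
                   death_delay = 48, death_threshold = 1e-5,
                   substrate = "acetate", product = "methane",
                   biomass_density = biomass_density),
    dead_species(biomass_density = biomass_density)
  )
}

#' @rdname default_species
#' @export
dead_species <- function(biomass_density = 573) {
  species_params("dead", cell_mass = 300, eps_capsule_mass = 0,
                 division_radius = 3, mu_max = 0,
                 death_delay = Inf, biomass_density = biomass_density)
}

validate_species <- function(species) {
  stopifnot(is.data.frame(species))
  for (i in seq_len(nrow(species))) {
    s <- species[i, ]
    bad <- function(field, msg) {
      abort(sprintf("species '%s': %s (%s = %s)", s$name, msg, field,
                    format(s[[field]])),
            class = "granusim_validation_error")
    }
    if (!is.finite(s$cell_mass) || s$cell_mass <= 0)
      bad("cell_mass", "cell mass must be > 0")
    if (s$eps_capsule_mass < 0)
      bad("eps_capsule_mass", "EPS capsule mass must be >= 0")
    if (s$mu_max < 0) bad("mu_max", "growth rate must be >= 0")
    if (identical(s$name, "dead") && s$mu_max != 0)
      bad("mu_max", "dead species must have mu_max = 0")
    if (s$mu_max > 0) {
      if (!is.finite(s$Ks) || s$Ks <= 0) bad("Ks", "Ks must be > 0")
      if (!is.finite(s$yield_biomass) || s$yield_biomass <= 0)
        bad("yield_biomass", "yield must be > 0")
      if (!is.finite(s$yield_product) || s$yield_product <= 0)
        bad("yield_product", "yield must be > 0")
    }
    if (!is.finite(s$biomass_density) || s$biomass_density <= 0)
      bad("biomass_density", "biomass density must be > 0")
    r0 <- agent_radius(s$cell_mass + s$eps_capsule_mass,
                       s$biomass_density, tau = 2)
    if (s$division_radius <= r0)
      bad("division_radius", "division radius must exceed the newborn radius")
  }
  invisible(species)
}

#' Agent radius from mass
#'
#' In the 2-D simulations each cell is a disc of fixed slice thickness
#' `tau`: radius = sqrt(m / (rho * pi * tau)). With `tau = NULL` the
#' 3-D-equivalent spherical radius (3 m / (4 pi rho))^(1/3) is returned.
#' The EPS capsule mass, if any, is included by the caller in `mass`.
#'
#' @param mass total mass incl. capsule, fg.
#' @param density biomass density, fg/um^3.
#' @param tau slice thickness, um, or NULL for the spherical radius.
#' @return radius, um.
#' @export
agent_radius <- function(mass, density = 573, tau = 2) {
  if (is.null(tau)) (3 * mass / (4 * pi * density))^(1 / 3)
  else sqrt(mass / (density * pi * tau))
}
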