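#' Read a simulation protocol file
#'
#' The protocol dialect is a small XML format with a `<world>` section
#' (domain geometry, numerics, the bulk glucose supply "SBulk" on the
#' glucose solute, scenario switches) and one `<species>` element per
#' species carrying its kinetic parameters and "initAreaNumber", the
#' initial cell count. Unspecified parameters are filled with the default
#' literature values (see [default_species()], [default_solutes()]); the
#' inert dead species is always present and cannot be removed.
#' Diffusivities are given in m^2/day in the file and converted to um^2/h
#' on load.
#'
#' @param path protocol file path.
#' @return a list with elements `config` ([world_config]), `species` and
#'   `solutes` (tibbles, one row each per species/solute).
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("protocol file not found: %s", path),
                 class = "granusim_config_error")
  }
  doc <- xml2::read_xml(path)
  world <- xml2::xml_find_first(doc, ".//world")
  if (inherits(world, "xml_missing")) {
    rlang::abort("missing required section: world",
                 class = "granusim_config_error")
  }

  att <- function(node, name, default = NULL) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  num <- function(node, name, default) {
    v <- att(node, name)
    if (is.null(v)) default else as.numeric(v)
  }

  # solutes: defaults overlaid by file entries
  solutes <- default_solutes()
  for (node in xml2::xml_find_all(world, "./solute")) {
    nm <- att(node, "name")
    if (is.null(nm)) {
      rlang::abort("missing required field: solute name",
                   class = "granusim_config_error")
    }
    i <- match(nm, solutes$name)
    row <- if (is.na(i)) {
      solute_params(nm, convert_diffusivity(num(node, "diffusivity", 1e-4)))
    } else solutes[i, ]
    d <- att(node, "diffusivity")
    if (!is.null(d)) row$D_liquid <- convert_diffusivity(as.numeric(d))
    row$bulk_value <- num(node, "SBulk", row$bulk_value)
    vol <- att(node, "volatile")
    if (!is.null(vol)) row$is_volatile <- tolower(vol) %in% c("true", "yes", "1")
    bnd <- att(node, "boundary")
    if (!is.null(bnd)) row$boundary <- bnd
    if (is.na(i)) solutes <- dplyr::bind_rows(solutes, row)
    else solutes[i, ] <- row
  }
  validate_solutes(solutes)

  # species: defaults overlaid by file entries; counts from initAreaNumber
  species <- default_species()
  counts <- c(acidogen = 100, methanogen = 100)
  sp_nodes <- xml2::xml_find_all(doc, ".//species")
  if (length(sp_nodes) > 0) counts <- c()
  for (node in sp_nodes) {
    nm <- att(node, "name")
    if (is.null(nm)) {
      rlang::abort("missing required field: species name",
                   class = "granusim_config_error")
    }
    i <- match(nm, species$name)
    row <- if (is.na(i)) dead_species() else species[i, ]
    row$name <- nm
    row$cell_mass <- num(node, "cellMass", row$cell_mass)
    row$eps_capsule_mass <- num(node, "epsCapsuleMass", row$eps_capsule_mass)
    row$division_radius <- num(node, "divisionRadius", row$division_radius)
    row$mu_max <- num(node, "muMax", row$mu_max)
    row$Ks <- num(node, "Ks", row$Ks)
    row$Ki <- num(node, "Ki", row$Ki)
    row$yield_biomass <- num(node, "yieldBiomass", row$yield_biomass)
    row$yield_product <- num(node, "yieldProduct", row$yield_product)
    row$death_delay <- num(node, "deathDelay", row$death_delay)
    row$death_threshold <- num(node, "deathThreshold", row$death_threshold)
    sub <- att(node, "substrate"); if (!is.null(sub)) row$substrate <- sub
    prd <- att(node, "product"); if (!is.null(prd)) row$product <- prd
    row$biomass_density <- num(node, "biomassDensity", row$biomass_density)
    if (is.na(i)) species <- dplyr::bind_rows(species, row)
    else species[i, ] <- row
    if (nm != "dead") counts[nm] <- num(node, "initAreaNumber", 0)
  }
  if (!"dead" %in% species$name) {
    species <- dplyr::bind_rows(species, dead_species())
  }
  validate_species(species)

  cfg <- world_config(
    domain_width = num(world, "domainWidth", 508),
    domain_height = num(world, "domainHeight", 508),
    grid_resolution = num(world, "gridResolution", 254),
    gamma = num(world, "biofilmDiffusivity", 0.3),
    timestep = num(world, "timestep", 1),
    duration = num(world, "duration", 650),
    seed = num(world, "seed", 42),
    scenario = att(world, "scenario", "granule"),
    init_counts = counts,
    init_region_radius = num(world, "initRegionRadius", 15),
    agitation_strength = num(world, "agitationStrength", 5),
    agitation_jitter_frac = num(world, "agitationJitterFrac", 0.03),
    boundary_layer = num(world, "boundaryLayer", 40),
    slice_thickness = num(world, "sliceThickness", 2),
    snapshot_every = num(world, "snapshotEvery", 10),
    shove_k = num(world, "shoveK", 0.5),
    shove_threshold_frac = num(world, "shoveThresholdFrac", 0.1),
    adhesion_hom = num(world, "adhesionHom", 0.5),
    adhesion_het = num(world, "adhesionHet", 0.5),
    adhesion_range_frac = num(world, "adhesionRangeFrac", 0.6),
    adhesion_range_min = num(world, "adhesionRangeMin", 0.5),
    relax_tol = num(world, "relaxTol", 0.1),
    relax_max_pass = num(world, "relaxMaxPass", 100),
    solver_tol = num(world, "solverTol", 1e-6),
    solver_max_iter = num(world, "solverMaxIter", 50),
    max_growth_frac = num(world, "maxGrowthFrac", 0.1),
    reactor_growth = tolower(att(world, "reactorGrowth", "false")) == "true",
    literal_methane_stoich =
      tolower(att(world, "literalMethaneStoich", "false")) == "true",
    methanogen_starves_on = att(world, "methanogenStarvesOn", "acetate")
  )
  list(config = cfg, species = species, solutes = solutes)
}

#' Write a simulation protocol file
#'
#' Inverse of [load_protocol()]: `load_protocol(write_protocol(x, path))`
#' reproduces `x` exactly. Diffusivities are written back in m^2/day.
#'
#' @param cfg a [world_config].
#' @param species,solutes parameter tibbles.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(cfg, species, solutes, path) {
  if (!"dead" %in% species$name) {
    species <- dplyr::bind_rows(species, dead_species())
  }
  fmt <- function(x) sprintf("%.15g", x)
  doc <- xml2::xml_new_root("granusim-protocol")
  world <- xml2::xml_add_child(doc, "world",
    domainWidth = fmt(cfg$domain_width),
    domainHeight = fmt(cfg$domain_height),
    gridResolution = as.character(cfg$grid_resolution),
    biofilmDiffusivity = fmt(cfg$gamma),
    timestep = fmt(cfg$timestep),
    duration = fmt(cfg$duration),
    seed = as.character(cfg$seed),
    scenario = cfg$scenario,
    initRegionRadius = fmt(cfg$init_region_radius),
    agitationStrength = fmt(cfg$agitation_strength),
    agitationJitterFrac = fmt(cfg$agitation_jitter_frac),
    boundaryLayer = fmt(cfg$boundary_layer),
    sliceThickness = fmt(cfg$slice_thickness),
    snapshotEvery = fmt(cfg$snapshot_every),
    shoveK = fmt(cfg$shove_k),
    shoveThresholdFrac = fmt(cfg$shove_threshold_frac),
    adhesionHom = fmt(cfg$adhesion_hom),
    adhesionHet = fmt(cfg$adhesion_het),
    adhesionRangeFrac = fmt(cfg$adhesion_range_frac),
    adhesionRangeMin = fmt(cfg$adhesion_range_min),
    relaxTol = fmt(cfg$relax_tol),
    relaxMaxPass = as.character(cfg$relax_max_pass),
    solverTol = fmt(cfg$solver_tol),
    solverMaxIter = as.character(cfg$solver_max_iter),
    maxGrowthFrac = fmt(cfg$max_growth_frac),
    reactorGrowth = tolower(as.character(cfg$reactor_growth)),
    literalMethaneStoich = tolower(as.character(cfg$literal_methane_stoich)),
    methanogenStarvesOn = cfg$methanogen_starves_on)
  for (i in seq_len(nrow(solutes))) {
    s <- solutes[i, ]
    xml2::xml_add_child(world, "solute",
      name = s$name,
      diffusivity = fmt(s$D_liquid / M2_PER_DAY_TO_UM2_PER_H),
      SBulk = fmt(s$bulk_value),
      volatile = tolower(as.character(s$is_volatile)),
      boundary = s$boundary)
  }
  for (i in seq_len(nrow(species))) {
    s <- species[i, ]
    count <- cfg$init_counts[s$name]
    node <- xml2::xml_add_child(doc, "species",
      name = s$name,
      initAreaNumber = as.character(
        if (is.na(count) || is.null(count)) 0 else as.integer(count)),
      cellMass = fmt(s$cell_mass),
      epsCapsuleMass = fmt(s$eps_capsule_mass),
      divisionRadius = fmt(s$division_radius),
      muMax = fmt(s$mu_max),
      deathDelay = fmt(s$death_delay),
      biomassDensity = fmt(s$biomass_density))
    opt <- function(field, attr) {
      if (is.finite(s[[field]]) || (is.character(s[[field]]) && !is.na(s[[field]]))) {
        xml2::xml_set_attr(node, attr, if (is.numeric(s[[field]]))
          fmt(s[[field]]) else s[[field]])
      }
    }
    opt("Ks", "Ks"); opt("Ki", "Ki")
    opt("yield_biomass", "yieldBiomass"); opt("yield_product", "yieldProduct")
    opt("death_threshold", "deathThreshold")
    opt("substrate", "substrate"); opt("product", "product")
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) {
             rlang::abort(sprintf("cannot write protocol to '%s': %s",
                                  path, conditionMessage(e)),
                          class = "granusim_io_error")
           })
  invisible(path)
}

#' Default protocol (granule scenario, literature parameters)
#'
#' @param sbulk bulk glucose, g/L. The default 0.175 g/L is the calibrated
#'   bulk supply of the reference granule-maturation run; see the methods
#'   vignette.
#' @param ... overrides passed to [world_config()].
#' @return list with `config`, `species`, `solutes`.
#' @export
default_protocol <- function(sbulk = 0.175, ...) {
  list(config = world_config(...),
       species = default_species(),
       solutes = default_solutes(sbulk = sbulk))
}
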