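#' Simulation configuration
#'
#' Collects the world geometry, numerics and scenario switches. Internal
#' units: um, h, fg, g/L.
#'
#' @param domain_width,domain_height domain size, um.
#' @param grid_resolution number of solute grid nodes per side (>= 8).
#'   The reference resolution is 2 um per node (254 nodes for the 508 um
#'   domain); a coarse 8 um mode (64 nodes) is used for fast runs.
#' @param gamma relative biofilm diffusivity in biomass-occupied grid
#'   cells, fraction of the liquid value (default 0.3).
#' @param timestep global biological timestep, h. Growth is sub-stepped
#'   whenever one step would change a cell mass by more than
#'   `max_growth_frac`.
#' @param duration simulated time, h.
#' @param seed integer random seed recorded with every run.
#' @param scenario "granule" (mesoscale, a single central seed
#'   agglomerate matures) or "reactor" (macroscale, dispersed cells
#'   aggregate under agitation; mechanics-only unless `reactor_growth`).
#' @param init_counts named integer vector of initial cell counts per
#'   species ("init area number"), e.g. `c(acidogen = 100, methanogen = 100)`.
#' @param init_region_radius radius of the central seeding disc in the
#'   granule scenario, um.
#' @param agitation_strength per-step random displacement scale, um
#'   (reactor scenario).
#' @param agitation_jitter_frac fraction of `agitation_strength` applied
#'   as independent per-cell jitter on top of the rigid per-agglomerate
#'   displacement; it erodes clusters that are not held together by
#'   adhesion.
#' @param boundary_layer thickness of the diffusive boundary layer
#'   around the biomass, um. The agitated reactor liquid is well mixed,
#'   so the fed solute is held at its bulk value everywhere farther
#'   than this from any biomass; use `Inf` to supply from the domain
#'   edges only.
#' @param slice_thickness 2-D slice thickness, um, used to convert agent
#'   masses to grid concentrations and radii.
#' @param snapshot_every snapshot cadence, h.
#' @param shove_k fraction of the pairwise overlap corrected per shove
#'   pass (split equally between the two cells).
#' @param shove_threshold_frac shove engages when the centre distance is
#'   below (1 + frac) * (r_i + r_j).
#' @param adhesion_hom,adhesion_het homogeneous (same-species) and
#'   heterogeneous (cross-species) adhesion strengths, fraction of the
#'   gap closed per pass.
#' @param adhesion_range_frac attraction range as a fraction of r_i + r_j
#'   beyond contact.
#' @param adhesion_range_min absolute floor of the attraction reach, um
#'   (EPS appendages have a fixed length scale, so small cells still
#'   capture neighbours).
#' @param relax_tol relaxation stops when the largest single displacement
#'   in a pass falls below this, um.
#' @param relax_max_pass iteration cap for relaxation.
#' @param solver_tol relative tolerance of the pseudo-steady-state solute
#'   solver (nonlinear fixed-point residual).
#' @param solver_max_iter Picard iteration cap.
#' @param max_growth_frac maximum relative mass change per growth
#'   sub-step.
#' @param reactor_growth logical; enable growth in the reactor scenario.
#' @param literal_methane_stoich logical; if TRUE, methane is produced at
#'   the rate acetate is consumed (1 g/g) instead of being scaled by the
#'   methane yield (0.26 g methane / g acetate). See the methods vignette.
#' @param methanogen_starves_on "acetate" (default: the starvation switch
#'   of methanogens monitors their own substrate) or "glucose".
#' @return an object of class `world_config`.
#' @export
world_config <- function(domain_width = 508, domain_height = 508,
                         grid_resolution = 254, gamma = 0.3,
                         timestep = 1, duration = 650, seed = 42L,
                         scenario = c("granule", "reactor"),
                         init_counts = c(acidogen = 100, methanogen = 100),
                         init_region_radius = 15,
                         agitation_strength = 5,
                         agitation_jitter_frac = 0.03,
                         boundary_layer = 40,
                         slice_thickness = 2,
                         snapshot_every = 10,
                         shove_k = 0.5, shove_threshold_frac = 0.1,
                         adhesion_hom = 0.5, adhesion_het = 0.5,
                         adhesion_range_frac = 0.6,
                         adhesion_range_min = 0.5,
                         relax_tol = 0.1, relax_max_pass = 100,
                         solver_tol = 1e-6, solver_max_iter = 50,
                         max_growth_frac = 0.1,
                         reactor_growth = FALSE,
                         literal_methane_stoich = FALSE,
                         methanogen_starves_on = c("acetate", "glucose")) {
  scenario <- match.arg(scenario)
  methanogen_starves_on <- match.arg(methanogen_starves_on)
  cfg <- structure(list(
    domain_width = as.numeric(domain_width),
    domain_height = as.numeric(domain_height),
    grid_resolution = as.integer(grid_resolution),
    gamma = as.numeric(gamma),
    timestep = as.numeric(timestep),
    duration = as.numeric(duration),
    seed = as.integer(seed),
    scenario = scenario,
    init_counts = setNames(as.integer(init_counts), names(init_counts)),
    init_region_radius = as.numeric(init_region_radius),
    agitation_strength = as.numeric(agitation_strength),
    agitation_jitter_frac = as.numeric(agitation_jitter_frac),
    boundary_layer = as.numeric(boundary_layer),
    slice_thickness = as.numeric(slice_thickness),
    snapshot_every = as.numeric(snapshot_every),
    shove_k = as.numeric(shove_k),
    shove_threshold_frac = as.numeric(shove_threshold_frac),
    adhesion_hom = as.numeric(adhesion_hom),
    adhesion_het = as.numeric(adhesion_het),
    adhesion_range_frac = as.numeric(adhesion_range_frac),
    adhesion_range_min = as.numeric(adhesion_range_min),
    relax_tol = as.numeric(relax_tol),
    relax_max_pass = as.integer(relax_max_pass),
    solver_tol = as.numeric(solver_tol),
    solver_max_iter = as.integer(solver_max_iter),
    max_growth_frac = as.numeric(max_growth_frac),
    reactor_growth = isTRUE(reactor_growth),
    literal_methane_stoich = isTRUE(literal_methane_stoich),
    methanogen_starves_on = methanogen_starves_on
  ), class = "world_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  check <- function(ok, field, msg) {
    if (!ok) {
      rlang::abort(sprintf("invalid configuration: %s (%s = %s)", msg, field,
                           paste(format(cfg[[field]]), collapse = ",")),
                   class = "granusim_validation_error")
    }
  }
  check(cfg$domain_width > 0 && cfg$domain_height > 0, "domain_width",
        "domain size must be positive")
  check(cfg$domain_width == cfg$domain_height, "domain_height",
        "only square domains are supported")
  check(cfg$grid_resolution >= 8, "grid_resolution",
        "grid resolution must be at least 8 nodes")
  check(cfg$gamma > 0 && cfg$gamma <= 1, "gamma",
        "biofilm diffusivity fraction must lie in (0, 1]")
  check(cfg$timestep > 0, "timestep", "timestep must be > 0")
  check(cfg$duration >= 0, "duration", "duration must be >= 0")
  check(all(cfg$init_counts >= 0), "init_counts",
        "initial counts must be >= 0")
  check(cfg$init_region_radius > 0 &&
          2 * cfg$init_region_radius <= min(cfg$domain_width,
                                            cfg$domain_height),
        "init_region_radius", "seeding disc must fit inside the domain")
  check(cfg$agitation_strength >= 0, "agitation_strength",
        "agitation strength must be >= 0")
  check(cfg$slice_thickness > 0, "slice_thickness",
        "slice thickness must be > 0")
  check(cfg$boundary_layer > 0, "boundary_layer",
        "boundary layer thickness must be > 0")
  check(cfg$solver_tol > 0, "solver_tol", "solver tolerance must be > 0")
  check(cfg$relax_tol > 0, "relax_tol", "relaxation tolerance must be > 0")
  cfg
}

#' @exportS3Method print world_config
print.world_config <- function(x, ...) {
  cat(sprintf(
    "<world_config> %s scenario, %.0f x %.0f um, %d x %d grid, dt %.2g h, %g h, seed %d\n",
    x$scenario, x$domain_width, x$domain_height, x$grid_resolution,
    x$grid_resolution, x$timestep, x$duration, x$seed))
  cat(sprintf("  init counts: %s; gamma %.2f; slice %.1f um\n",
              paste(names(x$init_counts), x$init_counts, sep = "=",
                    collapse = ", "),
              x$gamma, x$slice_thickness))
  invisible(x)
}

# grid spacing, um per node
grid_spacing <- function(cfg) cfg$domain_width / cfg$grid_resolution

# volume of one grid cell in litres (1 um^3 = 1e-15 L)
grid_cell_volume_L <- function(cfg) {
  grid_spacing(cfg)^2 * cfg$slice_thickness * 1e-15
}
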