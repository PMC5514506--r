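#' World state
#'
#' The unit of snapshotting: simulation clock, the agent table, one
#' concentration matrix per solute, and the cumulative methane production
#' ledger. Agents live in a tibble with columns `id`, `species`, `mass`
#' (biomass, fg), `capsule` (inert EPS mass, fg), `x`, `y` (um), `clock`
#' (h spent continuously below the starvation threshold).
#'
#' @param cfg a [world_config].
#' @param species,solutes parameter tibbles.
#' @param agents agent tibble.
#' @return an object of class `world_state`.
#' @keywords internal
new_world_state <- function(cfg, species, solutes, agents) {
  n <- cfg$grid_resolution
  fields <- lapply(seq_len(nrow(solutes)), function(i) {
    s <- solutes[i, ]
    matrix(if (s$boundary == "bulk") s$bulk_value else 0, n, n)
  })
  names(fields) <- solutes$name
  structure(list(
    time = 0,
    agents = agents,
    fields = fields,
    cumulative_ch4 = 0,
    cumulative_acetate_consumed = 0,
    cumulative_glucose_consumed = 0,
    next_id = if (nrow(agents)) max(agents$id) + 1L else 1L,
    config = cfg,
    species = species,
    solutes = solutes,
    events = list(substrate_cap = 0L, clip = 0L, relax_cap = 0L)
  ), class = "world_state")
}

#' @exportS3Method print world_state
print.world_state <- function(x, ...) {
  cnt <- table(factor(x$agents$species,
                      levels = unique(c(x$species$name, x$agents$species))))
  cat(sprintf("<world_state> t = %.1f h, %d agents (%s), cumulative CH4 %.3g fg\n",
              x$time, nrow(x$agents),
              paste(names(cnt), as.integer(cnt), sep = ":", collapse = ", "),
              x$cumulative_ch4))
  invisible(x)
}

agent_table <- function(id = integer(), species = character(),
                        mass = numeric(), capsule = numeric(),
                        x = numeric(), y = numeric(), clock = numeric()) {
  tibble::tibble(id = as.integer(id), species = as.character(species),
                 mass = as.numeric(mass), capsule = as.numeric(capsule),
                 x = as.numeric(x), y = as.numeric(y),
                 clock = as.numeric(clock))
}

# radii for an agent table (2-D disc convention, includes capsule)
agent_radii <- function(agents, species, cfg) {
  dens <- setNames(species$biomass_density, species$name)[agents$species]
  unname(agent_radius(agents$mass + agents$capsule, density = dens,
                      tau = cfg$slice_thickness))
}

#' Construct the initial world state
#'
#' Reactor scenario: the requested number of cells of each species is
#' placed uniformly at random over the whole domain without overlaps
#' (bounded rejection sampling). Granule scenario: all cells are placed
#' randomly mixed inside a central disc of radius
#' `cfg$init_region_radius` (the seed agglomerate) and relaxed to
#' contact. All cells start at their species' initial mass.
#'
#' @param cfg a [world_config].
#' @param species species parameter tibble.
#' @param solutes solute parameter tibble (defaults used if missing).
#' @param seed integer seed; `NULL` continues the caller's RNG stream.
#'   Identical (protocol, seed) pairs yield identical initial states.
#' @return a `world_state`.
#' @export
build_initial_state <- function(cfg, species = default_species(),
                                solutes = default_solutes(),
                                seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  counts <- cfg$init_counts[cfg$init_counts > 0]
  counts <- counts[names(counts) %in% species$name]
  # canonical order: the species table order, so that identical
  # (protocol, seed) pairs give identical states however counts were given
  counts <- counts[order(match(names(counts), species$name))]
  sp <- rep(names(counts), times = counts)
  n <- length(sp)
  if (n > 0) sp <- sample(sp)  # randomly mixed types

  sp_idx <- match(sp, species$name)
  mass <- species$cell_mass[sp_idx]
  capsule <- species$eps_capsule_mass[sp_idx]
  r <- agent_radius(mass + capsule,
                    density = species$biomass_density[sp_idx],
                    tau = cfg$slice_thickness)

  if (n == 0) {
    xs <- ys <- numeric()
  } else if (cfg$scenario == "granule") {
    cx <- cfg$domain_width / 2
    cy <- cfg$domain_height / 2
    rr <- cfg$init_region_radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    xs <- cx + rr * cos(th)
    ys <- cy + rr * sin(th)
  } else {
    xs <- ys <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        px <- runif(1, r[i], cfg$domain_width - r[i])
        py <- runif(1, r[i], cfg$domain_height - r[i])
        if (i == 1 || all((xs[seq_len(i - 1)] - px)^2 +
                            (ys[seq_len(i - 1)] - py)^2 >
                            (r[seq_len(i - 1)] + r[i])^2)) {
          xs[i] <- px; ys[i] <- py; placed <- TRUE; break
        }
      }
      if (!placed) {
        rlang::abort(
          sprintf("could not place %d non-overlapping cells (failed at %d)",
                  n, i),
          class = "granusim_placement_error")
      }
    }
  }

  agents <- agent_table(id = seq_len(n), species = sp, mass = mass,
                        capsule = capsule, x = xs, y = ys,
                        clock = rep(0, n))
  state <- new_world_state(cfg, species, solutes, agents)
  if (n > 0) {
    state$agents <- relax(state$agents, state$species, cfg,
                          tol = cfg$relax_tol)
  }
  state
}
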