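# Coupled solve of the three solute fields over one step.
# Glucose is pseudo-steady against the bulk Dirichlet boundary; acetate,
# which accumulates in the closed system, takes one implicit-Euler
# transient step under its zero-flux boundary; the two are iterated
# jointly (acetate feeds back on acidogen growth through product
# inhibition); volatile methane follows in one pseudo-steady solve with
# the absorbing far boundary from the converged acetate uptake. Monod
# uptake is linearized about the previous iterate, S/(Ks+S_prev), which
# keeps the operator an M-matrix and the fields nonnegative.
solve_solute_fields <- function(state, raster, solver,
                                dt = state$config$timestep) {
  cfg <- state$config
  sp <- state$species
  p_a <- sp[sp$name == "acidogen", ]
  p_m <- sp[sp$name == "methanogen", ]
  sol <- state$solutes
  glucose <- sol[sol$name == "glucose", ]
  acetate <- sol[sol$name == "acetate", ]
  methane <- sol[sol$name == "methane", ]
  Ba <- raster$biomass[["acidogen"]]
  Bm <- raster$biomass[["methanogen"]]
  mask <- raster$mask

  S_g <- state$fields[["glucose"]]
  S_a <- state$fields[["acetate"]]
  S_a_old <- S_a  # previous-step acetate for the transient update
  Dg <- glucose$D_liquid * mask
  Da <- acetate$D_liquid * mask
  bc_g <- if (glucose$boundary == "bulk") glucose$bulk_value else 0
  # the agitated bulk liquid pins the fed solute at SBulk outside the
  # boundary layer (penalty formulation keeps the matrix pattern fixed)
  occupied <- Reduce(`+`, raster$biomass) > 0
  far <- far_field_mask(occupied, cfg)
  KEX <- 1e6  # 1/h, exchange rate with the well-mixed bulk
  k_far <- KEX * far
  src_far <- KEX * bc_g * far
  acetate_mode <- if (acetate$boundary == "noflux") "noflux" else "dirichlet"
  acetate_trans <- if (acetate_mode == "noflux") 1 / dt else 0
  zero <- matrix(0, cfg$grid_resolution, cfg$grid_resolution)
  delta <- Inf
  for (it in seq_len(cfg$solver_max_iter)) {
    inhib <- p_a$Ki / (p_a$Ki + S_a)
    k_g <- p_a$mu_max * inhib * Ba / (p_a$yield_biomass * (p_a$Ks + S_g))
    S_g_new <- solve_linear_field(solver, Dg, k_g + k_far, src_far, bc_g)
    mu_a <- p_a$mu_max * S_g_new / (p_a$Ks + S_g_new) * inhib
    src_a <- p_a$yield_product / p_a$yield_biomass * mu_a * Ba
    k_a <- p_m$mu_max * Bm / (p_m$yield_biomass * (p_m$Ks + S_a))
    S_a_new <- solve_linear_field(solver, Da, k_a, src_a, 0,
                                  boundary = acetate_mode,
                                  trans = acetate_trans, S_old = S_a_old)
    delta <- max(
      max(abs(S_g_new - S_g)) / max(max(S_g_new), 1e-300),
      max(abs(S_a_new - S_a)) / max(max(S_a_new), 1e-300))
    S_g <- S_g_new
    S_a <- S_a_new
    if (delta < cfg$solver_tol) break
  }
  if (!(delta < cfg$solver_tol)) {
    rlang::abort(sprintf(
      "solute solver did not converge at t = %.1f h (residual %.3g)",
      state$time, delta), class = "granusim_solver_error")
  }
  # consumption rates at the converged fields, g/(L h)
  inhib <- p_a$Ki / (p_a$Ki + S_a)
  glucose_sink <- p_a$mu_max * inhib * Ba * S_g /
    (p_a$yield_biomass * (p_a$Ks + S_g))
  acetate_sink <- p_m$mu_max * Bm * S_a /
    (p_m$yield_biomass * (p_m$Ks + S_a))
  ch4_yield <- if (cfg$literal_methane_stoich) 1 else p_m$yield_product
  src_m <- ch4_yield * acetate_sink
  Dm <- methane$D_liquid * mask
  S_m <- solve_linear_field(solver, Dm, zero, src_m, 0)

  state$fields[["glucose"]] <- pmax(S_g, 0)
  state$fields[["acetate"]] <- pmax(S_a, 0)
  state$fields[["methane"]] <- pmax(S_m, 0)
  list(state = state, iterations = it,
       glucose_sink = glucose_sink, acetate_sink = acetate_sink)
}

#' Advance the world by one biological timestep
#'
#' Order of operations: (1) rasterize biomass and the diffusivity mask,
#' (2) solve the pseudo-steady solute fields, (3) growth and secretion
#' at the local concentrations (sub-stepped so no cell gains more than
#' `max_growth_frac` of its mass per sub-step; the substrate draw per
#' grid cell is capped by the standing solute mass plus what the solved
#' fluxes deliver over the step), (4) starvation death switch,
#' (5) division, (6) mechanical relaxation (preceded by agitation in the
#' reactor scenario), (7) clock advance.
#'
#' @param state a `world_state`.
#' @param dt timestep, h (default the configured timestep).
#' @param solver optional solver context, reused across steps.
#' @return the updated `world_state`.
#' @export
step_world <- function(state, dt = state$config$timestep, solver = NULL) {
  cfg <- state$config
  stopifnot(dt > 0, dt <= cfg$timestep + 1e-12)
  if (is.null(solver)) solver <- new_field_solver(cfg)
  raster <- rasterize_biomass(state$agents, state$species, cfg)
  solved <- solve_solute_fields(state, raster, solver, dt = dt)
  state <- solved$state

  grow <- cfg$scenario == "granule" || cfg$reactor_growth
  n_ag <- nrow(state$agents)
  if (grow && n_ag > 0) {
    cell <- raster$cell
    vol <- grid_spacing(cfg)^2 * cfg$slice_thickness  # um^3 (fg per g/L)
    local_conc <- lapply(state$fields, function(m) m[cell])
    # per-grid-cell substrate budget over the whole step, fg
    budget <- list(
      glucose = state$fields[["glucose"]] * vol +
        solved$glucose_sink * vol * dt,
      acetate = state$fields[["acetate"]] * vol +
        solved$acetate_sink * vol * dt)
    mu <- agent_growth_rates(state$agents, state$species, local_conc)
    nsub <- max(1L, ceiling(max(mu) * dt / cfg$max_growth_frac))
    sub_dt <- dt / nsub
    for (s in seq_len(nsub)) {
      rep_s <- step_growth(state$agents, state$species, local_conc, sub_dt,
                           literal_methane = cfg$literal_methane_stoich)
      sub_name <- setNames(state$species$substrate,
                           state$species$name)[state$agents$species]
      capres <- cap_substrate_draws(rep_s$substrate_consumed, sub_name,
                                    cell, budget, nsub)
      scale <- capres$scale
      if (capres$capped) {
        state$events$substrate_cap <- state$events$substrate_cap + 1L
      }
      gained <- rep_s$biomass_gained * scale
      consumed <- rep_s$substrate_consumed * scale
      secreted <- rep_s$product_secreted * scale
      state$agents$mass <- state$agents$mass + gained
      is_meth <- state$agents$species == "methanogen"
      is_acid <- state$agents$species == "acidogen"
      state$cumulative_ch4 <- state$cumulative_ch4 + sum(secreted[is_meth])
      state$cumulative_acetate_consumed <-
        state$cumulative_acetate_consumed + sum(consumed[is_meth])
      state$cumulative_glucose_consumed <-
        state$cumulative_glucose_consumed + sum(consumed[is_acid])
    }
    state$agents <- step_death(state$agents, state$species, local_conc,
                               dt, cfg)
    div <- maybe_divide(state$agents, state$species, cfg, state$next_id)
    state$agents <- div$agents
    state$next_id <- div$next_id
  }

  if (nrow(state$agents) > 1) {
    if (cfg$scenario == "reactor") {
      state$agents <- agitate(state$agents, state$species, cfg)
    }
    state$agents <- relax(state$agents, state$species, cfg)
    if (isTRUE(attr(state$agents, "capped"))) {
      state$events$relax_cap <- state$events$relax_cap + 1L
    }
  }
  state$time <- state$time + dt
  state
}

# Scale per-agent substrate draws so no grid cell is drawn below zero:
# the total draw in a cell over one sub-step may not exceed its share
# (1/nsub) of the cell's step budget (standing solute mass plus the mass
# the solved fluxes deliver over the step, in fg). Returns the per-agent
# scale factors and whether any cap engaged.
cap_substrate_draws <- function(consumed, substrate, cell, budget, nsub) {
  scale <- rep(1, length(consumed))
  capped <- FALSE
  for (sn in names(budget)) {
    users <- which(!is.na(substrate) & substrate == sn & consumed > 0)
    if (length(users) == 0) next
    draw <- tapply(consumed[users], cell[users], sum)
    avail <- budget[[sn]][as.integer(names(draw))] / nsub
    f <- pmin(1, avail / pmax(draw, 1e-300))
    if (any(f < 1)) {
      capped <- TRUE
      fmap <- setNames(f, names(draw))
      scale[users] <- pmin(scale[users], fmap[as.character(cell[users])])
    }
  }
  list(scale = scale, capped = capped)
}

summary_row <- function(state) {
  a <- state$agents
  totals <- solute_totals(state)
  std <- setNames(totals$standing_g, totals$solute)
  tibble::tibble(
    time = state$time,
    acidogens = sum(a$species == "acidogen"),
    methanogens = sum(a$species == "methanogen"),
    dead = sum(a$species == "dead"),
    acidogen_mass_fg = sum(a$mass[a$species == "acidogen"]),
    methanogen_mass_fg = sum(a$mass[a$species == "methanogen"]),
    dead_mass_fg = sum(a$mass[a$species == "dead"]),
    glucose_g = std[["glucose"]],
    acetate_g = std[["acetate"]],
    methane_g = std[["methane"]],
    ch4_cumulative_g = state$cumulative_ch4 * 1e-15,
    acetate_consumed_g = state$cumulative_acetate_consumed * 1e-15,
    glucose_consumed_g = state$cumulative_glucose_consumed * 1e-15
  )
}

#' Run a granulation simulation
#'
#' Builds the initial state from the protocol, then advances the
#' interleaved biomechanics/biochemistry loop to `duration`, recording a
#' summary row (per-type cell counts and biomass, solute totals,
#' cumulative methane) at every step and agent snapshots at the
#' configured cadence.
#'
#' @param protocol a protocol list (`config`, `species`, `solutes`) as
#'   returned by [default_protocol()] or [load_protocol()].
#' @param seed optional seed overriding the protocol seed.
#' @param duration optional duration override, h.
#' @param snapshot_fields keep the full solute fields in every snapshot
#'   (memory-heavy); the final state always carries them.
#' @param quiet suppress progress messages.
#' @return an object of class `granulation_run`: list with `config`,
#'   `species`, `solutes`, `summary` (tibble, one row per step),
#'   `snapshots` (list of agent tables with times), and `state` (final
#'   `world_state`).
#' @export
run_simulation <- function(protocol = default_protocol(), seed = NULL,
                           duration = NULL, snapshot_fields = FALSE,
                           quiet = TRUE) {
  cfg <- protocol$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(duration)) cfg$duration <- as.numeric(duration)
  set.seed(cfg$seed)
  state <- build_initial_state(cfg, protocol$species, protocol$solutes,
                               seed = NULL)
  state$config <- cfg
  solver <- new_field_solver(cfg)
  nsteps <- if (cfg$timestep > 0) floor(cfg$duration / cfg$timestep + 1e-9) else 0
  snapshots <- list()
  take_snap <- function(state) {
    snap <- list(time = state$time, agents = state$agents)
    if (snapshot_fields) snap$fields <- state$fields
    snap
  }
  snapshots[[1]] <- take_snap(state)
  next_snap <- cfg$snapshot_every
  rows <- vector("list", nsteps + 1)
  rows[[1]] <- summary_row(state)
  for (k in seq_len(nsteps)) {
    state <- step_world(state, cfg$timestep, solver)
    rows[[k + 1]] <- summary_row(state)
    if (state$time + 1e-9 >= next_snap) {
      snapshots[[length(snapshots) + 1]] <- take_snap(state)
      next_snap <- next_snap + cfg$snapshot_every
    }
    if (!quiet && k %% 50 == 0) {
      message(sprintf("t = %.0f h, %d agents", state$time,
                      nrow(state$agents)))
    }
  }
  structure(list(config = cfg, species = protocol$species,
                 solutes = protocol$solutes,
                 summary = dplyr::bind_rows(rows),
                 snapshots = snapshots, state = state),
            class = "granulation_run")
}

#' @exportS3Method print granulation_run
print.granulation_run <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "<granulation_run> %s scenario, %.0f h, seed %d\n",
    x$config$scenario, fin$time, x$config$seed))
  cat(sprintf(
    "  final: %d acidogens, %d methanogens, %d dead; cumulative CH4 %.3g g\n",
    fin$acidogens, fin$methanogens, fin$dead, fin$ch4_cumulative_g))
  invisible(x)
}

#' Write run outputs as plain-text tables
#'
#' Writes `summary.csv` (the per-step series), one `agents_<time>.csv`
#' per snapshot (id, species, x, y, radius, mass, starvation clock) and
#' the final solute fields as `field_<solute>.csv` (row-major grid,
#' origin at the lower-left, node-centred).
#'
#' @param run a `granulation_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (snap in run$snapshots) {
    a <- snap$agents
    a$radius <- agent_radii(a, run$species, run$config)
    utils::write.csv(
      a[, c("id", "species", "x", "y", "radius", "mass", "clock")],
      file.path(dir, sprintf("agents_%05.0f.csv", snap$time)),
      row.names = FALSE)
  }
  for (nm in names(run$state$fields)) {
    utils::write.table(run$state$fields[[nm]],
                       file.path(dir, sprintf("field_%s.csv", nm)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
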