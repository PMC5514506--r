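#' Acidogen specific growth rate
#'
#' Monod kinetics on glucose with non-competitive product inhibition by
#' acetate: `mu = mu_max * Sg/(Ks+Sg) * Ki/(Ki+Sa)`. Bounded by
#' `mu_max`; zero at zero glucose.
#'
#' @param S_g local glucose, g/L (vectorized).
#' @param S_a local acetate, g/L.
#' @param p one-row species tibble (acidogen parameters).
#' @return specific growth rate, 1/h.
#' @export
growth_rate_acidogen <- function(S_g, S_a, p) {
  if (any(S_g < 0) || any(S_a < 0)) {
    rlang::abort("concentrations must be nonnegative",
                 class = "granusim_domain_error")
  }
  p$mu_max * S_g / (p$Ks + S_g) * p$Ki / (p$Ki + S_a)
}

#' Methanogen specific growth rate
#'
#' Monod kinetics on acetate, no product inhibition:
#' `mu = mu_max * Sa/(Ks+Sa)`.
#'
#' @param S_a local acetate, g/L (vectorized).
#' @param p one-row species tibble (methanogen parameters).
#' @return specific growth rate, 1/h.
#' @export
growth_rate_methanogen <- function(S_a, p) {
  if (any(S_a < 0)) {
    rlang::abort("concentrations must be nonnegative",
                 class = "granusim_domain_error")
  }
  p$mu_max * S_a / (p$Ks + S_a)
}

# mu for every agent given local concentration vectors (aligned to agents)
agent_growth_rates <- function(agents, species, local_conc) {
  mu <- numeric(nrow(agents))
  sp <- split(seq_len(nrow(agents)), agents$species)
  for (nm in names(sp)) {
    idx <- sp[[nm]]
    p <- species[species$name == nm, ]
    if (nrow(p) == 0 || p$mu_max == 0) next
    sub <- local_conc[[p$substrate]][idx]
    mu[idx] <- if (is.finite(p$Ki)) {
      growth_rate_acidogen(sub, local_conc[[p$product]][idx], p)
    } else {
      growth_rate_methanogen(sub, p)
    }
  }
  mu
}

#' One growth increment for a table of agents
#'
#' Explicit per-step growth at the local (pseudo-steady) concentrations:
#' `dm = mu * m * dt`, substrate consumed `dm / yield_biomass`, product
#' secreted `yield_product x substrate consumed`. Dead agents and agents
#' of extinct substrate concentration grow by zero. The caller is
#' responsible for sub-stepping (keeping `mu * dt` small) and for
#' capping the substrate draw against local availability.
#'
#' @param agents agent tibble.
#' @param species species parameter tibble.
#' @param local_conc named list of per-agent concentration vectors
#'   (g/L), one entry per solute, aligned with `agents` rows.
#' @param dt timestep, h.
#' @param literal_methane if TRUE, methanogen product equals the acetate
#'   consumed (1 g/g) instead of `yield_product` x acetate consumed.
#' @return growth report tibble: `id`, `species`, `mu`,
#'   `biomass_gained`, `substrate_consumed`, `product_secreted` (fg).
#' @export
step_growth <- function(agents, species, local_conc, dt,
                        literal_methane = FALSE) {
  stopifnot(dt > 0)
  mu <- agent_growth_rates(agents, species, local_conc)
  dm <- mu * agents$mass * dt
  yb <- setNames(species$yield_biomass, species$name)[agents$species]
  yp <- setNames(species$yield_product, species$name)[agents$species]
  if (literal_methane) {
    prod_sol <- setNames(species$product, species$name)[agents$species]
    yp[!is.na(prod_sol) & prod_sol == "methane"] <- 1
  }
  consumed <- ifelse(dm > 0, dm / yb, 0)
  secreted <- ifelse(dm > 0, consumed * yp, 0)
  tibble::tibble(id = agents$id, species = agents$species, mu = mu,
                 biomass_gained = dm, substrate_consumed = consumed,
                 product_secreted = secreted)
}

#' Starvation death switch
#'
#' An agent whose monitored substrate stays below its species' death
#' threshold accumulates starvation time; any recovery above the
#' threshold resets the clock. After `death_delay` (48 h) of continuous
#' starvation the agent is irreversibly converted to the inert dead
#' species, its mass preserved. Acidogens monitor glucose; methanogens
#' monitor their own substrate (acetate) by default, or glucose when
#' `cfg$methanogen_starves_on == "glucose"`.
#'
#' @inheritParams step_growth
#' @param cfg a [world_config].
#' @return updated agent tibble.
#' @export
step_death <- function(agents, species, local_conc, dt, cfg) {
  stopifnot(dt > 0)
  if (nrow(agents) == 0) return(agents)
  monitored <- rep(NA_real_, nrow(agents))
  thr <- rep(NA_real_, nrow(agents))
  for (nm in unique(agents$species)) {
    p <- species[species$name == nm, ]
    if (nrow(p) == 0 || p$mu_max == 0) next
    sol <- p$substrate
    if (nm == "methanogen" && cfg$methanogen_starves_on == "glucose") {
      sol <- "glucose"
    }
    idx <- agents$species == nm
    monitored[idx] <- local_conc[[sol]][idx]
    thr[idx] <- p$death_threshold
  }
  live <- !is.na(monitored) & is.finite(thr)
  starving <- live & monitored < thr
  agents$clock[live & !starving] <- 0
  agents$clock[starving] <- agents$clock[starving] + dt
  delay <- setNames(species$death_delay, species$name)[agents$species]
  dies <- live & agents$clock >= delay
  agents$species[dies] <- "dead"  # irreversible; mass kept as inert biomass
  agents
}

#' Division of cells above the division radius
#'
#' A cell whose radius reaches the division radius (3 um) splits into
#' two daughters. The biomass is split 0.5 +/- 5% (uniform, seeded)
#' between them -- biomass is conserved exactly -- and the daughters are
#' placed at antipodal offsets of half a daughter radius along a random
#' direction; the subsequent relaxation separates them to contact. Each
#' methanogen daughter carries a fresh EPS capsule.
#'
#' @param agents agent tibble.
#' @param species species parameter tibble.
#' @param cfg a [world_config].
#' @param next_id next free agent id.
#' @return list with `agents`, `next_id`, `n_divided`.
#' @export
maybe_divide <- function(agents, species, cfg, next_id = NULL) {
  if (is.null(next_id)) next_id <- if (nrow(agents)) max(agents$id) + 1L else 1L
  r <- agent_radii(agents, species, cfg)
  divr <- setNames(species$division_radius, species$name)[agents$species]
  dead <- agents$species == "dead"
  idx <- which(!dead & r >= divr)
  if (length(idx) == 0) {
    return(list(agents = agents, next_id = next_id, n_divided = 0L))
  }
  k <- length(idx)
  frac <- runif(k, 0.45, 0.55)
  theta <- runif(k, 0, 2 * pi)
  parents <- agents[idx, ]
  caps <- setNames(species$eps_capsule_mass, species$name)[parents$species]
  m1 <- parents$mass * frac
  m2 <- parents$mass - m1
  dens <- setNames(species$biomass_density, species$name)[parents$species]
  r1 <- agent_radius(m1 + caps, dens, cfg$slice_thickness)
  r2 <- agent_radius(m2 + caps, dens, cfg$slice_thickness)
  off1x <- 0.5 * r1 * cos(theta); off1y <- 0.5 * r1 * sin(theta)
  off2x <- -0.5 * r2 * cos(theta); off2y <- -0.5 * r2 * sin(theta)

  agents$mass[idx] <- m1
  agents$capsule[idx] <- caps
  agents$x[idx] <- pmin(pmax(parents$x + off1x, 0), cfg$domain_width)
  agents$y[idx] <- pmin(pmax(parents$y + off1y, 0), cfg$domain_height)

  daughters <- agent_table(
    id = seq.int(next_id, length.out = k),
    species = parents$species,
    mass = m2, capsule = caps,
    x = pmin(pmax(parents$x + off2x, 0), cfg$domain_width),
    y = pmin(pmax(parents$y + off2y, 0), cfg$domain_height),
    clock = parents$clock)
  list(agents = dplyr::bind_rows(agents, daughters),
       next_id = next_id + k, n_divided = k)
}
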