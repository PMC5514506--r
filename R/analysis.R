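as_state_parts <- function(x, species = NULL, cfg = NULL) {
  if (inherits(x, "world_state")) {
    list(agents = x$agents, species = x$species, cfg = x$config)
  } else if (inherits(x, "granulation_run")) {
    list(agents = x$state$agents, species = x$species, cfg = x$config)
  } else {
    stopifnot(!is.null(species), !is.null(cfg))
    list(agents = x, species = species, cfg = cfg)
  }
}

#' Granule morphology metrics
#'
#' Finds the largest connected component of the contact graph (the
#' granule), its biomass-weighted centroid, its diameter -- twice the
#' 95th-percentile radial distance of its agents from the centroid,
#' robust to stray detached cells -- and the radius of the contiguous
#' dead-dominated core (outermost radial bin below which every occupied
#' bin holds more than 50% dead mass).
#'
#' @param x a `world_state`, `granulation_run`, or agent tibble (then
#'   `species` and `cfg` are required).
#' @param species,cfg parameter tibble and [world_config] when `x` is an
#'   agent tibble.
#' @param n_bins radial bins used for dead-core detection.
#' @param slack_frac contact slack for the component search.
#' @return tibble with one row: `centroid_x`, `centroid_y` (um),
#'   `diameter_mm`, `dead_core_radius_um`, `n_granule` (agents in the
#'   granule), `n_total`.
#' @export
granule_metrics <- function(x, species = NULL, cfg = NULL, n_bins = 20,
                            slack_frac = 0.3) {
  parts <- as_state_parts(x, species, cfg)
  agents <- parts$agents
  if (nrow(agents) == 0) {
    rlang::abort("no agents: granule metrics undefined",
                 class = "granusim_analysis_error")
  }
  comp <- contact_components(agents, parts$species, parts$cfg, slack_frac)
  main <- as.integer(names(which.max(table(comp))))
  g <- agents[comp == main, ]
  w <- g$mass + g$capsule
  cx <- sum(w * g$x) / sum(w)
  cy <- sum(w * g$y) / sum(w)
  d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  r <- agent_radii(g, parts$species, parts$cfg)
  diameter_um <- if (nrow(g) == 1) 2 * r else 2 * quantile(d, 0.95,
                                                           names = FALSE)
  # dead-core: contiguous central run of radial bins with >50% dead mass
  core <- 0
  if (nrow(g) > 1 && any(g$species == "dead")) {
    edges <- seq(0, max(d) + 1e-9, length.out = n_bins + 1)
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    for (b in seq_len(n_bins)) {
      inb <- bin == b
      tot <- sum(w[inb])
      if (tot == 0) next  # empty bin: keep scanning outward
      frac_dead <- sum(w[inb & g$species == "dead"]) / tot
      if (frac_dead > 0.5) core <- edges[b + 1] else break
    }
  }
  tibble::tibble(centroid_x = cx, centroid_y = cy,
                 diameter_mm = diameter_um / 1000,
                 dead_core_radius_um = core,
                 n_granule = nrow(g), n_total = nrow(agents))
}

#' Quarter-wise radial cell-type distribution
#'
#' Reproduces the published validation procedure on simulated output:
#' the granule disc is split into four angular quarters about the
#' centroid, agents are counted per cell type in concentric radial
#' bins within each quarter, and the across-quarter mean and standard
#' deviation per bin give the stratification profile with an error
#' estimate. The four quarters partition the disc, so the counts sum to
#' the number of agents within the outermost bin.
#'
#' @inheritParams granule_metrics
#' @param n_bins number of radial bins (>= 2).
#' @param max_radius outer analysis radius, um (default: the most
#'   distant agent of the main component).
#' @return object of class `radial_profile`: list with `counts` (tidy
#'   tibble: bin, bin_lo, bin_hi, quarter, species, count), `summary`
#'   (per bin and species: mean and sd across quarters) and `bin_edges`.
#' @export
radial_profile <- function(x, species = NULL, cfg = NULL, n_bins = 5,
                           max_radius = NULL) {
  stopifnot(n_bins >= 2)
  parts <- as_state_parts(x, species, cfg)
  agents <- parts$agents
  if (nrow(agents) == 0) {
    rlang::abort("no agents: radial profile undefined",
                 class = "granusim_analysis_error")
  }
  gm <- granule_metrics(x, species, cfg)
  dx <- agents$x - gm$centroid_x
  dy <- agents$y - gm$centroid_y
  d <- sqrt(dx^2 + dy^2)
  if (is.null(max_radius)) max_radius <- max(d) + 1e-9
  edges <- seq(0, max_radius, length.out = n_bins + 1)
  keep <- d <= max_radius
  theta <- atan2(dy[keep], dx[keep]) %% (2 * pi)
  quarter <- pmin(4L, as.integer(floor(theta / (pi / 2))) + 1L)
  bin <- pmin(n_bins, pmax(1L, findInterval(d[keep], edges,
                                            rightmost.closed = TRUE)))
  sp_levels <- intersect(c("acidogen", "methanogen", "dead"),
                         unique(c(parts$species$name, agents$species)))
  counts <- tidyr::expand_grid(bin = seq_len(n_bins), quarter = 1:4,
                               species = sp_levels)
  obs <- tibble::tibble(bin = bin, quarter = quarter,
                        species = agents$species[keep]) |>
    dplyr::count(.data$bin, .data$quarter, .data$species, name = "count")
  counts <- dplyr::left_join(counts, obs,
                             by = c("bin", "quarter", "species")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  bin_lo = edges[.data$bin], bin_hi = edges[.data$bin + 1])
  summary <- counts |>
    dplyr::group_by(.data$bin, .data$bin_lo, .data$bin_hi, .data$species) |>
    dplyr::summarise(mean = mean(.data$count), sd = sd(.data$count),
                     total = sum(.data$count), .groups = "drop")
  structure(list(counts = counts, summary = summary, bin_edges = edges,
                 centroid = c(gm$centroid_x, gm$centroid_y)),
            class = "radial_profile")
}

#' @exportS3Method print radial_profile
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d bins x 4 quarters, %d cells\n",
              length(x$bin_edges) - 1, sum(x$counts$count)))
  print(x$summary)
  invisible(x)
}

#' Radial profile of a labelled pixel grid
#'
#' Pixel-counting mode of [radial_profile()]: accepts any pre-labelled
#' grid (e.g. a segmented granule image) with one label per cell type
#' and zero/NA for background, and counts labelled pixels per radial
#' bin and quarter about the grid centre (or a given centre).
#'
#' @param labels integer or character matrix; 0, "" or NA = background.
#' @param n_bins number of radial bins.
#' @param center (x, y) centre in pixel units; default the label
#'   centroid.
#' @param pixel_size physical size of one pixel (scales `bin_edges`).
#' @return a `radial_profile` object.
#' @export
radial_profile_grid <- function(labels, n_bins = 5, center = NULL,
                                pixel_size = 1) {
  stopifnot(is.matrix(labels), n_bins >= 2)
  lab <- as.vector(labels)
  bg <- is.na(lab) | lab == 0 | lab == ""
  ix <- rep(seq_len(nrow(labels)), times = ncol(labels))
  iy <- rep(seq_len(ncol(labels)), each = nrow(labels))
  ix <- ix[!bg]; iy <- iy[!bg]; lab <- as.character(lab[!bg])
  if (length(lab) == 0) {
    rlang::abort("no labelled pixels", class = "granusim_analysis_error")
  }
  if (is.null(center)) center <- c(mean(ix), mean(iy))
  dx <- ix - center[1]; dy <- iy - center[2]
  d <- sqrt(dx^2 + dy^2)
  edges <- seq(0, max(d) + 1e-9, length.out = n_bins + 1)
  theta <- atan2(dy, dx) %% (2 * pi)
  quarter <- pmin(4L, as.integer(floor(theta / (pi / 2))) + 1L)
  bin <- pmin(n_bins, pmax(1L, findInterval(d, edges,
                                            rightmost.closed = TRUE)))
  counts <- tidyr::expand_grid(bin = seq_len(n_bins), quarter = 1:4,
                               species = sort(unique(lab)))
  obs <- tibble::tibble(bin = bin, quarter = quarter, species = lab) |>
    dplyr::count(.data$bin, .data$quarter, .data$species, name = "count")
  counts <- dplyr::left_join(counts, obs,
                             by = c("bin", "quarter", "species")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  bin_lo = edges[.data$bin] * pixel_size,
                  bin_hi = edges[.data$bin + 1] * pixel_size)
  summary <- counts |>
    dplyr::group_by(.data$bin, .data$bin_lo, .data$bin_hi, .data$species) |>
    dplyr::summarise(mean = mean(.data$count), sd = sd(.data$count),
                     total = sum(.data$count), .groups = "drop")
  structure(list(counts = counts, summary = summary,
                 bin_edges = edges * pixel_size, centroid = center),
            class = "radial_profile")
}

#' Specific methanogenic activity
#'
#' Converts the cumulative methane production of a run to a gas volume
#' (ideal-gas density of methane, default 0.716 g/L at 0 degC and
#' 1 atm) and divides by the final total agent mass. Reported both as
#' ml CH4 per g biomass and as a mass ratio.
#'
#' @param run a `granulation_run` (or a `world_state` with a cumulative
#'   methane ledger).
#' @param ch4_gas_density methane gas density, g/L.
#' @return tibble with one row: `ch4_g`, `ch4_ml`, `biomass_g`,
#'   `activity_ml_per_g`, `activity_g_per_g`.
#' @export
specific_methanogenic_activity <- function(run, ch4_gas_density = 0.716) {
  state <- if (inherits(run, "granulation_run")) run$state else run
  ch4_g <- state$cumulative_ch4 * 1e-15
  biomass_g <- sum(state$agents$mass + state$agents$capsule) * 1e-15
  if (biomass_g <= 0) {
    rlang::abort("zero biomass: specific activity undefined",
                 class = "granusim_analysis_error")
  }
  ch4_ml <- ch4_g / ch4_gas_density * 1000
  tibble::tibble(ch4_g = ch4_g, ch4_ml = ch4_ml, biomass_g = biomass_g,
                 activity_ml_per_g = ch4_ml / biomass_g,
                 activity_g_per_g = ch4_g / biomass_g)
}

#' Granule diameter over time
#'
#' Applies [granule_metrics()] to every stored snapshot.
#'
#' @param run a `granulation_run`.
#' @return tibble with `time` (h) and `diameter_mm`.
#' @export
diameter_series <- function(run) {
  purrr::map_dfr(run$snapshots, function(snap) {
    if (nrow(snap$agents) == 0) {
      return(tibble::tibble(time = snap$time, diameter_mm = NA_real_))
    }
    gm <- granule_metrics(snap$agents, run$species, run$config)
    tibble::tibble(time = snap$time, diameter_mm = gm$diameter_mm)
  })
}

#' First time a diameter is reached
#'
#' Linear interpolation of the snapshot diameter series at the first
#' upward crossing of `target_mm`.
#'
#' @param run a `granulation_run`.
#' @param target_mm target diameter, mm.
#' @return time, h (NA if never reached).
#' @export
time_to_diameter <- function(run, target_mm) {
  ds <- diameter_series(run)
  ds <- ds[!is.na(ds$diameter_mm), ]
  hit <- which(ds$diameter_mm >= target_mm)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(ds$time[1])
  t0 <- ds$time[i - 1]; t1 <- ds$time[i]
  d0 <- ds$diameter_mm[i - 1]; d1 <- ds$diameter_mm[i]
  t0 + (target_mm - d0) / (d1 - d0) * (t1 - t0)
}

#' Mean radial position per cell type
#'
#' The stratification statistic: mean distance from the granule
#' centroid per species. In a mature granule the ordering is
#' dead < methanogen < acidogen (dead core, methanogen shell, acidogen
#' rim).
#'
#' @inheritParams granule_metrics
#' @return tibble with `species`, `mean_radius_um`, `n`.
#' @export
radial_means <- function(x, species = NULL, cfg = NULL) {
  parts <- as_state_parts(x, species, cfg)
  gm <- granule_metrics(x, species, cfg)
  a <- parts$agents
  d <- sqrt((a$x - gm$centroid_x)^2 + (a$y - gm$centroid_y)^2)
  tibble::tibble(species = a$species, r = d) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(mean_radius_um = mean(.data$r), n = dplyr::n(),
                     .groups = "drop")
}
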