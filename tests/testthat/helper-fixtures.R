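# Small, fast protocols and geometric fixtures used across the suite.

# miniature granule protocol: 128 um domain, 32-node grid, 20+20 cells
tiny_protocol <- function(sbulk = 0.2, duration = 20, seed = 1, n = 20, ...) {
  default_protocol(sbulk = sbulk, grid_resolution = 32,
                   domain_width = 128, domain_height = 128,
                   init_counts = c(acidogen = n, methanogen = n),
                   init_region_radius = 8, duration = duration,
                   seed = seed, ...)
}

# configuration for hand-built agent tables (analysis fixtures)
fixture_cfg <- function(domain = 400, ...) {
  world_config(domain_width = domain, domain_height = domain,
               grid_resolution = 50, duration = 0, ...)
}

# concentric-ring fixture with known stratification:
# dead core (r < 50 um), methanogen shell (50-100), acidogen rim
# (100-150), centred at (200, 200). Cells are large (6 um) so the rings
# form one connected component; each shell holds a multiple of 4 cells
# at angles strictly inside the quarters, so per-quarter counts are
# exactly equal.
ring_agents <- function(cfg = fixture_cfg(), rotate = 0) {
  mass6 <- 573 * pi * cfg$slice_thickness * 36  # radius 6 um discs
  rows <- list()
  id <- 1L
  for (r in seq(5, 149, by = 8)) {
    sp <- if (r < 50) "dead" else if (r < 100) "methanogen" else "acidogen"
    nk <- max(8L, 4L * ceiling(2 * pi * r / 8 / 4))
    th <- 1e-3 + (seq_len(nk) - 1) * 2 * pi / nk + rotate
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = seq.int(id, length.out = nk), species = sp, mass = mass6,
      capsule = 0, x = 200 + r * cos(th), y = 200 + r * sin(th),
      clock = 0)
    id <- id + nk
  }
  dplyr::bind_rows(rows)
}
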