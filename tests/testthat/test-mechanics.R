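# brute-force all-pairs physical-overlap check, independent of the
# spatial hash (overlap beyond true contact r_i + r_j)
overlap_oracle <- function(agents, species, cfg) {
  r <- agent_radius(agents$mass + agents$capsule, 573, cfg$slice_thickness)
  worst <- -Inf
  n <- nrow(agents)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((agents$x[i] - agents$x[j])^2 +
                  (agents$y[i] - agents$y[j])^2)
      worst <- max(worst, (r[i] + r[j]) - d)
    }
  }
  worst
}

mkagents <- function(x, y, mass = 573 * pi * 2, species = "acidogen") {
  # default mass gives radius 1 um at slice thickness 2
  agent_table(id = seq_along(x), species = rep(species, length.out = length(x)),
              mass = rep(mass, length.out = length(x)),
              capsule = 0, x = x, y = y, clock = 0)
}

test_that("shoving separates overlapping pairs and leaves others alone", {
  sp <- default_species()
  cfg <- world_config(domain_width = 50, domain_height = 50,
                      grid_resolution = 8, shove_threshold_frac = 0)
  a <- mkagents(c(24, 25), c(25, 25))  # radius-1 cells at distance 1
  a2 <- relax(a, sp, cfg, tol = 1e-3)
  d <- sqrt(diff(a2$x)^2 + diff(a2$y)^2)
  expect_gte(d, 2 - 1e-2)
  # non-overlapping pair: exactly zero displacement
  b <- mkagents(c(10, 20), c(10, 10))
  res <- shove_pass(b, sp, cfg)
  expect_equal(res$max_disp, 0)
  expect_identical(res$agents$x, b$x)
  # pair displacements are equal and opposite
  res2 <- shove_pass(a, sp, cfg)
  expect_equal(res2$dx[1], -res2$dx[2])
  expect_equal(res2$dy[1], -res2$dy[2])
  # coincident centres get separated (random direction, seeded)
  set.seed(4)
  cc <- mkagents(c(25, 25), c(25, 25))
  cc2 <- relax(cc, sp, cfg, tol = 1e-3)
  expect_gt(sqrt(diff(cc2$x)^2 + diff(cc2$y)^2), 1)
})

test_that("relaxation removes all overlaps in dense clusters", {
  sp <- default_species()
  cfg <- world_config(domain_width = 60, domain_height = 60,
                      grid_resolution = 8, relax_max_pass = 400)
  set.seed(7)
  a <- mkagents(runif(60, 25, 35), runif(60, 25, 35))
  relaxed <- relax(a, sp, cfg, tol = 0.01)
  expect_lte(overlap_oracle(relaxed, sp, cfg), 0.05)
  expect_equal(max_pair_overlap(relaxed, sp, cfg),
               overlap_oracle(relaxed, sp, cfg), tolerance = 1e-9)
  # an already-relaxed state does not move (shove only)
  again <- relax(relaxed, sp, cfg, tol = 0.01, use_adhesion = FALSE)
  expect_equal(attr(again, "passes"), 1)
  expect_equal(again$x, relaxed$x, tolerance = 0.02)
})

test_that("relaxation monotonically reduces the maximum overlap", {
  sp <- default_species()
  cfg <- world_config(domain_width = 60, domain_height = 60,
                      grid_resolution = 8)
  set.seed(12)
  a <- mkagents(runif(30, 27, 33), runif(30, 27, 33))
  prev <- max_pair_overlap(a, sp, cfg)
  for (k in 1:15) {
    a <- shove_pass(a, sp, cfg)$agents
    cur <- max_pair_overlap(a, sp, cfg)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("adhesion draws nearby cells to contact and defaults off cleanly", {
  sp <- default_species()
  cfg <- world_config(domain_width = 50, domain_height = 50,
                      grid_resolution = 8, shove_threshold_frac = 0,
                      adhesion_hom = 0.2, adhesion_het = 0.2)
  a <- mkagents(c(24, 26.4), c(25, 25))  # gap 0.4 um beyond contact
  gaps <- numeric(30)
  for (k in 1:30) {
    a <- adhesion_pass(a, sp, cfg)
    gaps[k] <- sqrt(diff(a$x)^2 + diff(a$y)^2) - 2
  }
  expect_true(all(diff(gaps) <= 1e-12))   # monotone shrink
  expect_lt(gaps[30], 0.01)               # reaches contact
  # outside the attraction range: no motion
  b <- mkagents(c(10, 20), c(10, 10))
  expect_identical(adhesion_pass(b, sp, cfg)$x, b$x)
  # zero strengths: identity
  cfg0 <- world_config(domain_width = 50, domain_height = 50,
                       grid_resolution = 8, adhesion_hom = 0,
                       adhesion_het = 0)
  expect_identical(adhesion_pass(a, sp, cfg0), a)
})

test_that("agitation is a seeded 2-D random walk with rigid agglomerates", {
  sp <- default_species()
  cfg <- world_config(domain_width = 4000, domain_height = 4000,
                      grid_resolution = 100, agitation_strength = 2)
  # strength 0 is the identity
  a <- mkagents(c(100, 200), c(100, 200))
  expect_identical(agitate(a, sp, cfg, strength = 0), a)
  # ensemble of isolated walkers: MSD grows linearly, slope 2 sigma^2
  set.seed(21)
  n <- 150
  w <- mkagents(seq(200, 3800, length.out = n), rep(2000, n))
  x0 <- w$x; y0 <- w$y
  msd <- numeric(2)
  for (k in 1:100) w <- agitate(w, sp, cfg)
  msd[1] <- mean((w$x - x0)^2 + (w$y - y0)^2)
  for (k in 1:100) w <- agitate(w, sp, cfg)
  msd[2] <- mean((w$x - x0)^2 + (w$y - y0)^2)
  sigma2 <- cfg$agitation_strength^2
  expect_equal(msd[1], 2 * sigma2 * 100, tolerance = 0.25)
  expect_equal(msd[2] / msd[1], 2, tolerance = 0.25)
  # determinism under a fixed seed
  set.seed(33)
  w1 <- agitate(mkagents(c(50, 60), c(50, 50)), sp, cfg)
  set.seed(33)
  w2 <- agitate(mkagents(c(50, 60), c(50, 50)), sp, cfg)
  expect_identical(w1, w2)
  # touching cells move rigidly (one shared displacement; no jitter)
  set.seed(8)
  cfg_rigid <- world_config(domain_width = 4000, domain_height = 4000,
                            grid_resolution = 100, agitation_strength = 2,
                            agitation_jitter_frac = 0)
  pair <- mkagents(c(1000, 1001.9), c(1000, 1000))
  moved <- agitate(pair, sp, cfg_rigid)
  expect_equal(moved$x[1] - pair$x[1], moved$x[2] - pair$x[2])
  expect_equal(moved$y[1] - pair$y[1], moved$y[2] - pair$y[2])
})

test_that("agitation with adhesion aggregates dispersed cells", {
  sp <- default_species()
  cfg <- world_config(scenario = "reactor", domain_width = 200,
                      domain_height = 200, grid_resolution = 25,
                      agitation_strength = 4,
                      init_counts = c(acidogen = 100, methanogen = 100))
  st <- build_initial_state(cfg, sp, default_solutes(), seed = 5)
  a <- st$agents
  n0 <- max(contact_components(a, sp, cfg))
  set.seed(5)
  for (k in 1:500) {
    a <- agitate(a, sp, cfg)
    a <- relax(a, sp, cfg)
  }
  n1 <- max(contact_components(a, sp, cfg))
  expect_gt(n0, 150)       # starts dispersed
  expect_lt(n1, n0 / 2)    # agglomerates form
})

test_that("adhesion keeps clusters cohesive under agitation", {
  sp <- default_species()
  gyration <- function(a) {
    sqrt(mean((a$x - mean(a$x))^2 + (a$y - mean(a$y))^2))
  }
  base <- function(adh) {
    world_config(scenario = "reactor", domain_width = 300,
                 domain_height = 300, grid_resolution = 38,
                 agitation_strength = 3, adhesion_hom = adh,
                 adhesion_het = adh)
  }
  run_cluster <- function(cfg) {
    set.seed(14)
    th <- seq(0, 2 * pi, length.out = 21)[-21]
    a <- mkagents(150 + 3 * cos(th), 150 + 3 * sin(th))
    for (k in 1:200) {
      a <- agitate(a, sp, cfg)
      a <- relax(a, sp, cfg)
    }
    gyration(a)
  }
  g_on <- run_cluster(base(0.3))
  g_off <- run_cluster(base(0))
  expect_lt(g_on, 12)       # bounded: cluster holds together
  expect_gt(g_off, 2 * g_on)  # without adhesion the cluster disperses
})
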