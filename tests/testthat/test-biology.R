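acid <- default_species()[default_species()$name == "acidogen", ]
meth <- default_species()[default_species()$name == "methanogen", ]

test_that("Monod growth laws reproduce the half-saturation values", {
  # glucose at Ks, no acetate: half of mu_max
  expect_equal(growth_rate_acidogen(0.26, 0, acid), 0.104)
  # glucose at Ks, acetate at Ki: half-saturation x half-inhibition
  expect_equal(growth_rate_acidogen(0.26, 0.1, acid), 0.052)
  expect_equal(growth_rate_acidogen(0, 0.5, acid), 0)
  # acetate at Ks: half of mu_max
  expect_equal(growth_rate_methanogen(0.005, meth), 0.05)
  expect_equal(growth_rate_methanogen(0, meth), 0)
  # saturation: large acetate approaches mu_max
  expect_equal(growth_rate_methanogen(100, meth), 0.1, tolerance = 1e-4)
  expect_error(growth_rate_acidogen(-0.1, 0, acid),
               class = "granusim_domain_error")
  expect_error(growth_rate_methanogen(-1, meth),
               class = "granusim_domain_error")
})

test_that("growth rates are monotone and bounded by mu_max", {
  sg <- seq(0, 2, length.out = 50)
  mu <- growth_rate_acidogen(sg, 0.05, acid)
  expect_true(all(diff(mu) > 0))          # increasing in glucose
  expect_true(all(mu >= 0 & mu <= acid$mu_max))
  sa <- seq(0, 1, length.out = 50)
  mu_inh <- growth_rate_acidogen(0.26, sa, acid)
  expect_true(all(diff(mu_inh) < 0))      # decreasing in acetate
  mu_m <- growth_rate_methanogen(sa, meth)
  expect_true(all(diff(mu_m) > 0))
  expect_true(all(mu_m <= meth$mu_max))
})

test_that("one growth step follows the yields exactly", {
  sp <- default_species()
  a <- agent_table(id = 1, species = "acidogen", mass = 300, capsule = 0,
                   x = 10, y = 10, clock = 0)
  # S_g = Ks, S_a = 0: mu = 0.104/h, dm = 31.2 fg over 1 h
  conc <- list(glucose = 0.26, acetate = 0, methane = 0)
  rep1 <- step_growth(a, sp, conc, dt = 1)
  expect_equal(rep1$mu, 0.104)
  expect_equal(rep1$biomass_gained, 31.2)
  expect_equal(rep1$substrate_consumed, 104)        # 31.2 / 0.3
  expect_equal(rep1$product_secreted, 85.28)        # 104 * 0.82
  # zero substrate: zero-change report
  rep0 <- step_growth(a, sp, list(glucose = 0, acetate = 0, methane = 0), 1)
  expect_equal(rep0$biomass_gained, 0)
  expect_equal(rep0$substrate_consumed, 0)
  # dead agents do not grow
  d <- a |> dplyr::mutate(species = "dead")
  repd <- step_growth(d, sp, conc, 1)
  expect_equal(repd$biomass_gained, 0)
  # methanogen stoichiometry: CH4 = 0.26 x acetate consumed
  m <- agent_table(id = 2, species = "methanogen", mass = 1500,
                   capsule = 10, x = 10, y = 10, clock = 0)
  repm <- step_growth(m, sp, list(glucose = 0, acetate = 1, methane = 0), 1)
  expect_equal(repm$product_secreted,
               repm$substrate_consumed * 0.26)
  expect_equal(repm$biomass_gained,
               repm$substrate_consumed * 0.15)
  # literal stoichiometry mode: product equals substrate consumed
  repl <- step_growth(m, sp, list(glucose = 0, acetate = 1, methane = 0), 1,
                      literal_methane = TRUE)
  expect_equal(repl$product_secreted, repl$substrate_consumed)
})

test_that("starvation kills after exactly the death delay, with reset", {
  sp <- default_species()
  cfg <- world_config()
  a <- agent_table(id = 1, species = "acidogen", mass = 300, capsule = 0,
                   x = 10, y = 10, clock = 0)
  starve <- list(glucose = 0.01, acetate = 0, methane = 0)  # < 0.02 g/L
  fed <- list(glucose = 0.05, acetate = 0, methane = 0)
  for (h in 1:47) a <- step_death(a, sp, starve, 1, cfg)
  expect_equal(a$species, "acidogen")   # 47 h below threshold: alive
  expect_equal(a$clock, 47)
  a48 <- step_death(a, sp, starve, 1, cfg)
  expect_equal(a48$species, "dead")     # 48 h: irreversible conversion
  expect_equal(a48$mass, 300)           # mass preserved as inert biomass
  # dead stays dead even in plentiful substrate
  arev <- step_death(a48, sp, list(glucose = 10, acetate = 10,
                                   methane = 0), 1, cfg)
  expect_equal(arev$species, "dead")
  # recovery at 40 h resets the clock
  b <- agent_table(id = 1, species = "acidogen", mass = 300, capsule = 0,
                   x = 10, y = 10, clock = 40)
  b <- step_death(b, sp, fed, 1, cfg)
  expect_equal(b$clock, 0)
  expect_equal(b$species, "acidogen")
  # methanogens monitor acetate by default ...
  m <- agent_table(id = 2, species = "methanogen", mass = 1500,
                   capsule = 10, x = 1, y = 1, clock = 0)
  m1 <- step_death(m, sp, list(glucose = 0, acetate = 1e-6, methane = 0),
                   1, cfg)
  expect_equal(m1$clock, 1)
  # ... or glucose under the literal switch
  cfg_lit <- world_config(methanogen_starves_on = "glucose")
  m2 <- step_death(m, sp, list(glucose = 1, acetate = 1e-6, methane = 0),
                   1, cfg_lit)
  expect_equal(m2$clock, 0)
})

test_that("division conserves biomass and splits near the division radius", {
  sp <- default_species()
  cfg <- world_config()
  m_div <- 573 * pi * cfg$slice_thickness * 3.1^2  # radius 3.1 um
  a <- agent_table(id = 1, species = "acidogen", mass = m_div, capsule = 0,
                   x = 100, y = 100, clock = 0)
  set.seed(2)
  res <- maybe_divide(a, sp, cfg, next_id = 2L)
  expect_equal(nrow(res$agents), 2)
  expect_equal(sum(res$agents$mass), m_div)            # exact conservation
  expect_true(all(abs(res$agents$mass / m_div - 0.5) <= 0.05 + 1e-12))
  expect_equal(res$agents$id, c(1L, 2L))
  expect_equal(res$next_id, 3L)
  # below the division radius: unchanged
  small <- a |> dplyr::mutate(mass = 300)
  res2 <- maybe_divide(small, sp, cfg, next_id = 2L)
  expect_identical(res2$agents, small)
  # dead cells never divide
  deadbig <- a |> dplyr::mutate(species = "dead")
  expect_equal(nrow(maybe_divide(deadbig, sp, cfg)$agents), 1)
})

test_that("unlimited substrate gives exponential growth at about mu_max", {
  # small division radius so count tracks biomass closely
  sp <- dplyr::bind_rows(
    species_params("acidogen", cell_mass = 300, division_radius = 0.45,
                   mu_max = 0.208, Ks = 0.26, Ki = 0.1,
                   yield_biomass = 0.3, yield_product = 0.82,
                   death_threshold = 0.02, substrate = "glucose",
                   product = "acetate"),
    dead_species())
  cfg <- world_config(domain_width = 200, domain_height = 200,
                      grid_resolution = 25, relax_max_pass = 20)
  a <- agent_table(id = 1, species = "acidogen", mass = 300, capsule = 0,
                   x = 100, y = 100, clock = 0)
  conc_of <- function(n) list(glucose = rep(100, n), acetate = rep(0, n),
                              methane = rep(0, n))
  set.seed(9)
  dt <- 0.25
  nid <- 2L
  t_tot <- 30
  for (k in seq_len(t_tot / dt)) {
    repk <- step_growth(a, sp, conc_of(nrow(a)), dt)
    a$mass <- a$mass + repk$biomass_gained
    div <- maybe_divide(a, sp, cfg, nid)
    a <- div$agents; nid <- div$next_id
  }
  mu_hat <- 0.208  # saturated growth (inhibition-free, S >> Ks)
  mass_rate <- log(sum(a$mass) / 300) / t_tot
  count_rate <- log(nrow(a)) / t_tot
  expect_equal(mass_rate, mu_hat, tolerance = 0.05)  # Euler discretization
  expect_equal(count_rate, mu_hat, tolerance = 0.2)  # doubling time ~ ln2/mu
  expect_true(all(a$mass > 0))
})
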