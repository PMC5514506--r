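test_that("an empty world advances and fields match the boundary data", {
  proto <- tiny_protocol(sbulk = 0.15)
  cfg <- proto$config
  cfg$init_counts <- c(acidogen = 0, methanogen = 0)
  st <- build_initial_state(cfg, proto$species, proto$solutes, seed = 1)
  st2 <- step_world(st)
  expect_equal(st2$time, cfg$timestep)
  expect_equal(max(abs(st2$fields$glucose - 0.15)), 0, tolerance = 1e-10)
  expect_equal(max(abs(st2$fields$acetate)), 0, tolerance = 1e-12)
  expect_equal(st2$cumulative_ch4, 0)
})

test_that("a single acidogen produces acetate within one step", {
  proto <- tiny_protocol()
  cfg <- proto$config
  cfg$init_counts <- c(acidogen = 1, methanogen = 0)
  set.seed(1)
  st <- build_initial_state(cfg, proto$species, proto$solutes, seed = NULL)
  st2 <- step_world(st)
  expect_gt(max(st2$fields$acetate), 0)
  expect_gt(st2$cumulative_glucose_consumed, 0)
  expect_gt(st2$agents$mass, 300)
  expect_equal(st2$cumulative_ch4, 0)  # no methanogens yet
})

test_that("runs are deterministic under a fixed seed", {
  r1 <- run_simulation(tiny_protocol(duration = 8, seed = 31))
  r2 <- run_simulation(tiny_protocol(duration = 8, seed = 31))
  expect_identical(r1$state$agents, r2$state$agents)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$state$fields, r2$state$fields)
  r3 <- run_simulation(tiny_protocol(duration = 8, seed = 32))
  expect_false(identical(r3$state$agents$x, r1$state$agents$x))
})

test_that("the run ledger closes stoichiometrically", {
  run <- run_simulation(tiny_protocol(duration = 40, seed = 2))
  s <- run$summary
  # clocks and ledgers are monotone
  expect_true(all(diff(s$time) > 0))
  expect_true(all(diff(s$ch4_cumulative_g) >= 0))
  expect_true(all(diff(s$glucose_consumed_g) >= 0))
  # methane produced = 0.26 x acetate consumed, exactly, at all times
  expect_equal(s$ch4_cumulative_g, 0.26 * s$acetate_consumed_g,
               tolerance = 1e-12)
  # acetate cannot be consumed faster than it is produced
  acetate_produced <- 0.82 * s$glucose_consumed_g
  expect_true(all(s$acetate_consumed_g <= acetate_produced + 1e-18))
  # closed-system acetate balance: standing mass = produced - consumed
  # (to the agent-draw vs field-sink discretization mismatch)
  n <- nrow(s)
  expect_equal(s$acetate_g[n],
               0.82 * s$glucose_consumed_g[n] - s$acetate_consumed_g[n],
               tolerance = 0.05)
  # living + dead biomass never decreases (no decay in the model)
  total_mass <- s$acidogen_mass_fg + s$methanogen_mass_fg + s$dead_mass_fg
  expect_true(all(diff(total_mass) >= -1e-9))
  # biomass gain follows the yields: dB = 0.3 dG(acidogen) + 0.15 dA(methanogen)
  gain_fg <- (total_mass - total_mass[1])
  expected_fg <- (0.3 * s$glucose_consumed_g +
                    0.15 * s$acetate_consumed_g) * 1e15
  expect_equal(gain_fg, expected_fg, tolerance = 1e-6)
  # agent ids stay unique through division
  expect_equal(anyDuplicated(run$state$agents$id), 0)
})

test_that("substrate draw is capped by local availability", {
  cap <- granusim:::cap_substrate_draws
  # two agents overdraw cell 1 (budget 100 against demand 120); the
  # third overdraws cell 2; scales are per cell, shared by its users
  res <- cap(consumed = c(60, 60, 10),
             substrate = c("glucose", "glucose", "glucose"),
             cell = c(1L, 1L, 2L),
             budget = list(glucose = c(100, 5)), nsub = 1)
  expect_true(res$capped)
  expect_equal(res$scale, c(100 / 120, 100 / 120, 0.5))
  # within budget: identity, no cap event
  ok <- cap(consumed = c(1, 2), substrate = c("glucose", "acetate"),
            cell = c(1L, 1L), budget = list(glucose = 10, acetate = 10),
            nsub = 1)
  expect_false(ok$capped)
  expect_equal(ok$scale, c(1, 1))
  # dead agents (no substrate) are never scaled
  dead <- cap(consumed = c(5, 0), substrate = c("glucose", NA),
              cell = c(1L, 1L), budget = list(glucose = 1), nsub = 1)
  expect_equal(dead$scale[2], 1)
  # the budget is shared across sub-steps
  sub <- cap(consumed = 10, substrate = "glucose", cell = 1L,
             budget = list(glucose = 40), nsub = 4)
  expect_equal(sub$scale, 1)
  sub2 <- cap(consumed = 20, substrate = "glucose", cell = 1L,
              budget = list(glucose = 40), nsub = 4)
  expect_equal(sub2$scale, 0.5)
})

test_that("acidogen growth precedes methanogen growth", {
  run <- run_simulation(tiny_protocol(duration = 60, seed = 6))
  s <- run$summary
  half <- s$time <= 30
  acid_gain_early <- s$acidogen_mass_fg[sum(half)] / s$acidogen_mass_fg[1]
  meth_gain_early <- s$methanogen_mass_fg[sum(half)] / s$methanogen_mass_fg[1]
  # acidogens have glucose from t = 0; methanogens must wait for acetate
  expect_gt(acid_gain_early, meth_gain_early)
  # methane appears only after acetate has accumulated
  t_acetate <- s$time[which(s$acetate_g > 0)[1]]
  t_ch4 <- s$time[which(s$ch4_cumulative_g > 0)[1]]
  expect_gte(t_ch4, t_acetate)
})

test_that("reactor scenario is mechanics-only unless growth is enabled", {
  proto <- tiny_protocol(duration = 5, seed = 3)
  proto$config$scenario <- "reactor"
  proto$config$init_counts <- c(acidogen = 10, methanogen = 10)
  run <- run_simulation(proto)
  expect_equal(sum(run$state$agents$mass),
               sum(10 * 300 + 10 * 1500))  # no growth
  proto$config$reactor_growth <- TRUE
  run2 <- run_simulation(proto)
  expect_gt(sum(run2$state$agents$mass), 10 * 300 + 10 * 1500)
})

test_that("zero-duration runs return the initial state only", {
  run <- run_simulation(tiny_protocol(duration = 0, seed = 1))
  expect_equal(nrow(run$summary), 1)
  expect_equal(run$state$time, 0)
  expect_equal(length(run$snapshots), 1)
})

test_that("run outputs are written as plain-text tables", {
  run <- run_simulation(tiny_protocol(duration = 5, seed = 1))
  dir <- withr::local_tempdir()
  write_run_outputs(run, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "field_glucose.csv")))
  s <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(s), nrow(run$summary))
  ag <- list.files(dir, pattern = "^agents_")
  expect_equal(length(ag), length(run$snapshots))
})
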