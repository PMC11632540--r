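test_that("runs are deterministic and the two engines are bit-identical", {
  cfg <- tiny_cfg()
  for (sc in list(c(0, 0, 0), c(0.3, 1, 0.15))) {
    a <- run_simulation(cfg, sc, seed = 7, engine = "cpp", log_events = TRUE)
    b <- run_simulation(cfg, sc, seed = 7, engine = "cpp", log_events = TRUE)
    expect_identical(a$daily, b$daily)
    r <- run_simulation(cfg, sc, seed = 7, engine = "r", log_events = TRUE)
    expect_equal(a[c("overdoses_total", "deaths_total", "overdoses_released",
                     "deaths_released", "kits_total", "census_mean")],
                 r[c("overdoses_total", "deaths_total", "overdoses_released",
                     "deaths_released", "kits_total", "census_mean")])
    expect_identical(a$daily, r$daily)
    expect_equal(unclass(a$ledger), unclass(r$ledger))
    expect_equal(a$events, r$events)
  }
})

test_that("degenerate hazards behave: no fatality, no overdoses", {
  cfg <- tiny_cfg(f_fatal = 0)
  run <- run_simulation(cfg, c(0, 0, 0), seed = 1)
  expect_gt(run$overdoses_total, 0)
  expect_equal(run$deaths_total, 0)
  run0 <- run_simulation(tiny_cfg(p0_daily_od = 0), c(0, 0, 0), seed = 1)
  expect_equal(run0$overdoses_total, 0)
})

test_that("tallies satisfy their ordering invariants", {
  run <- run_simulation(thn_config(scale = 0.05), c(0, 1, 0), seed = 2)
  expect_lte(run$deaths_total, run$overdoses_total)
  expect_lte(run$deaths_released, run$overdoses_released)
  expect_lte(run$overdoses_released, run$overdoses_total)
  expect_lte(run$deaths_released, run$deaths_total)
})

test_that("warm-up tallies never leak into horizon tallies", {
  cfg <- tiny_cfg(p0_daily_od = 5e-3)   # plenty of warm-up events
  run <- run_simulation(cfg, c(0, 0, 0), seed = 3, log_events = TRUE)
  expect_true(all(run$events$day >= 0))
  expect_true(all(run$events$day < cfg$horizon))
  expect_equal(nrow(run$events), run$overdoses_total)
  expect_equal(nrow(run$daily), cfg$warmup + cfg$horizon)
})

test_that("horizon deaths match the closed-form expectation oracle", {
  # homogeneous reference population, no jail: E[deaths] =
  # n * horizon * p0 * P(fatal | event, no kit), depletion negligible
  cfg <- flat_cfg(n = 5000, p0 = 3e-4, horizon = 300)
  reps <- run_replicates(cfg, c(0, 0, 0), n = 5, base_seed = 11)
  p_day <- cfg$p0_daily_od
  p_fatal <- analytic_death_probability(cfg, FALSE)
  expected <- 5000 * 300 * p_day * p_fatal
  se <- sqrt(expected / 5)
  expect_lt(abs(reps$deaths_total - expected), 3 * se)
  # and overdoses themselves
  exp_od <- 5000 * 300 * p_day
  expect_lt(abs(reps$overdoses_total - exp_od), 3 * sqrt(exp_od / 5))
})

test_that("replicate averaging is the arithmetic mean of its runs", {
  cfg <- tiny_cfg()
  reps <- run_replicates(cfg, c(0.15, 0.5, 0.15), n = 3, base_seed = 4)
  expect_equal(reps$deaths_total,
               mean(vapply(reps$runs, `[[`, numeric(1), "deaths_total")))
  expect_equal(reps$kits_total,
               mean(vapply(reps$runs, `[[`, numeric(1), "kits_total")))
  one <- run_replicates(cfg, c(0.15, 0.5, 0.15), n = 1, base_seed = 4)
  expect_equal(one$deaths_total, one$runs[[1]]$deaths_total)
  expect_equal(one$runs[[1]]$seed, derive_seed(4, 0, 1))
})

test_that("derived seeds are distinct across sweep cells", {
  cells <- expand.grid(draw = 0:63, rep = 1:10)
  seeds <- mapply(derive_seed, 1L, cells$draw, cells$rep)
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_identical(derive_seed(1, 5, 2), derive_seed(1, 5, 2))
})

test_that("sweeps include a baseline per draw and zero-coverage averts nothing", {
  cfg <- tiny_cfg()
  draws <- sample_parameter_draws(default_ranges(), 2, "uniform_random", 5)
  # request a 'coverage-zero intervention' plus one real scenario: the
  # baseline is added automatically
  sc <- scenario_grid()[c(1, 19), ]
  sw <- run_sweep(cfg, draws, sc, replicates = 2, base_seed = 6)
  expect_equal(nrow(sw), 2 * 2)
  expect_true(all(c(1, 19) %in% sw$scenario))
  pm <- per_draw_metrics(sw)
  expect_equal(pm$pct_averted[pm$scenario == 1], c(0, 0))  # exact, CRN
  expect_equal(pm$deaths_averted[pm$scenario == 1], c(0, 0))
})

test_that("fatal outcomes respond monotonically to bystander presence (CRN)", {
  lo <- thn_config(scale = 0.02, p_bystander = 0.3)
  hi <- thn_config(scale = 0.02, p_bystander = 0.9)
  for (seed in 1:3) {
    d_lo <- run_simulation(lo, c(0.3, 1, 0.3), seed = seed)$deaths_total
    d_hi <- run_simulation(hi, c(0.3, 1, 0.3), seed = seed)$deaths_total
    expect_lte(d_hi, d_lo)
  }
})

test_that("run export writes the daily, ledger and event tables", {
  run <- run_simulation(tiny_cfg(), c(0.3, 1, 0.3), seed = 8, log_events = TRUE)
  dir <- withr::local_tempdir()
  write_run_csv(run, dir)
  expect_true(file.exists(file.path(dir, "daily.csv")))
  led <- utils::read.csv(file.path(dir, "ledger.csv"))
  expect_equal(led$community + led$jail + led$network + led$replacements,
               run$kits_total)
  expect_true(file.exists(file.path(dir, "events.csv")))
})
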