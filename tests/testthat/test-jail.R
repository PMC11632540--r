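test_that("log-normal stay fit matches the published median and mean exactly", {
  cfg <- thn_config()
  d <- stay_distribution(cfg)
  expect_equal(exp(d$meanlog), 12)                      # analytic median
  expect_equal(exp(d$meanlog + d$sdlog^2 / 2), 54.1)    # analytic mean
  expect_equal(d$sdlog, sqrt(2 * log(54.1 / 12)))
  expect_error(stay_distribution(thn_config(stay_mean = 10, stay_median = 12)),
               "log-normal")
})

test_that("stay draws are positive whole days with the right location", {
  cfg <- thn_config()
  set.seed(1)
  s <- sample_stay_duration(cfg, 20000)
  expect_true(all(s >= 1L) && is.integer(s))
  # ceiling shifts the median of a continuous median-12 law to ~12
  expect_lt(abs(stats::median(s) - 12), 1.01)
})

test_that("bookings draw Poisson counts and sample the free CLI pool uniformly", {
  cfg <- thn_config(n_iou = 200, n_niou = 600, n_cli = 500, booking_rate = 5,
                    stay_mean = 10, stay_median = 5, scale = 1)
  pop <- build_population(cfg, seed = 3)
  state <- new_jail_state()
  rng <- thn_rng(77)
  booked_per_day <- integer(200)
  for (day in 1:200) {
    bk <- step_bookings(pop, state, day, cfg, rng)
    pop <- bk$pop; state <- bk$state
    booked_per_day[day] <- length(bk$booked)
    rl <- step_releases(pop, state, day)
    pop <- rl$pop
    expect_true(all(pop$cli[bk$booked]))            # only CLI persons book
  }
  expect_lt(abs(mean(booked_per_day) - 5), 3 * sqrt(5 / 200))
  # zero rate books no one
  cfg0 <- thn_config(booking_rate = 0)
  pop0 <- build_population(tiny_cfg(booking_rate = 0), seed = 1)
  expect_length(step_bookings(pop0, new_jail_state(), 1, cfg0)$booked, 0)
})

test_that("release bookkeeping: booked day d with stay s releases once at d+s", {
  cfg <- thn_config(n_iou = 50, n_niou = 100, n_cli = 100, booking_rate = 3,
                    scale = 1)
  pop <- build_population(cfg, seed = 5)
  state <- new_jail_state()
  set.seed(42)
  bk <- step_bookings(pop, state, 10, cfg)
  pop <- bk$pop
  expect_gt(length(bk$booked), 0)
  scheduled <- pop$release_day[bk$booked]
  expect_true(all(scheduled > 10))
  released_log <- integer(0)
  for (day in 11:max(scheduled)) {
    rl <- step_releases(pop, state, day)
    pop <- rl$pop
    if (length(rl$released)) {
      expect_true(all(scheduled[match(rl$released, bk$booked)] == day))
      expect_true(all(pop$days_since_release[rl$released] == 0L))
      # release day itself sits in the week 0-2 risk window
      expect_equal(release_multiplier(cfg, pop$days_since_release[rl$released]),
                   rep(cfg$rr_release_wk0_2, length(rl$released)))
      released_log <- c(released_log, rl$released)
    }
  }
  expect_identical(sort(released_log), sort(bk$booked))  # exactly one release each
})

test_that("steady-state seeding fills the jail to the census target", {
  cfg <- thn_config(scale = 0.02)
  pop <- build_population(cfg, seed = 6)
  set.seed(6)
  init <- initialize_steady_state(pop, cfg)
  expect_equal(sum(init$pop$in_jail), round(6000 * 0.02))
  expect_true(all(init$pop$release_day[init$pop$in_jail] >= -cfg$warmup))
  # length-biased residual stays: mean total stay of seeded inmates exceeds
  # the fresh-draw mean
  d <- stay_distribution(cfg)
  set.seed(1)
  lb <- stats::rlnorm(20000, d$meanlog + d$sdlog^2, d$sdlog)
  expect_gt(mean(lb), 54.1)
})

test_that("census conservation holds exactly at every tick", {
  cfg <- tiny_cfg()
  for (eng in c("cpp", "r")) {
    run <- run_simulation(cfg, c(0, 0.5, 0), seed = 8, engine = eng)
    d <- run$daily
    expect_equal(d$census,
                 run$census0 + cumsum(d$bookings) - cumsum(d$releases),
                 info = eng)
  }
})

test_that("long-run census obeys Little's law within 5%", {
  # no overdoses: pure queue; expected census = booking rate x mean stay
  cfg <- thn_config(scale = 0.05, p0_daily_od = 0, horizon = 2000, warmup = 0)
  run <- run_simulation(cfg, c(0, 0, 0), seed = 12)
  expected <- 132 * 0.05 * 54.1
  burn <- run$daily$census[run$daily$day > 500]
  expect_lt(abs(mean(burn) - expected) / expected, 0.05)
})

test_that("in-custody composition converges to the inmate use fractions", {
  cfg <- thn_config(scale = 0.05, p0_daily_od = 0, horizon = 600, warmup = 0)
  pop <- build_population(cfg, seed = 13)
  set.seed(13)
  init <- initialize_steady_state(pop, cfg)
  pop <- init$pop
  state <- new_jail_state()
  rng <- thn_rng(13)
  for (day in 0:599) {
    bk <- step_bookings(pop, state, day, cfg, rng)
    pop <- bk$pop; state <- bk$state
    pop <- step_releases(pop, state, day)$pop
  }
  inmates <- which(pop$in_jail)
  n <- length(inmates)
  frac_iou <- mean(pop$use_type[inmates] == 1L)
  expect_lt(abs(frac_iou - 0.035), 3 * sqrt(0.035 * 0.965 / n))
})
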