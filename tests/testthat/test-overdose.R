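test_that("relative risk multiplies the published attribute effects", {
  cfg <- thn_config()
  # all reference categories: male, NIOU, 18-24, never incarcerated
  expect_equal(relative_risk(cfg, "NIOU", FALSE, "18-24", NA), 1.0)
  cfg2 <- thn_config(rr_female = 0.8, rr_iou = 3, rr_release_wk0_2 = 6,
                     rr_age_30plus = 2)
  expect_equal(relative_risk(cfg2, "IOU", TRUE, ">=30", 5), 28.8)
  # worst-case corner of the uncertainty ranges
  hi <- thn_config(rr_female = 1.41, rr_iou = 9, rr_release_wk0_2 = 10,
                   rr_age_30plus = 5.15)
  expect_equal(relative_risk(hi, "IOU", TRUE, ">=30", 0), 1.41 * 9 * 10 * 5.15)
  expect_error(relative_risk(cfg, "NONE", FALSE, "18-24", NA), "opioids")
})

test_that("post-release windows are half-open at 14 and 28 days", {
  cfg <- thn_config()
  m <- release_multiplier(cfg, c(NA, 0, 13, 14, 27, 28, 365))
  expect_equal(m, c(1, cfg$rr_release_wk0_2, cfg$rr_release_wk0_2,
                    cfg$rr_release_wk3_4, cfg$rr_release_wk3_4,
                    cfg$rr_release_wk5plus, cfg$rr_release_wk5plus))
})

test_that("daily overdose probability scales the baseline and clamps at 1", {
  cfg <- thn_config(p0_daily_od = 3.3e-4)
  expect_equal(daily_overdose_probability(cfg, "NIOU", FALSE, "18-24", NA),
               3.3e-4)
  cfg2 <- thn_config(p0_daily_od = 3.3e-4, rr_female = 0.8, rr_iou = 3,
                     rr_release_wk0_2 = 6, rr_age_30plus = 2)
  expect_equal(daily_overdose_probability(cfg2, "IOU", TRUE, ">=30", 5),
               3.3e-4 * 28.8)
  path <- thn_config(p0_daily_od = 0.5, rr_iou = 9)
  expect_equal(daily_overdose_probability(path, "IOU", FALSE, "18-24", NA), 1)
})

test_that("overdose draws hit the closed-form expectation and spare the jailed", {
  cfg <- flat_cfg(n = 2000, p0 = 3e-3)
  pop <- build_population(cfg, seed = 1)
  pop$in_jail[1:100] <- TRUE
  set.seed(2)
  total <- 0L
  for (day in 1:200) {
    ids <- draw_overdoses(pop, cfg)
    expect_false(any(ids %in% 1:100))
    total <- total + length(ids)
  }
  expected <- 1900 * 200 * 3e-3
  expect_lt(abs(total - expected), 3 * sqrt(expected))
  expect_length(draw_overdoses(pop, thn_config(p0_daily_od = 0)), 0)
})

test_that("bystander tree enumeration matches the frozen hand computation", {
  cfg <- thn_config(f_fatal = 0.10, p_bystander = 0.6, p_administer = 0.7,
                    p_ems = 0.5, eff_naloxone = 0.95, eff_ems = 0.5)
  # 0.10 * (0.4 + 0.6 * (0.7 * 0.05 + 0.3 * (0.5 * 0.5 + 0.5)))
  expect_equal(analytic_death_probability(cfg, TRUE), 0.0556)
  # no kit: p_administer is a dead branch
  expect_equal(analytic_death_probability(cfg, FALSE),
               0.10 * (1 - 0.6 * 0.5 * 0.5))
  cfg2 <- thn_config(p_administer = 0.9)
  expect_equal(analytic_death_probability(cfg2, FALSE),
               analytic_death_probability(cfg, FALSE))
})

test_that("stochastic resolution agrees with the analytic oracle", {
  cfg <- thn_config(f_fatal = 0.10, p_bystander = 0.6, p_administer = 0.7,
                    p_ems = 0.5, eff_naloxone = 0.95, eff_ems = 0.5)
  n <- 1e5
  set.seed(3)
  for (avail in c(TRUE, FALSE)) {
    ev <- resolve_overdose(cfg, rep(avail, n))
    p <- analytic_death_probability(cfg, avail)
    expect_lt(abs(mean(ev$fatal) - p), 3 * sqrt(p * (1 - p) / n))
    # structural invariants of the tree
    expect_true(all(ev$bystander_present[ev$naloxone_administered]))
    expect_true(all(ev$bystander_present[ev$ems_called]))
    if (!avail) expect_false(any(ev$naloxone_administered))
    # branch frequencies: chi-square goodness of fit against the tree
    pb <- cfg$p_bystander; pa <- if (avail) cfg$p_administer else 0
    pe <- cfg$p_ems
    branch_prob <- function(by, adm, ems) {
      if (!by) return(if (!adm && !ems) 1 - pb else 0)
      pb * (if (adm) pa else 1 - pa) * (if (ems) pe else 1 - pe)
    }
    key <- paste(ev$bystander_present, ev$naloxone_administered,
                 ev$ems_called, sep = "/")
    tab <- table(key)
    probs <- vapply(strsplit(names(tab), "/", fixed = TRUE), function(s) {
      b <- as.logical(s)
      branch_prob(b[1], b[2], b[3])
    }, numeric(1))
    expect_true(all(probs > 0))
    expect_equal(sum(probs), 1)  # all positive-probability branches observed
    chisq <- stats::chisq.test(tab, p = probs)
    expect_gt(chisq$p.value, 0.001)
  }
})

test_that("keyed resolution reproduces the same law as the stream version", {
  cfg <- thn_config()
  rng <- thn_rng(5)
  n <- 2e4
  # distinct (pid, day) keys give i.i.d. uniforms
  ev <- resolve_overdose(cfg, rep(TRUE, n), rng, pids = seq_len(n), day = 1L)
  p <- analytic_death_probability(cfg, TRUE)
  expect_lt(abs(mean(ev$fatal) - p), 4 * sqrt(p * (1 - p) / n))
  expect_identical(ev, resolve_overdose(cfg, rep(TRUE, n), rng,
                                        pids = seq_len(n), day = 1L))
})

test_that("death probability responds monotonically to the tree parameters", {
  grid <- expand.grid(p_by = c(0.3, 0.6, 0.9), p_adm = c(0.5, 0.7, 0.9),
                      p_ems = c(0.2, 0.5, 0.8))
  for (avail in c(TRUE, FALSE)) {
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      base <- thn_config(p_bystander = g$p_by, p_administer = g$p_adm,
                         p_ems = g$p_ems)
      p0 <- analytic_death_probability(base, avail)
      # non-increasing in bystander presence
      up <- thn_config(p_bystander = min(1, g$p_by + 0.05),
                       p_administer = g$p_adm, p_ems = g$p_ems)
      expect_lte(analytic_death_probability(up, avail), p0)
      # non-increasing in administration probability (given availability)
      up <- thn_config(p_bystander = g$p_by, p_administer = min(1, g$p_adm + 0.05),
                       p_ems = g$p_ems)
      expect_lte(analytic_death_probability(up, avail), p0)
      # non-decreasing in fatality probability
      up <- thn_config(p_bystander = g$p_by, p_administer = g$p_adm,
                       p_ems = g$p_ems, f_fatal = 0.13)
      expect_gte(analytic_death_probability(up, avail), p0)
    }
  }
})
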