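# Synthetic run objects with controlled tallies for metric arithmetic.
fake_run <- function(deaths, kits = 0, deaths_rel = deaths / 10, seed = 1L,
                     scale = 1, kit_cost = 76) {
  structure(list(seed = seed, scale = scale, deaths_total = deaths,
                 deaths_released = deaths_rel, kits_total = kits,
                 cfg = thn_config(kit_cost = kit_cost)),
            class = "thn_run")
}

test_that("deaths averted percentage follows its definition", {
  base <- fake_run(2000)
  run <- fake_run(1766, kits = 5000)
  expect_equal(deaths_averted_pct(run, base), 11.7)
  expect_equal(deaths_averted_pct(base, base), 0)
  expect_true(is.na(deaths_averted_pct(run, fake_run(0))))
  expect_error(deaths_averted_pct(run, fake_run(2000, seed = 2L)),
               "provenance")
  # released-person restriction uses the released tallies
  expect_equal(deaths_averted_pct(fake_run(1900, deaths_rel = 150), base,
                                  "released"), 25)
})

test_that("NNT and cost per death averted compose as kit_cost x NNT", {
  base <- fake_run(2000)
  run <- fake_run(2000 - 8.02, kits = 958)
  expect_equal(nnt(run, base), 958 / 8.02)
  expect_equal(cost_per_death_averted(run, base), 76 * 958 / 8.02)
  expect_equal(cost_per_death_averted(run, base, kit_cost = 152),
               2 * cost_per_death_averted(run, base))
  # no deaths averted: undefined
  expect_true(is.na(nnt(base, base)))
  expect_true(is.na(nnt(fake_run(2100, kits = 10), base)))
  # zero kits with positive effect: NNT 0
  expect_equal(nnt(fake_run(1990, kits = 0), base), 0)
})

# A hand-built sweep table: 4 draws, baseline + two scenarios, scale 0.5.
fake_sweep <- function() {
  rows <- expand.grid(draw = 1:4, scenario = c(1, 2, 19))
  g <- scenario_grid()
  rows <- merge(rows, g, by = "scenario")
  rows$deaths_total <- ifelse(rows$scenario == 1, 100,
                       ifelse(rows$scenario == 2, 99, 95)) + rows$draw
  rows$deaths_released <- ifelse(rows$scenario == 1, 10,
                          ifelse(rows$scenario == 2, 9.5, 7)) + rows$draw / 10
  rows$kits_total <- ifelse(rows$scenario == 1, 0,
                     ifelse(rows$scenario == 2, 50, 300)) * (1 + rows$draw / 100)
  rows$overdoses_total <- rows$deaths_total * 10
  rows$overdoses_released <- rows$deaths_released * 10
  rows
}

test_that("per-draw metrics join baselines by draw and rescale kit counts", {
  sw <- fake_sweep()
  cfg <- thn_config(scale = 0.5)
  pm <- per_draw_metrics(sw, cfg)
  expect_equal(nrow(pm), nrow(sw))
  s2 <- pm[pm$scenario == 2 & pm$draw == 1, ]
  expect_equal(s2$pct_averted, 100 * 1 / 101)       # baseline 101, run 100
  expect_equal(s2$kits_total, 50 * 1.01 / 0.5)      # per unscaled population
  expect_equal(s2$nnt, 50 * 1.01 / 1)               # both at run scale
  expect_equal(s2$cost_per_death_averted, 76 * s2$nnt)
  expect_equal(pm$pct_averted[pm$scenario == 1], rep(0, 4))
  expect_true(all(is.na(pm$nnt[pm$scenario == 1])))
})

test_that("scenario summaries take type-7 medians and IQRs over draws", {
  sw <- fake_sweep()
  cfg <- thn_config(scale = 0.5)
  pm <- per_draw_metrics(sw, cfg)
  # force a known set of values for one metric
  pm$pct_averted[pm$scenario == 19] <- 1:4
  s <- summarize_scenarios(pm, cfg)
  expect_equal(nrow(s), 3)
  r19 <- s[s$scenario == 19, ]
  expect_equal(r19$pct_averted_med, 2.5)
  expect_equal(r19$pct_averted_q1, 1.75)
  expect_equal(r19$pct_averted_q3, 3.25)
  expect_true(all(c(r19$pct_averted_q1 <= r19$pct_averted_med,
                    r19$pct_averted_med <= r19$pct_averted_q3)))
  base_row <- s[s$scenario == 1, ]
  expect_equal(base_row$pct_averted_med, 0)
  expect_true(is.na(base_row$cost_per_death_averted_med))
  expect_equal(base_row$cost_per_death_averted_missing, 4L)
})

test_that("the per-draw cost identity cost = kit_cost x NNT is exact", {
  cfg <- thn_config(scale = 0.5)
  pm <- per_draw_metrics(fake_sweep(), cfg)
  ok <- !is.na(pm$nnt)
  expect_equal(pm$cost_per_death_averted[ok], 76 * pm$nnt[ok])
})

test_that("report formatting matches the published table conventions", {
  s <- data.frame(scenario = 2, cov_community = 0, cov_jail = 0,
                  cov_network = 0.15,
                  kits_total_med = 958.3, kits_total_q1 = 710.4,
                  kits_total_q3 = 1188.2,
                  pct_averted_med = 0.342, pct_averted_q1 = 0.2, pct_averted_q3 = 0.56,
                  cost_per_death_averted_med = 9078,
                  cost_per_death_averted_q1 = 5910,
                  cost_per_death_averted_q3 = 14651,
                  nnt_med = 119.44, nnt_q1 = 77.81, nnt_q3 = 192.96)
  rep <- scenario_report(s)
  expect_equal(rep$kits_distributed, "958 (710-1 188)")
  expect_equal(rep$pct_deaths_averted, "0.34 (0.20-0.56)")
  expect_equal(rep$cost_per_death_averted, "9 100 (5 900-14 700)")
  expect_equal(rep$nnt, "119.4 (77.8-193.0)")
  expect_equal(rep$network_pct, 15)
})
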