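# Small-scale configuration factories shared across the suite.

# one-hundredth-size city, short horizon: fast structural checks
tiny_cfg <- function(...) {
  thn_config(scale = 0.01, horizon = 60, warmup = 20, replicates = 2, ...)
}

# homogeneous opioid-user population with no jail stream: closed-form
# expectations stay simple (reference category everywhere, RR = 1)
flat_cfg <- function(n = 5000, p0 = 3e-4, horizon = 300, ...) {
  thn_config(n_iou = 0, n_niou = n, n_cli = 0, census_target = 0,
             frac_inmates_iou = 0, frac_inmates_niou = 0,
             sex_female_frac = 0, age_dist = c(1, 0, 0),
             p0_daily_od = p0, horizon = horizon, warmup = 0,
             scale = 1, ...)
}
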