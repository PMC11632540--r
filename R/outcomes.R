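# Outcome metrics: deaths averted, cost per death averted, NNT, and
# median/IQR summaries over parameter draws.

.check_provenance <- function(run, baseline) {
  if (!identical(run$scale, baseline$scale) ||
      !identical(run$seed, baseline$seed))
    stop("run and baseline do not share provenance ",
         "(they must come from the same seed(s) and population scale)",
         call. = FALSE)
}

#' Percent of overdose deaths averted versus baseline
#'
#' `100 * (baseline deaths - scenario deaths) / baseline deaths`, either for
#' the whole opioid-using population or restricted to persons with at least
#' one jail release during the horizon.  Undefined (NA) when the baseline
#' records no deaths.
#'
#' @param run,baseline `thn_run` (or replicate-averaged) results sharing
#'   seed(s) and scale.
#' @param population `"all"` or `"released"`.
#' @return percentage (possibly `NA`).
#' @export
deaths_averted_pct <- function(run, baseline,
                               population = c("all", "released")) {
  population <- match.arg(population)
  .check_provenance(run, baseline)
  f <- if (population == "all") "deaths_total" else "deaths_released"
  b <- baseline[[f]]
  if (!is.finite(b) || b <= 0) return(NA_real_)
  100 * (b - run[[f]]) / b
}

#' Number needed to treat
#'
#' THN kits distributed (including replacements) divided by the number of
#' overdose deaths averted versus baseline.  Missing when no deaths are
#' averted.
#'
#' @inheritParams deaths_averted_pct
#' @return kits per death averted (possibly `NA`).
#' @export
nnt <- function(run, baseline) {
  .check_provenance(run, baseline)
  averted <- baseline$deaths_total - run$deaths_total
  if (!is.finite(averted) || averted <= 0) return(NA_real_)
  run$kits_total / averted
}

#' Direct program cost per death averted
#'
#' Kit cost times kits distributed, divided by deaths averted versus
#' baseline; identical to the incremental cost-effectiveness ratio against
#' the zero-cost baseline, and equal to `kit_cost * nnt()` by construction.
#'
#' @inheritParams deaths_averted_pct
#' @param kit_cost cost per kit (defaults to the run's configuration).
#' @return cost per death averted (possibly `NA`).
#' @export
cost_per_death_averted <- function(run, baseline,
                                   kit_cost = run$cfg$kit_cost) {
  kit_cost * nnt(run, baseline)
}

#' Per-draw outcome metrics from a sweep
#'
#' Joins every sweep row to its same-draw baseline (common random numbers)
#' and computes, per (draw, scenario): kits distributed re-expressed per
#' unscaled population, percent deaths averted (overall and among released
#' persons), deaths averted (per unscaled population), NNT and cost per
#' death averted.  Metrics that require positive baseline deaths or positive
#' averted deaths are `NA` where undefined.
#'
#' @param sweep a `thn_sweep` from [run_sweep()].
#' @param cfg configuration (defaults to the sweep's).
#' @return a data.frame, one row per (draw, scenario).
#' @export
per_draw_metrics <- function(sweep, cfg = attr(sweep, "cfg")) {
  stopifnot(is.data.frame(sweep))
  scale <- cfg$scale
  base <- sweep[sweep$cov_community == 0 & sweep$cov_jail == 0 &
                  sweep$cov_network == 0, ]
  if (!nrow(base)) stop("sweep contains no baseline scenario rows", call. = FALSE)
  bi <- match(sweep$draw, base$draw)
  if (anyNA(bi)) stop("missing baseline rows for some draws", call. = FALSE)
  b_deaths <- base$deaths_total[bi]
  b_deaths_rel <- base$deaths_released[bi]
  averted <- b_deaths - sweep$deaths_total
  averted_rel <- b_deaths_rel - sweep$deaths_released
  out <- data.frame(
    draw = sweep$draw, scenario = sweep$scenario,
    cov_community = sweep$cov_community, cov_jail = sweep$cov_jail,
    cov_network = sweep$cov_network,
    kits_total = sweep$kits_total / scale,
    deaths_total = sweep$deaths_total / scale,
    deaths_averted = averted / scale,
    deaths_averted_released = averted_rel / scale,
    pct_averted = ifelse(b_deaths > 0, 100 * averted / b_deaths, NA_real_),
    pct_averted_released = ifelse(b_deaths_rel > 0,
                                  100 * averted_rel / b_deaths_rel, NA_real_),
    nnt = ifelse(averted > 0, sweep$kits_total / averted, NA_real_))
  out$cost_per_death_averted <- cfg$kit_cost * out$nnt
  out
}

#' Median/IQR outcome summary per scenario
#'
#' Summarises the per-draw metrics of a sweep as the median and interquartile
#' range (25th/75th percentile, linear interpolation) across parameter draws,
#' per scenario.  Missing per-draw values (e.g. cost when no deaths were
#' averted) are excluded, with the exclusion count reported.  The baseline
#' scenario row shows 0% averted and missing cost/NNT.
#'
#' @param sweep a `thn_sweep`, or a per-draw metrics table from
#'   [per_draw_metrics()].
#' @param cfg configuration (defaults to the sweep's).
#' @return a data.frame of class `thn_outcomes`, one row per scenario, with
#'   `<metric>_med`, `<metric>_q1`, `<metric>_q3` columns.
#' @export
summarize_scenarios <- function(sweep, cfg = attr(sweep, "cfg")) {
  pm <- if ("pct_averted" %in% names(sweep)) sweep
        else per_draw_metrics(sweep, cfg)
  metrics <- c("kits_total", "pct_averted", "pct_averted_released",
               "deaths_averted", "cost_per_death_averted", "nnt")
  scen <- unique(pm[, c("scenario", "cov_community", "cov_jail",
                        "cov_network")])
  scen <- scen[order(scen$scenario), , drop = FALSE]
  qs <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE,
                                    names = FALSE, type = 7)
  rows <- lapply(seq_len(nrow(scen)), function(i) {
    sub <- pm[pm$scenario == scen$scenario[i], , drop = FALSE]
    row <- scen[i, , drop = FALSE]
    row$n_draws <- nrow(sub)
    for (m in metrics) {
      x <- sub[[m]]
      n_ok <- sum(is.finite(x))
      v <- if (n_ok) qs(x) else c(NA_real_, NA_real_, NA_real_)
      row[[paste0(m, "_med")]] <- v[1L]
      row[[paste0(m, "_q1")]] <- v[2L]
      row[[paste0(m, "_q3")]] <- v[3L]
      row[[paste0(m, "_missing")]] <- nrow(sub) - n_ok
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("thn_outcomes", "data.frame")
  out
}

.round100 <- function(x) 100 * round(x / 100)

#' Formatted scenario report
#'
#' Formats an outcome summary in the conventional layout for THN scenario
#' tables: coverage percentages, kits as integers, percent averted to two
#' decimals, costs rounded to the nearest $100, NNT to one decimal, each as
#' `median (q1-q3)`.
#'
#' @param summaries a `thn_outcomes` table from [summarize_scenarios()].
#' @param path optional CSV output path.
#' @return a data.frame of formatted strings (invisibly written to `path` if
#'   given).
#' @export
scenario_report <- function(summaries, path = NULL) {
  fmt3 <- function(med, q1, q3, f) {
    ifelse(is.na(med), "NA",
           sprintf("%s (%s-%s)", f(med), f(q1), f(q3)))
  }
  f_int <- function(x) formatC(round(x), format = "d", big.mark = " ")
  f_pct <- function(x) sprintf("%.2f", x)
  f_cost <- function(x) formatC(.round100(x), format = "d", big.mark = " ")
  f_nnt <- function(x) sprintf("%.1f", x)
  g <- function(m) summaries[[paste0(m, "_med")]]
  q1 <- function(m) summaries[[paste0(m, "_q1")]]
  q3 <- function(m) summaries[[paste0(m, "_q3")]]
  out <- data.frame(
    scenario = summaries$scenario,
    community_pct = 100 * summaries$cov_community,
    jail_pct = 100 * summaries$cov_jail,
    network_pct = 100 * summaries$cov_network,
    kits_distributed = fmt3(g("kits_total"), q1("kits_total"),
                            q3("kits_total"), f_int),
    pct_deaths_averted = fmt3(g("pct_averted"), q1("pct_averted"),
                              q3("pct_averted"), f_pct),
    cost_per_death_averted = fmt3(g("cost_per_death_averted"),
                                  q1("cost_per_death_averted"),
                                  q3("cost_per_death_averted"), f_cost),
    nnt = fmt3(g("nnt"), q1("nnt"), q3("nnt"), f_nnt))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
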