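# Orchestration: single runs, replicate averaging, and the scenario x
# parameter-draw sweep with common random numbers.

#' Derive a cell seed from a base seed
#'
#' Deterministic mixing hash (two rounds of a Knuth-style multiplicative
#' congruential update modulo 2^31 - 1) of `(base_seed, draw, replicate)`.
#' Used everywhere a sweep cell needs its own seed, so results are
#' reproducible across platforms and independent of loop order.  Scenarios
#' intentionally do not enter the hash: runs of different scenarios in the
#' same (draw, replicate) cell share a seed (common random numbers).
#'
#' @param base_seed,draw,replicate non-negative integers.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(base_seed, draw = 0L, replicate = 1L) {
  m <- 2147483647
  h <- as.numeric(base_seed) %% m
  h <- (h * 69069 + as.numeric(draw) * 40503 + 12345) %% m
  h <- (h * 69069 + as.numeric(replicate) * 40503 + 12345) %% m
  as.integer(h)
}

# Demographic relative-risk product per person (release window excluded;
# that part is time-varying and applied by the engines each day).
.rr_demographic <- function(pop, cfg) {
  age_mult <- c(1, cfg$rr_age_25_29, cfg$rr_age_30plus)[pop$age_group]
  rr <- ifelse(pop$female, cfg$rr_female, 1) *
    ifelse(pop$use_type == USE_IOU, cfg$rr_iou, 1) * age_mult
  rr[pop$use_type == USE_NONE] <- 0
  rr
}

#' Run one simulation
#'
#' Executes the full protocol for one scenario and seed: build the synthetic
#' population, seed the jail at its steady-state census, run `warmup` days of
#' jail dynamics and overdoses with tallies discarded and no THN, distribute
#' community kits, then run `horizon` days.  Each day is processed in a fixed
#' order: bookings, releases, jail/network distribution, overdose draws,
#' event resolution, ledger update, tallies, post-release clocks.
#'
#' The default engine is the compiled daily loop; `engine = "r"` runs the
#' identical protocol composed from the exported R operations (slower, used
#' for cross-validation).  Both engines draw every within-loop decision from
#' the same counter-based keyed source ([thn_rng()]), so a given seed yields
#' bit-identical results from either engine, and runs of different scenarios
#' under one seed are coupled decision-by-decision (common random numbers).
#'
#' @param cfg a [thn_config()] bundle.
#' @param scenario scenario id, coverage triple, or grid row (see
#'   [as_scenario()]).
#' @param seed integer seed; identical inputs give identical results.
#' @param engine `"cpp"` (compiled) or `"r"`.
#' @param log_events keep a per-event log (day, person, bystander tree
#'   outcome) for the horizon; memory-heavy at full scale.
#' @return an object of class `thn_run`: horizon tallies
#'   (`overdoses_total`, `deaths_total`, and the same restricted to persons
#'   with at least one release during the horizon), the kit `ledger` and
#'   `kits_total` (including replacements), `census_mean`, a `daily`
#'   data.frame (day, bookings, releases, census), and optionally `events`.
#' @export
run_simulation <- function(cfg, scenario = c(0, 0, 0), seed = 1L,
                           engine = c("cpp", "r"), log_events = FALSE) {
  engine <- match.arg(engine)
  validate_config(cfg)
  scenario <- as_scenario(scenario)
  pop <- build_population(cfg, seed = seed)   # seeds the RNG stream
  init <- initialize_steady_state(pop, cfg)
  pop <- init$pop
  res <- if (engine == "cpp") .run_engine_cpp(pop, cfg, scenario, seed, log_events)
         else .run_engine_r(pop, cfg, scenario, seed, log_events)
  days <- seq.int(-cfg$warmup, cfg$horizon - 1L)
  ledger <- structure(res$ledger, class = "thn_ledger")
  out <- list(
    scenario = scenario,
    seed = as.integer(seed),
    engine = engine,
    scale = cfg$scale,
    overdoses_total = res$overdoses_total,
    deaths_total = res$deaths_total,
    overdoses_released = res$overdoses_released,
    deaths_released = res$deaths_released,
    ledger = ledger,
    kits_total = total_kits(ledger),
    census0 = res$census0,
    census_mean = mean(res$census[days >= 0]),
    pool_shortfalls = res$pool_shortfalls,
    daily = data.frame(day = days, bookings = res$bookings,
                       releases = res$releases, census = res$census),
    cfg = cfg
  )
  if (log_events) out$events <- res$events
  structure(out, class = "thn_run")
}

.run_engine_cpp <- function(pop, cfg, scenario, seed, log_events) {
  d <- stay_distribution(cfg)
  eff <- effective_sizes(cfg)
  pars <- list(p0_daily_od = cfg$p0_daily_od, f_fatal = cfg$f_fatal,
               rr_release_wk0_2 = cfg$rr_release_wk0_2,
               rr_release_wk3_4 = cfg$rr_release_wk3_4,
               rr_release_wk5plus = cfg$rr_release_wk5plus,
               p_bystander = cfg$p_bystander, p_administer = cfg$p_administer,
               p_ems = cfg$p_ems, eff_naloxone = cfg$eff_naloxone,
               eff_ems = cfg$eff_ems, booking_rate = eff$booking_rate,
               meanlog = d$meanlog, sdlog = d$sdlog)
  .sim_core(pop$use_type, pop$cli, pop$in_jail, pop$release_day,
            pop$days_since_release, pop$has_kit, pop$peer_kit, pop$alive,
            .rr_demographic(pop, cfg), pars, unname(scenario),
            cfg$warmup, cfg$horizon, as.numeric(as.integer(seed)), log_events)
}

.run_engine_r <- function(pop, cfg, scenario, seed, log_events) {
  n <- length(pop$pid)
  rng <- thn_rng(seed)
  state <- new_jail_state()
  ledger <- new_ledger()
  ndays <- cfg$warmup + cfg$horizon
  census <- integer(ndays); bookings <- integer(ndays); releases <- integer(ndays)
  od_count <- integer(n); died_h <- logical(n); released_flag <- logical(n)
  ov_total <- 0; deaths_total <- 0
  census0 <- sum(pop$in_jail)
  ev_log <- if (log_events) vector("list", ndays) else NULL

  for (day in seq.int(-cfg$warmup, cfg$horizon - 1L)) {
    idx <- day + cfg$warmup + 1L
    if (day == 0L) {
      cd <- apply_community_distribution(pop, scenario, ledger, rng, day)
      pop <- cd$pop; ledger <- cd$ledger
    }
    bk <- step_bookings(pop, state, day, cfg, rng)
    pop <- bk$pop; state <- bk$state
    rl <- step_releases(pop, state, day)
    pop <- rl$pop; rel <- rl$released
    if (day >= 0L && length(rel)) {
      released_flag[rel] <- TRUE
      jd <- apply_jail_release_distribution(pop, rel, scenario, ledger, rng, day)
      pop <- jd$pop; ledger <- jd$ledger
      nd <- apply_network_distribution(pop, rel, scenario, ledger, rng, day)
      pop <- nd$pop; ledger <- nd$ledger
    }
    evs <- draw_overdoses(pop, cfg, rng, day)
    if (length(evs)) {
      avail <- availability_and_use(pop, evs)$availability
      tree <- resolve_overdose(cfg, avail, rng, evs, day)
      ledger <- availability_and_use(pop, evs, tree$naloxone_administered,
                                     ledger)$ledger
      fatal_ids <- evs[tree$fatal]
      pop$alive[fatal_ids] <- FALSE
      if (day >= 0L) {
        ov_total <- ov_total + length(evs)
        od_count[evs] <- od_count[evs] + 1L
        deaths_total <- deaths_total + sum(tree$fatal)
        died_h[fatal_ids] <- TRUE
        if (log_events)
          ev_log[[idx]] <- data.frame(day = day, pid = evs,
                                      bystander_present = tree$bystander_present,
                                      naloxone_available = avail,
                                      naloxone_administered = tree$naloxone_administered,
                                      ems_called = tree$ems_called,
                                      fatal = tree$fatal,
                                      victim_released_ever = released_flag[evs])
      }
    }
    adv <- pop$alive & !pop$in_jail & !is.na(pop$days_since_release)
    pop$days_since_release[adv] <- pop$days_since_release[adv] + 1L
    census[idx] <- sum(pop$in_jail)
    bookings[idx] <- length(bk$booked)
    releases[idx] <- length(rel)
  }
  out <- list(overdoses_total = ov_total, deaths_total = deaths_total,
              overdoses_released = sum(od_count[released_flag]),
              deaths_released = sum(died_h & released_flag),
              ledger = unclass(ledger), census = census, bookings = bookings,
              releases = releases, census0 = census0,
              pool_shortfalls = state$pool_shortfalls)
  if (log_events)
    out$events <- do.call(rbind, ev_log[!vapply(ev_log, is.null, logical(1))])
  out
}

#' @export
print.thn_run <- function(x, ...) {
  cat("<thn_run> scenario (community ", x$scenario[["cov_community"]],
      ", jail ", x$scenario[["cov_jail"]], ", network ",
      x$scenario[["cov_network"]], "), seed ", x$seed,
      ", scale ", x$scale, "\n", sep = "")
  cat(sprintf("  overdoses %s (released persons %s), deaths %s (released %s)\n",
              format(x$overdoses_total), format(x$overdoses_released),
              format(x$deaths_total), format(x$deaths_released)))
  cat(sprintf("  kits: community %s, jail %s, network %s, replacements %s (total %s); mean census %.0f\n",
              format(x$ledger[["community"]]), format(x$ledger[["jail"]]),
              format(x$ledger[["network"]]), format(x$ledger[["replacements"]]),
              format(x$kits_total), x$census_mean))
  invisible(x)
}

#' @export
summary.thn_run <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Average a scenario over stochastic replicates
#'
#' Runs `n` independent replicates with seeds derived deterministically from
#' `base_seed` via [derive_seed()] and returns the arithmetic mean of all
#' count fields, alongside the individual runs.
#'
#' @inheritParams run_simulation
#' @param n number of replicates (default `cfg$replicates`).
#' @param base_seed base seed for [derive_seed()].
#' @param draw draw index entering the seed derivation (0 for stand-alone
#'   use; [run_sweep()] passes the parameter-draw id).
#' @return an object of classes `thn_replicates`/`thn_run`: the averaged
#'   tallies at top level plus `runs` (the per-replicate `thn_run` list).
#' @export
run_replicates <- function(cfg, scenario = c(0, 0, 0), n = cfg$replicates,
                           base_seed = 1L, engine = c("cpp", "r"), draw = 0L) {
  stopifnot(n >= 1)
  engine <- match.arg(engine)
  scenario <- as_scenario(scenario)
  seeds <- vapply(seq_len(n), function(r) derive_seed(base_seed, draw, r),
                  integer(1))
  runs <- lapply(seeds, function(s) run_simulation(cfg, scenario, s, engine))
  avg <- function(f) mean(vapply(runs, `[[`, numeric(1), f))
  ledger <- structure(rowMeans(vapply(runs, function(r) unclass(r$ledger),
                                      numeric(5))), class = "thn_ledger")
  structure(list(
    scenario = scenario, seed = seeds, engine = engine, scale = cfg$scale,
    overdoses_total = avg("overdoses_total"),
    deaths_total = avg("deaths_total"),
    overdoses_released = avg("overdoses_released"),
    deaths_released = avg("deaths_released"),
    ledger = ledger, kits_total = total_kits(ledger),
    census_mean = avg("census_mean"),
    n = as.integer(n), runs = runs, cfg = cfg
  ), class = c("thn_replicates", "thn_run"))
}

#' Scenario x parameter-draw sweep with common random numbers
#'
#' For every parameter draw, runs the baseline scenario and every requested
#' scenario, averaging `replicates` stochastic runs per cell.  Within a
#' (draw, replicate) cell all scenarios share a derived seed, so
#' deaths-averted comparisons against baseline use common random numbers;
#' the baseline compared against itself averts exactly zero deaths.
#'
#' @param cfg a [thn_config()] bundle.
#' @param draws data.frame of parameter draws from
#'   [sample_parameter_draws()], or `NULL` for a single default-parameter
#'   "draw".
#' @param scenarios rows of [scenario_grid()] (or a vector of scenario ids).
#'   The baseline (scenario 1) is always included.
#' @param replicates stochastic replicates per cell.
#' @param base_seed base seed for [derive_seed()].
#' @param engine `"cpp"` or `"r"`.
#' @param verbose print progress per draw.
#' @return a data.frame of class `thn_sweep`, one row per (draw, scenario):
#'   coverages and replicate-averaged tallies.  The configuration and seed
#'   are kept as attributes.
#' @export
run_sweep <- function(cfg, draws = NULL, scenarios = scenario_grid(),
                      replicates = 3L, base_seed = 1L,
                      engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  if (is.numeric(scenarios) && is.null(dim(scenarios))) {
    g <- scenario_grid()
    scenarios <- g[g$scenario %in% scenarios, , drop = FALSE]
  }
  stopifnot(is.data.frame(scenarios),
            all(c("scenario", "cov_community", "cov_jail", "cov_network") %in%
                  names(scenarios)))
  if (!any(scenarios$cov_community == 0 & scenarios$cov_jail == 0 &
             scenarios$cov_network == 0))
    scenarios <- rbind(scenario_grid()[1L, ], scenarios)
  if (is.null(draws)) draws <- data.frame(draw = 1L)

  rows <- vector("list", nrow(draws) * nrow(scenarios))
  k <- 0L
  for (di in seq_len(nrow(draws))) {
    drow <- draws[di, , drop = FALSE]
    draw_id <- if ("draw" %in% names(drow)) as.integer(drow$draw) else di
    cfg_d <- apply_draw(cfg, drow)
    for (si in seq_len(nrow(scenarios))) {
      srow <- scenarios[si, , drop = FALSE]
      rep_run <- run_replicates(cfg_d, srow, n = replicates,
                                base_seed = base_seed, engine = engine,
                                draw = draw_id)
      k <- k + 1L
      rows[[k]] <- data.frame(
        draw = draw_id, scenario = srow$scenario,
        cov_community = srow$cov_community, cov_jail = srow$cov_jail,
        cov_network = srow$cov_network,
        overdoses_total = rep_run$overdoses_total,
        deaths_total = rep_run$deaths_total,
        overdoses_released = rep_run$overdoses_released,
        deaths_released = rep_run$deaths_released,
        kits_community = rep_run$ledger[["community"]],
        kits_jail = rep_run$ledger[["jail"]],
        kits_network = rep_run$ledger[["network"]],
        kits_replacements = rep_run$ledger[["replacements"]],
        kits_used = rep_run$ledger[["used"]],
        kits_total = rep_run$kits_total,
        census_mean = rep_run$census_mean)
    }
    if (verbose)
      message("draw ", draw_id, "/", nrow(draws), " done (",
              nrow(scenarios), " scenarios x ", replicates, " replicates)")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cfg") <- cfg
  attr(out, "base_seed") <- base_seed
  attr(out, "replicates") <- as.integer(replicates)
  class(out) <- c("thn_sweep", "data.frame")
  out
}

#' @export
print.thn_sweep <- function(x, ...) {
  cat("<thn_sweep> ", length(unique(x$draw)), " draw(s) x ",
      length(unique(x$scenario)), " scenario(s), ",
      attr(x, "replicates"), " replicate(s) per cell\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n")
  invisible(x)
}

#' @export
summary.thn_sweep <- function(object, ...) summarize_scenarios(object)

#' Export run tables to CSV
#'
#' Writes `daily.csv` (day, bookings, releases, census), `ledger.csv`, and,
#' if the run logged events, `events.csv` into `dir`.
#'
#' @param run a `thn_run`.
#' @param dir output directory (created if needed).
#' @export
write_run_csv <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$daily, file.path(dir, "daily.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(t(unclass(run$ledger))),
                   file.path(dir, "ledger.csv"), row.names = FALSE)
  if (!is.null(run$events))
    utils::write.csv(run$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
  invisible(dir)
}
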