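# Jail circulation: daily bookings, length-of-stay, releases, steady-state
# seeding of the census.

#' Log-normal stay distribution fitted to the published mean/median
#'
#' The in-custody length of stay is log-normal with log-scale location
#' `mu = log(stay_median)` and shape `sigma` solving
#' `exp(mu + sigma^2/2) = stay_mean`, i.e.
#' `sigma = sqrt(2 * log(stay_mean / stay_median))` -- the minimal
#' two-parameter family matching both printed statistics with a heavy right
#' tail.
#'
#' @param cfg a [thn_config()] bundle.
#' @return list with `meanlog` and `sdlog`.
#' @export
#' @examples
#' stay_distribution(thn_config())  # median 12 d, mean 54.1 d
stay_distribution <- function(cfg) {
  if (cfg$stay_mean < cfg$stay_median)
    stop("no log-normal stay distribution exists with mean < median",
         call. = FALSE)
  list(meanlog = log(cfg$stay_median),
       sdlog = sqrt(2 * log(cfg$stay_mean / cfg$stay_median)))
}

#' Sample jail stay durations
#'
#' Draws from the fitted log-normal stay distribution, rounded up to whole
#' days (minimum 1 day).
#'
#' @param cfg a [thn_config()] bundle.
#' @param n number of draws.
#' @return integer vector of stay lengths in days.
#' @export
sample_stay_duration <- function(cfg, n = 1L) {
  d <- stay_distribution(cfg)
  pmax(1L, as.integer(ceiling(stats::rlnorm(n, d$meanlog, d$sdlog))))
}

#' Create an empty jail state
#'
#' Custody membership and scheduled release days live on the population
#' object (`in_jail`, `release_day`); the jail state tracks the daily census
#' and event counts.
#'
#' @return an object of class `thn_jail_state` with integer vectors `census`,
#'   `bookings`, `releases` (one entry per processed day) and a
#'   `pool_shortfalls` counter.
#' @export
new_jail_state <- function() {
  structure(list(census = integer(), bookings = integer(),
                 releases = integer(), pool_shortfalls = 0L),
            class = "thn_jail_state")
}

#' Seed the jail at its steady-state census
#'
#' Fills custody with `census_target` (scaled) CLI persons before the warm-up
#' starts.  Total stays for the seeded inmates are drawn length-biased from
#' the stay distribution (for a log-normal, the length-biased law is
#' log-normal with location `meanlog + sdlog^2`), and the residual stay is a
#' uniform fraction of the total, so the census is near steady state from
#' day one rather than filling from empty over a warm-up that is short
#' relative to the mean stay.
#'
#' @param pop a `thn_population` (no one in custody).
#' @param cfg a [thn_config()] bundle.
#' @param start_day day index at which the warm-up begins (e.g. `-warmup`).
#' @return list with the updated `pop` and a count `seeded`.
#' @export
initialize_steady_state <- function(pop, cfg, start_day = -cfg$warmup) {
  d <- stay_distribution(cfg)
  eff <- effective_sizes(cfg)
  eligible <- which(pop$cli & pop$alive & !pop$in_jail)
  n_seed <- min(eff$census_target, length(eligible))
  if (n_seed < eff$census_target)
    warning("CLI pool smaller than census_target; seeding ", n_seed, " inmates")
  ids <- if (n_seed == length(eligible)) eligible
         else eligible[sample.int(length(eligible), n_seed)]
  total <- stats::rlnorm(n_seed, d$meanlog + d$sdlog^2, d$sdlog)
  residual <- pmax(1L, as.integer(ceiling(stats::runif(n_seed) * total)))
  pop$in_jail[ids] <- TRUE
  pop$release_day[ids] <- as.integer(start_day) + residual - 1L
  pop$days_since_release[ids] <- NA_integer_
  list(pop = pop, seeded = n_seed)
}

#' One day of jail bookings
#'
#' Draws `K ~ Poisson(booking_rate)` (scaled) and books K persons sampled
#' uniformly without replacement from CLI persons who are alive and not in
#' custody.  Each booked person receives a sampled stay and scheduled release
#' day; `days_since_release` resets to absent while in custody; kit
#' possession is unchanged.  If the eligible pool is smaller than K the whole
#' pool is booked and a shortfall is recorded on the state.
#'
#' With a keyed `rng` (see [thn_rng()]) the Poisson count comes from the
#' inverse CDF of a day-keyed uniform and the without-replacement selection
#' uses keyed rejection sampling (the attempt index keys each candidate
#' draw), so booking decisions are coupled across scenarios sharing a seed.
#' With `rng = NULL` the draws come from R's global stream.
#'
#' @param pop a `thn_population`.
#' @param state a `thn_jail_state`.
#' @param day integer day index.
#' @param cfg a [thn_config()] bundle.
#' @param rng a [thn_rng()] keyed source, or `NULL` for the global stream.
#' @return list with updated `pop`, `state`, and integer vector `booked` of
#'   person ids booked today.
#' @export
step_bookings <- function(pop, state, day, cfg, rng = NULL) {
  eff <- effective_sizes(cfg)
  d <- stay_distribution(cfg)
  cli_ids <- which(pop$cli)
  if (eff$booking_rate <= 0 || !length(cli_ids))
    return(list(pop = pop, state = state, booked = integer(0)))
  keyed <- !is.null(rng)
  k_target <- if (keyed)
    stats::qpois(keyed_uniform(rng, 0L, day, 1L), eff$booking_rate)
  else stats::rpois(1L, eff$booking_rate)
  eligible_mask <- pop$cli & pop$alive & !pop$in_jail
  n_free <- sum(eligible_mask)
  draw_stay <- function(pid) {
    s <- if (keyed) stats::qlnorm(keyed_uniform(rng, pid, day, 3L),
                                  d$meanlog, d$sdlog)
         else stats::rlnorm(1L, d$meanlog, d$sdlog)
    max(1L, as.integer(ceiling(s)))
  }
  booked <- integer(0)
  if (k_target >= n_free) {
    if (k_target > n_free) {
      state$pool_shortfalls <- state$pool_shortfalls + 1L
      warning("eligible CLI pool (", n_free, ") smaller than booking draw (",
              k_target, "); booking the whole pool", call. = FALSE)
    }
    booked <- which(eligible_mask)
    for (pid in booked) {
      pop$in_jail[pid] <- TRUE
      pop$release_day[pid] <- as.integer(day) + draw_stay(pid)
      pop$days_since_release[pid] <- NA_integer_
    }
  } else if (k_target > 0L) {
    n_pool <- length(cli_ids)
    j <- 0L
    while (length(booked) < k_target) {
      j <- j + 1L
      u <- if (keyed) keyed_uniform(rng, j, day, 2L) else stats::runif(1L)
      pid <- cli_ids[1L + as.integer(floor(u * n_pool))]
      if (pop$alive[pid] && !pop$in_jail[pid]) {
        pop$in_jail[pid] <- TRUE
        pop$release_day[pid] <- as.integer(day) + draw_stay(pid)
        pop$days_since_release[pid] <- NA_integer_
        booked <- c(booked, pid)
      }
    }
  }
  list(pop = pop, state = state, booked = booked)
}

#' One day of jail releases
#'
#' Persons whose scheduled release day equals `day` leave custody;
#' `days_since_release` is set to 0 (the release day itself falls in the
#' week 0-2 risk window) and increments daily thereafter.
#'
#' @inheritParams step_bookings
#' @return list with updated `pop` and integer vector `released`.
#' @export
step_releases <- function(pop, state, day) {
  released <- which(pop$in_jail & !is.na(pop$release_day) &
                      pop$release_day == day)
  if (length(released)) {
    pop$in_jail[released] <- FALSE
    pop$release_day[released] <- NA_integer_
    pop$days_since_release[released] <- 0L
  }
  list(pop = pop, released = released)
}
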