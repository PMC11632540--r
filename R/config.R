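# Model parameters, uncertainty ranges, scenario grid, and config I/O.

# Canonical parameter table: defaults for point runs and the uncertainty
# ranges swept in sensitivity analyses.  Probabilities are stored as
# fractions everywhere inside the package; the %-to-fraction conversion for
# published figures happens exactly once, here.
.param_table <- function() {
  p <- list(
    # name,               default,  lower,   upper,  swept
    p0_daily_od       = list(3.3e-4, 1.6e-4,  5.0e-4, TRUE),
    f_fatal           = list(0.10,   0.07,    0.13,   TRUE),
    rr_female         = list(0.81,   0.21,    1.41,   TRUE),
    rr_iou            = list(4.75,   0.50,    9.00,   TRUE),
    rr_release_wk0_2  = list(6.00,   2.00,    10.0,   TRUE),
    rr_release_wk3_4  = list(4.00,   2.00,    6.00,   TRUE),
    rr_release_wk5plus= list(1.50,   1.00,    2.00,   TRUE),
    rr_age_25_29      = list(2.085,  0.39,    3.78,   TRUE),
    rr_age_30plus     = list(2.935,  0.72,    5.15,   TRUE),
    p_bystander       = list(0.60,   0.30,    0.90,   TRUE),
    p_administer      = list(0.70,   0.50,    0.90,   TRUE),
    p_ems             = list(0.50,   0.20,    0.80,   TRUE),
    frac_inmates_iou  = list(0.035,  0.02,    0.05,   TRUE),
    frac_inmates_niou = list(0.105,  0.06,    0.15,   TRUE),
    eff_naloxone      = list(0.95,   NA,      NA,     FALSE),
    eff_ems           = list(0.50,   NA,      NA,     FALSE),
    booking_rate      = list(132,    NA,      NA,     FALSE),
    stay_median       = list(12,     NA,      NA,     FALSE),
    stay_mean         = list(54.1,   NA,      NA,     FALSE),
    census_target     = list(6000,   NA,      NA,     FALSE),
    n_iou             = list(24000,  NA,      NA,     FALSE),
    n_niou            = list(66000,  NA,      NA,     FALSE),
    n_cli             = list(50000,  NA,      NA,     FALSE),
    sex_female_frac   = list(0.25,   NA,      NA,     FALSE),
    kit_cost          = list(76,     NA,      NA,     FALSE),
    horizon           = list(365L,   NA,      NA,     FALSE),
    warmup            = list(90L,    NA,      NA,     FALSE),
    replicates        = list(10L,    NA,      NA,     FALSE),
    scale             = list(1.0,    NA,      NA,     FALSE)
  )
  p
}

#' Default model configuration
#'
#' Builds the full parameter bundle for the simulator.  Point defaults for
#' the parameters that are swept in sensitivity analyses are the midpoints of
#' their uncertainty intervals (see [default_ranges()]); structural constants
#' (population sizes, jail throughput, kit cost, horizon) are the published
#' point estimates for the modelled setting.
#'
#' All probabilities and coverages are fractions in \[0, 1\].  `age_dist` is
#' the categorical distribution over the age groups 18-24, 25-29 and >= 30.
#' `scale` jointly scales all population counts, the booking rate and the
#' jail census target (e.g. `scale = 0.1` runs a one-tenth-size city);
#' tallies from a scaled run are re-expressed per unscaled population by the
#' outcome summaries.
#'
#' @param ... named parameter overrides, e.g. `thn_config(p0_daily_od = 2e-4)`.
#' @return A named list of class `thn_config`, validated against all
#'   parameter invariants.
#' @seealso [load_config()], [default_ranges()], [scenario_grid()]
#' @export
#' @examples
#' cfg <- thn_config(scale = 0.01, replicates = 2)
#' cfg$booking_rate
thn_config <- function(...) {
  tab <- .param_table()
  cfg <- lapply(tab, `[[`, 1L)
  cfg$age_dist <- c(0.10, 0.15, 0.75)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(dots)) cfg[[k]] <- dots[[k]]
  }
  cfg <- .coerce_config(cfg)
  validate_config(cfg)
  structure(cfg, class = "thn_config")
}

.coerce_config <- function(cfg) {
  int_keys <- c("horizon", "warmup", "replicates")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  num_keys <- setdiff(names(cfg), c(int_keys, "age_dist"))
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$age_dist <- as.numeric(unlist(cfg$age_dist))
  cfg
}

#' Validate a configuration bundle
#'
#' Checks every parameter invariant: probabilities and fractions in \[0, 1\],
#' relative risks positive, feasible jail stay statistics
#' (`stay_mean >= stay_median > 0`), positive horizon, non-negative warm-up,
#' and a normalised three-category age distribution.  Errors name the
#' offending key.
#'
#' @param cfg a configuration list as returned by [thn_config()].
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok))
      stop("invalid configuration value for '", key, "': ", what, call. = FALSE)
  }
  prob_keys <- c("p0_daily_od", "f_fatal", "p_bystander", "p_administer",
                 "p_ems", "eff_naloxone", "eff_ems", "frac_inmates_iou",
                 "frac_inmates_niou", "sex_female_frac")
  for (k in prob_keys)
    chk(is.numeric(cfg[[k]]) && length(cfg[[k]]) == 1L &&
          is.finite(cfg[[k]]) && cfg[[k]] >= 0 && cfg[[k]] <= 1,
        k, "must be a probability in [0, 1]")
  rr_keys <- c("rr_female", "rr_iou", "rr_release_wk0_2", "rr_release_wk3_4",
               "rr_release_wk5plus", "rr_age_25_29", "rr_age_30plus")
  for (k in rr_keys)
    chk(is.numeric(cfg[[k]]) && is.finite(cfg[[k]]) && cfg[[k]] > 0,
        k, "relative risks must be > 0")
  count_keys <- c("n_iou", "n_niou", "n_cli", "census_target")
  for (k in count_keys)
    chk(is.finite(cfg[[k]]) && cfg[[k]] >= 0, k, "must be a non-negative count")
  chk(cfg$booking_rate >= 0, "booking_rate", "must be >= 0")
  chk(cfg$stay_median > 0, "stay_median", "must be > 0")
  chk(cfg$stay_mean >= cfg$stay_median, "stay_mean",
      "must be >= stay_median (log-normal stay fit is otherwise infeasible)")
  chk(cfg$frac_inmates_iou + cfg$frac_inmates_niou < 1,
      "frac_inmates_niou", "inmate opioid-use fractions must sum to < 1")
  chk(cfg$kit_cost >= 0, "kit_cost", "must be >= 0")
  chk(cfg$horizon > 0L, "horizon", "must be > 0")
  chk(cfg$warmup >= 0L, "warmup", "must be >= 0")
  chk(cfg$replicates >= 1L, "replicates", "must be >= 1")
  chk(cfg$scale > 0, "scale", "must be > 0")
  chk(length(cfg$age_dist) == 3L && all(cfg$age_dist >= 0) &&
        abs(sum(cfg$age_dist) - 1) < 1e-8,
      "age_dist", "must be 3 non-negative weights summing to 1")
  invisible(cfg)
}

#' Load a configuration from YAML text or file
#'
#' Reads a flat key-value YAML document whose keys mirror the configuration
#' field names exactly (see [thn_config()]).  Missing keys take the
#' documented defaults; unknown keys are rejected.
#'
#' @param source a path to a YAML file, or a string containing YAML.
#' @return a validated `thn_config` bundle.
#' @export
#' @examples
#' load_config("p0_daily_od: 0.00033\nhorizon: 30")
load_config <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  parsed <- tryCatch(
    if (file.exists(source)) yaml::read_yaml(source) else yaml::yaml.load(source),
    error = function(e) stop("configuration parse failure: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(parsed)) parsed <- list()
  if (!is.list(parsed)) stop("configuration must be a key-value document",
                             call. = FALSE)
  do.call(thn_config, parsed)
}

#' Serialise a configuration to YAML
#'
#' `format_config()` returns the fully resolved configuration as YAML text
#' (the `--print-config` facility); `write_config()` writes it to a file.
#' `load_config(format_config(cfg))` reproduces `cfg` exactly.
#'
#' @param cfg a `thn_config` bundle.
#' @param path file path for `write_config`.
#' @return YAML text (`format_config`) or `path` invisibly (`write_config`).
#' @export
format_config <- function(cfg) {
  validate_config(cfg)
  yaml::as.yaml(unclass(cfg), precision = 15L)
}

#' @rdname format_config
#' @export
write_config <- function(cfg, path) {
  writeLines(format_config(cfg), path)
  invisible(path)
}

#' @export
print.thn_config <- function(x, ...) {
  cat("<thn_config>\n")
  cat(format_config(x))
  invisible(x)
}

#' Uncertainty ranges for the sensitivity analysis
#'
#' Lower/upper bounds for every parameter swept in the global sensitivity
#' analysis: the baseline daily overdose probability, the per-overdose
#' fatality probability, the relative-risk multipliers (sex, injection use,
#' post-release windows, age), the three bystander-behaviour probabilities,
#' and the inmate opioid-use composition fractions.  Published percentage
#' bounds are converted to fractions.
#'
#' @return a data.frame with columns `parameter`, `lower`, `upper`,
#'   `default` (the interval midpoint used for point runs).
#' @export
default_ranges <- function() {
  tab <- .param_table()
  swept <- vapply(tab, `[[`, logical(1), 4L)
  tab <- tab[swept]
  data.frame(
    parameter = names(tab),
    lower = vapply(tab, function(x) as.numeric(x[[2L]]), numeric(1)),
    upper = vapply(tab, function(x) as.numeric(x[[3L]]), numeric(1)),
    default = vapply(tab, function(x) as.numeric(x[[1L]]), numeric(1)),
    row.names = NULL
  )
}

#' The intervention scenario grid
#'
#' The full cross product of community coverage (0, 15, 30% of the opioid
#' user population), jail-release coverage (0, 50, 100% of opioid-using
#' persons at release) and peer-network probability (0, 15, 30%) -- 27
#' scenarios, numbered with the no-intervention baseline as scenario 1.
#' Network level varies fastest, then community, then jail, so e.g.
#' scenario 19 is jail-only distribution at 100%.
#'
#' @return a data.frame with columns `scenario`, `cov_community`, `cov_jail`,
#'   `cov_network` (all coverages as fractions).
#' @export
#' @examples
#' scenario_grid()[c(1, 2, 19, 27), ]
scenario_grid <- function() {
  g <- expand.grid(cov_network = c(0, 0.15, 0.30),
                   cov_community = c(0, 0.15, 0.30),
                   cov_jail = c(0, 0.50, 1.00),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("cov_community", "cov_jail", "cov_network")]
  data.frame(scenario = seq_len(nrow(g)), g, row.names = NULL)
}

#' Resolve a scenario specification
#'
#' Accepts a scenario id (row of [scenario_grid()]), a named or unnamed
#' numeric coverage triple `(community, jail, network)`, or a one-row
#' data.frame with the grid columns.
#'
#' @param scenario scenario id, coverage triple, or grid row.
#' @return a named numeric vector `c(cov_community, cov_jail, cov_network)`.
#' @export
as_scenario <- function(scenario) {
  if (is.data.frame(scenario)) {
    stopifnot(nrow(scenario) == 1L)
    scenario <- unlist(scenario[, c("cov_community", "cov_jail", "cov_network")])
  } else if (length(scenario) == 1L && is.numeric(scenario)) {
    g <- scenario_grid()
    if (!scenario %in% g$scenario) stop("unknown scenario id: ", scenario,
                                        call. = FALSE)
    scenario <- unlist(g[g$scenario == scenario,
                         c("cov_community", "cov_jail", "cov_network")])
  }
  scenario <- as.numeric(scenario)
  if (length(scenario) != 3L || any(!is.finite(scenario)) ||
      any(scenario < 0) || any(scenario > 1))
    stop("scenario coverages must be three fractions in [0, 1]", call. = FALSE)
  names(scenario) <- c("cov_community", "cov_jail", "cov_network")
  scenario
}

#' Sample parameter draws for sensitivity sweeps
#'
#' Draws `n` points from the hypercube defined by `ranges`, either as a Sobol
#' low-discrepancy sequence, a Latin hypercube, or plain uniform sampling.
#' Each draw is a full override set for the swept parameters; apply one with
#' [apply_draw()].
#'
#' The Sobol sequence is deterministic (the `seed` is ignored for
#' `method = "sobol_sequence"`); for the stochastic methods the same seed
#' yields identical draws.
#'
#' @param ranges a data.frame as from [default_ranges()] (columns
#'   `parameter`, `lower`, `upper`).
#' @param n number of draws (>= 1).
#' @param method sampling scheme.
#' @param seed integer RNG seed for the stochastic methods.
#' @return a data.frame with column `draw` (1..n) plus one column per
#'   parameter.
#' @export
sample_parameter_draws <- function(ranges, n,
                                   method = c("sobol_sequence",
                                              "latin_hypercube",
                                              "uniform_random"),
                                   seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  stopifnot(all(c("parameter", "lower", "upper") %in% names(ranges)))
  if (any(ranges$lower > ranges$upper))
    stop("ranges must satisfy lower <= upper", call. = FALSE)
  d <- nrow(ranges)
  u <- switch(method,
    sobol_sequence = sobol_sequence(n, d),
    latin_hypercube = { set.seed(seed); lhs::randomLHS(n, d) },
    uniform_random = { set.seed(seed); matrix(stats::runif(n * d), n, d) })
  x <- sweep(u, 2L, ranges$upper - ranges$lower, `*`)
  x <- sweep(x, 2L, ranges$lower, `+`)
  colnames(x) <- ranges$parameter
  data.frame(draw = seq_len(n), x, row.names = NULL)
}

#' Apply a parameter draw to a configuration
#'
#' @param cfg a `thn_config` bundle.
#' @param draw a one-row data.frame (or named vector/list) of parameter
#'   overrides, e.g. one row of [sample_parameter_draws()].
#' @return the overridden, re-validated `thn_config`.
#' @export
apply_draw <- function(cfg, draw) {
  if (is.data.frame(draw)) {
    stopifnot(nrow(draw) == 1L)
    draw <- as.list(draw)
  } else draw <- as.list(draw)
  draw$draw <- NULL
  for (k in names(draw)) {
    if (!k %in% names(cfg)) stop("unknown parameter in draw: ", k, call. = FALSE)
    cfg[[k]] <- as.numeric(draw[[k]])
  }
  validate_config(cfg)
  cfg
}

# Effective (scale-adjusted) structural sizes for a run.
effective_sizes <- function(cfg) {
  list(n_iou = as.integer(round(cfg$n_iou * cfg$scale)),
       n_niou = as.integer(round(cfg$n_niou * cfg$scale)),
       n_cli = as.integer(round(cfg$n_cli * cfg$scale)),
       booking_rate = cfg$booking_rate * cfg$scale,
       census_target = as.integer(round(cfg$census_target * cfg$scale)))
}
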