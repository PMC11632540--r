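# Overdose hazard model and bystander-resolution tree.

#' Post-release relative-risk multiplier
#'
#' Selects the overdose risk multiplier from days since jail release using
#' 0-based half-open windows: \[0, 14) days -> week 0-2, \[14, 28) -> week
#' 3-4, \[28, Inf) -> week >= 5 (which persists indefinitely after any
#' incarceration).  `NA` (never released) maps to the reference multiplier 1.
#'
#' @param cfg a [thn_config()] bundle.
#' @param days_since_release integer vector (NA = never released).
#' @return numeric vector of multipliers.
#' @export
release_multiplier <- function(cfg, days_since_release) {
  out <- rep(1, length(days_since_release))
  idx <- !is.na(days_since_release)
  d <- days_since_release[idx]
  out[idx] <- ifelse(d < 14L, cfg$rr_release_wk0_2,
              ifelse(d < 28L, cfg$rr_release_wk3_4, cfg$rr_release_wk5plus))
  out
}

#' Person-level relative risk of overdose
#'
#' The product of the multipliers for the person's attributes: sex
#' (`rr_female` if female), injection use (`rr_iou` if IOU), the post-release
#' window (see [release_multiplier()]) and age group (`rr_age_25_29`,
#' `rr_age_30plus`).  Reference categories (male, NIOU, never incarcerated,
#' age 18-24) multiply by 1.  Defined only for opioid users.
#'
#' @param cfg a [thn_config()] bundle.
#' @param use_type integer codes (1 = IOU, 2 = NIOU) or labels.
#' @param female logical vector.
#' @param age_group integer 1..3 (18-24, 25-29, >= 30) or labels.
#' @param days_since_release integer vector (NA = never released).
#' @return numeric vector of relative risks (> 0).
#' @export
#' @examples
#' cfg <- thn_config(rr_female = 0.8, rr_iou = 3, rr_release_wk0_2 = 6,
#'                   rr_age_30plus = 2)
#' relative_risk(cfg, "IOU", TRUE, ">=30", 5)  # 0.8 * 3 * 6 * 2 = 28.8
relative_risk <- function(cfg, use_type, female, age_group,
                          days_since_release = NA_integer_) {
  if (is.character(use_type))
    use_type <- match(use_type, use_type_labels) - 1L
  if (is.character(age_group))
    age_group <- match(age_group, age_group_labels)
  if (any(use_type == USE_NONE))
    stop("relative_risk is undefined for persons who do not use opioids",
         call. = FALSE)
  n <- max(length(use_type), length(female), length(age_group),
           length(days_since_release))
  use_type <- rep_len(use_type, n); female <- rep_len(female, n)
  age_group <- rep_len(age_group, n)
  days_since_release <- rep_len(days_since_release, n)
  age_mult <- c(1, cfg$rr_age_25_29, cfg$rr_age_30plus)[age_group]
  ifelse(female, cfg$rr_female, 1) *
    ifelse(use_type == USE_IOU, cfg$rr_iou, 1) *
    release_multiplier(cfg, days_since_release) *
    age_mult
}

#' Risk-adjusted daily overdose probability
#'
#' `min(1, p0_daily_od * relative_risk)`: the baseline daily probability
#' scaled by the person's multiplicative relative risk, clamped at 1 (upper
#' corners of the sensitivity ranges can push the product past 1).
#'
#' @inheritParams relative_risk
#' @return numeric vector of probabilities.
#' @export
daily_overdose_probability <- function(cfg, use_type, female, age_group,
                                       days_since_release = NA_integer_) {
  pmin(1, cfg$p0_daily_od *
         relative_risk(cfg, use_type, female, age_group, days_since_release))
}

#' Draw today's overdose events
#'
#' Independent Bernoulli draw per alive, out-of-custody opioid user with the
#' person's risk-adjusted daily probability; at most one overdose per person
#' per day.  With a keyed `rng` the occurrence uniform is keyed by (person,
#' day), coupling occurrences across scenarios sharing a seed.
#'
#' @param pop a `thn_population`.
#' @param cfg a [thn_config()] bundle.
#' @param rng a [thn_rng()] keyed source, or `NULL` for the global stream.
#' @param day integer day index (keys the uniforms when `rng` is given).
#' @return integer vector of person ids overdosing today.
#' @export
draw_overdoses <- function(pop, cfg, rng = NULL, day = 0L) {
  eligible <- which(pop$use_type != USE_NONE & pop$alive & !pop$in_jail)
  if (!length(eligible)) return(integer(0))
  p <- daily_overdose_probability(cfg, pop$use_type[eligible],
                                  pop$female[eligible],
                                  pop$age_group[eligible],
                                  pop$days_since_release[eligible])
  u <- if (is.null(rng)) stats::runif(length(eligible))
       else keyed_uniform(rng, eligible, day, 7L)
  eligible[u < p]
}

#' Resolve overdose events through the bystander tree
#'
#' For each event: a bystander is present with probability `p_bystander`;
#' when present, naloxone is administered with probability `p_administer`
#' provided a kit is available at the scene, and EMS is called independently
#' with probability `p_ems`.  The event is fatal with probability
#' `f_fatal * m`, where `m = 1 - eff_naloxone` if naloxone was administered,
#' else `1 - eff_ems` if EMS was called, else 1 (naloxone dominates; the two
#' effects do not stack).  Four uniforms drive each event (presence,
#' administration, EMS, fatality); with a keyed `rng` they are keyed by
#' (person, day, purpose), so an event resolves identically across scenarios
#' sharing a seed unless kit availability actually differs.
#'
#' @param cfg a [thn_config()] bundle.
#' @param availability logical vector: a kit (own or peer) is available at
#'   each event.
#' @param rng a [thn_rng()] keyed source, or `NULL` for the global stream.
#' @param pids integer person ids for the events (required with `rng`).
#' @param day integer day index (keys the uniforms when `rng` is given).
#' @return data.frame with logical columns `bystander_present`,
#'   `naloxone_administered`, `ems_called`, `fatal`.
#' @export
resolve_overdose <- function(cfg, availability, rng = NULL, pids = NULL,
                             day = 0L) {
  n <- length(availability)
  if (is.null(rng)) {
    u_by <- stats::runif(n); u_adm <- stats::runif(n)
    u_ems <- stats::runif(n); u_fatal <- stats::runif(n)
  } else {
    stopifnot(length(pids) == n)
    u_by <- keyed_uniform(rng, pids, day, 8L)
    u_adm <- keyed_uniform(rng, pids, day, 9L)
    u_ems <- keyed_uniform(rng, pids, day, 10L)
    u_fatal <- keyed_uniform(rng, pids, day, 11L)
  }
  bystander <- u_by < cfg$p_bystander
  administered <- bystander & availability & (u_adm < cfg$p_administer)
  ems <- bystander & (u_ems < cfg$p_ems)
  mult <- ifelse(administered, 1 - cfg$eff_naloxone,
                 ifelse(ems, 1 - cfg$eff_ems, 1))
  fatal <- u_fatal < cfg$f_fatal * mult
  data.frame(bystander_present = bystander, naloxone_administered = administered,
             ems_called = ems, fatal = fatal)
}

#' Closed-form death probability for an overdose event
#'
#' Enumerates the bystander tree of [resolve_overdose()]:
#' `P(fatal) = f_fatal * ((1 - p_by) + p_by * m)` with
#' `m = q * (1 - eff_naloxone) + (1 - q) * (1 - p_ems * eff_ems)` and
#' `q = p_administer` if a kit is available, else 0.  Serves as the exact
#' oracle for the stochastic resolution.
#'
#' @param cfg a [thn_config()] bundle.
#' @param availability logical vector (recycled).
#' @return numeric vector of death probabilities.
#' @export
analytic_death_probability <- function(cfg, availability) {
  q <- ifelse(availability, cfg$p_administer, 0)
  m_present <- q * (1 - cfg$eff_naloxone) +
    (1 - q) * (1 - cfg$p_ems * cfg$eff_ems)
  cfg$f_fatal * ((1 - cfg$p_bystander) + cfg$p_bystander * m_present)
}
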