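# Synthetic population: opioid users (by injection route), the
# criminal-legal-system-involved (CLI) pool, their overlap, and demographics.

# use_type codes used throughout (and in the compiled core)
USE_NONE <- 0L
USE_IOU  <- 1L
USE_NIOU <- 2L

use_type_labels <- c("NONE", "IOU", "NIOU")
age_group_labels <- c("18-24", "25-29", ">=30")

#' Build the synthetic agent population
#'
#' Creates `n_iou` injection opioid users, `n_niou` non-injection users, and
#' enough opioid-naive persons to fill the CLI pool of size `n_cli`
#' (all scaled by `cfg$scale`).  The CLI pool contains
#' `round(frac_inmates_iou * n_cli)` IOUs and `round(frac_inmates_niou *
#' n_cli)` NIOUs, drawn uniformly from the user pools; the remainder are
#' non-users.  Because bookings later sample uniformly from the CLI pool, the
#' expected in-custody composition equals these fractions.  Sex and age group
#' are i.i.d. from the configured marginals for every person.
#'
#' @param cfg a [thn_config()] bundle.
#' @param seed integer seed; identical `(cfg, seed)` gives an identical
#'   population.
#' @return an object of class `thn_population`: a list of aligned per-person
#'   vectors (`pid`, `use_type`, `female`, `age_group`, `cli`, `in_jail`,
#'   `release_day`, `days_since_release`, `has_kit`, `peer_kit`, `alive`).
#'   `days_since_release` is `NA` for the never-released; `release_day` is
#'   `NA` outside custody.
#' @export
build_population <- function(cfg, seed = 1L) {
  validate_config(cfg)
  eff <- effective_sizes(cfg)
  n_cli_iou <- as.integer(round(cfg$frac_inmates_iou * eff$n_cli))
  n_cli_niou <- as.integer(round(cfg$frac_inmates_niou * eff$n_cli))
  if (n_cli_iou > eff$n_iou)
    stop("infeasible population: CLI injection users (", n_cli_iou,
         ") exceed the IOU pool (", eff$n_iou, ")", call. = FALSE)
  if (n_cli_niou > eff$n_niou)
    stop("infeasible population: CLI non-injection users (", n_cli_niou,
         ") exceed the NIOU pool (", eff$n_niou, ")", call. = FALSE)
  n_cli_none <- eff$n_cli - n_cli_iou - n_cli_niou
  n <- eff$n_iou + eff$n_niou + n_cli_none

  set.seed(seed)
  use_type <- c(rep(USE_IOU, eff$n_iou), rep(USE_NIOU, eff$n_niou),
                rep(USE_NONE, n_cli_none))
  cli <- rep(FALSE, n)
  if (n_cli_iou > 0L)
    cli[sample.int(eff$n_iou, n_cli_iou)] <- TRUE
  if (n_cli_niou > 0L)
    cli[eff$n_iou + sample.int(eff$n_niou, n_cli_niou)] <- TRUE
  if (n_cli_none > 0L)
    cli[eff$n_iou + eff$n_niou + seq_len(n_cli_none)] <- TRUE
  female <- stats::runif(n) < cfg$sex_female_frac
  age_group <- sample.int(3L, n, replace = TRUE, prob = cfg$age_dist)

  structure(list(
    pid = seq_len(n),
    use_type = use_type,
    female = female,
    age_group = age_group,
    cli = cli,
    in_jail = rep(FALSE, n),
    release_day = rep(NA_integer_, n),
    days_since_release = rep(NA_integer_, n),
    has_kit = rep(FALSE, n),
    peer_kit = rep(FALSE, n),
    alive = rep(TRUE, n)
  ), class = "thn_population", scale = cfg$scale)
}

#' @export
print.thn_population <- function(x, ...) {
  cat("<thn_population> ", length(x$pid), " persons (",
      sum(x$use_type == USE_IOU), " IOU, ", sum(x$use_type == USE_NIOU),
      " NIOU, ", sum(x$cli), " CLI)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.thn_population <- function(x, ...) {
  data.frame(pid = x$pid,
             use_type = use_type_labels[x$use_type + 1L],
             female = x$female,
             age_group = age_group_labels[x$age_group],
             cli = x$cli,
             in_jail = x$in_jail,
             release_day = x$release_day,
             days_since_release = x$days_since_release,
             has_kit = x$has_kit,
             peer_kit = x$peer_kit,
             alive = x$alive)
}

#' Cross-tabulated population counts
#'
#' Counts persons by use type, CLI status, custody status, sex and age
#' group.  Counts always sum to the total population; structural marginals
#' (user counts, CLI pool size) match the build inputs exactly, sampled
#' demographics within binomial error.
#'
#' @param pop a `thn_population`.
#' @return a data.frame of counts, one row per occupied cell.
#' @export
population_summary <- function(pop) {
  df <- as.data.frame(pop)
  tab <- as.data.frame(table(use_type = df$use_type, cli = df$cli,
                             in_jail = df$in_jail, female = df$female,
                             age_group = df$age_group),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  names(tab)[names(tab) == "Freq"] <- "count"
  rownames(tab) <- NULL
  tab
}

#' Write a population to CSV
#'
#' One row per person, columns as in [as.data.frame.thn_population()]; for
#' audit and fixture reuse.
#'
#' @param pop a `thn_population`.
#' @param path output file path.
#' @export
write_population_csv <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}
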