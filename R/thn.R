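# Take-home naloxone distribution channels and the kit ledger.

#' Create an empty kit ledger
#'
#' Tracks kits by channel plus replacements and uses.  At every tick the
#' identity `total kits = community + jail + network + replacements` holds,
#' and `used == replacements` (a used kit is replaced immediately).
#'
#' @return a named numeric vector of class `thn_ledger` with entries
#'   `community`, `jail`, `network`, `replacements`, `used`.
#' @export
new_ledger <- function() {
  structure(c(community = 0, jail = 0, network = 0, replacements = 0, used = 0),
            class = "thn_ledger")
}

#' @export
print.thn_ledger <- function(x, ...) {
  cat("<thn_ledger> community", x[["community"]], "| jail", x[["jail"]],
      "| network", x[["network"]], "| replacements", x[["replacements"]],
      "| used", x[["used"]], "| total", total_kits(x), "\n")
  invisible(x)
}

#' Total kits distributed
#'
#' @param ledger a `thn_ledger`.
#' @param include_replacements count replacement kits handed out after use
#'   (default TRUE, the convention used for cost and NNT metrics).
#' @return total kit count.
#' @export
total_kits <- function(ledger, include_replacements = TRUE) {
  base <- ledger[["community"]] + ledger[["jail"]] + ledger[["network"]]
  if (include_replacements) base + ledger[["replacements"]] else base
}

#' One-time community distribution at horizon start
#'
#' Each alive opioid user independently receives a kit with probability
#' `cov_community`.  Called once, after the warm-up.
#'
#' @param pop a `thn_population`.
#' @param scenario coverage triple (see [as_scenario()]).
#' @param ledger a `thn_ledger`.
#' @param rng a [thn_rng()] keyed source, or `NULL` for the global stream.
#' @param day integer day index (keys the uniforms when `rng` is given).
#' @return list with updated `pop` and `ledger`.
#' @export
apply_community_distribution <- function(pop, scenario, ledger, rng = NULL,
                                         day = 0L) {
  scenario <- as_scenario(scenario)
  users <- which(pop$use_type != USE_NONE & pop$alive)
  if (length(users)) {
    u <- if (is.null(rng)) stats::runif(length(users))
         else keyed_uniform(rng, users, day, 4L)
    give <- u < scenario[["cov_community"]] & !pop$has_kit[users]
    pop$has_kit[users[give]] <- TRUE
    ledger[["community"]] <- ledger[["community"]] + sum(give)
  }
  list(pop = pop, ledger = ledger)
}

#' Jail-release distribution
#'
#' Each opioid-using person released today receives a kit with probability
#' `cov_jail`.  Re-receipt is idempotent: a person holds at most one own kit,
#' and the ledger counts kits, not offers.
#'
#' @param pop a `thn_population`.
#' @param released integer ids released today.
#' @param scenario coverage triple.
#' @param ledger a `thn_ledger`.
#' @param rng a [thn_rng()] keyed source, or `NULL` for the global stream.
#' @param day integer day index (keys the uniforms when `rng` is given).
#' @return list with updated `pop` and `ledger`.
#' @export
apply_jail_release_distribution <- function(pop, released, scenario, ledger,
                                            rng = NULL, day = 0L) {
  scenario <- as_scenario(scenario)
  rel <- released[pop$use_type[released] != USE_NONE & pop$alive[released]]
  if (length(rel)) {
    u <- if (is.null(rng)) stats::runif(length(rel))
         else keyed_uniform(rng, rel, day, 5L)
    give <- u < scenario[["cov_jail"]] & !pop$has_kit[rel]
    pop$has_kit[rel[give]] <- TRUE
    ledger[["jail"]] <- ledger[["jail"]] + sum(give)
  }
  list(pop = pop, ledger = ledger)
}

#' Peer-network distribution
#'
#' Each opioid-using person released today acquires, with probability
#' `cov_network`, at least one peer holding a kit that would be available at
#' an overdose (`peer_kit` flag).  Setting an already-set flag is idempotent
#' and not double-counted.
#'
#' @inheritParams apply_jail_release_distribution
#' @return list with updated `pop` and `ledger`.
#' @export
apply_network_distribution <- function(pop, released, scenario, ledger,
                                       rng = NULL, day = 0L) {
  scenario <- as_scenario(scenario)
  rel <- released[pop$use_type[released] != USE_NONE & pop$alive[released]]
  if (length(rel)) {
    u <- if (is.null(rng)) stats::runif(length(rel))
         else keyed_uniform(rng, rel, day, 6L)
    give <- u < scenario[["cov_network"]] & !pop$peer_kit[rel]
    pop$peer_kit[rel[give]] <- TRUE
    ledger[["network"]] <- ledger[["network"]] + sum(give)
  }
  list(pop = pop, ledger = ledger)
}

#' Kit availability at an event, and post-event replacement
#'
#' Availability at a person's overdose is `has_kit | peer_kit`.  For each
#' event at which naloxone was administered the ledger records one use and
#' one immediate replacement; possession flags remain set.
#'
#' @param pop a `thn_population`.
#' @param pids integer ids of the persons overdosing.
#' @param administered logical: naloxone administered at each event.
#' @param ledger a `thn_ledger`.
#' @return list with `availability` (logical) and the updated `ledger`.
#' @export
availability_and_use <- function(pop, pids, administered = NULL,
                                 ledger = new_ledger()) {
  availability <- pop$has_kit[pids] | pop$peer_kit[pids]
  if (!is.null(administered)) {
    n_used <- sum(administered)
    ledger[["used"]] <- ledger[["used"]] + n_used
    ledger[["replacements"]] <- ledger[["replacements"]] + n_used
  }
  list(availability = availability, ledger = ledger)
}
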