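# Global sensitivity screening of the simulator via Saltelli sampling and
# Sobol indices.

.outcome_from_cell <- function(outcome, run, baseline, scale) {
  switch(outcome,
    deaths_total = run$deaths_total / scale,
    pct_averted = if (baseline$deaths_total > 0)
      100 * (baseline$deaths_total - run$deaths_total) / baseline$deaths_total
      else NA_real_,
    pct_averted_released = if (baseline$deaths_released > 0)
      100 * (baseline$deaths_released - run$deaths_released) /
        baseline$deaths_released else NA_real_,
    deaths_averted = (baseline$deaths_total - run$deaths_total) / scale,
    deaths_averted_released =
      (baseline$deaths_released - run$deaths_released) / scale,
    stop("unknown outcome selector: ", outcome, call. = FALSE))
}

#' Sobol parameter screening of the simulator
#'
#' Estimates first-order and total-order Sobol indices of a simulation
#' outcome with respect to the swept parameters, by evaluating the model over
#' a Saltelli design ([saltelli_design()]) and applying the Jansen
#' estimators ([sobol_indices()]).  `n_base * (d + 2)` design points are
#' evaluated; each evaluation averages `replicates` stochastic runs, and for
#' averted-death outcomes pairs every run with a same-seed baseline run
#' (common random numbers).  The same replicate seeds are reused at every
#' design point, so a parameter with a collapsed (zero-width) range has a
#' total-order index of exactly zero.
#'
#' @param cfg a [thn_config()] bundle (sets everything not swept, including
#'   `scale` -- screening is usually run at reduced population scale).
#' @param ranges swept-parameter ranges, as [default_ranges()].
#' @param scenario intervention scenario under which the outcome is measured.
#' @param outcome one of `"pct_averted_released"`, `"pct_averted"`,
#'   `"deaths_averted"`, `"deaths_averted_released"`, `"deaths_total"`.
#' @param n_base Saltelli base sample size (powers of 2 recommended).
#' @param base_seed integer seed (design and replicate seeds).
#' @param replicates stochastic replicates averaged per design point.
#' @param engine `"cpp"` or `"r"`.
#' @param verbose print progress.
#' @return a data.frame with columns `parameter`, `S1`, `ST`, carrying the
#'   outcome name and design size as attributes.
#' @export
sobol_screening <- function(cfg, ranges = default_ranges(),
                            scenario = c(0, 1, 0),
                            outcome = c("pct_averted_released", "pct_averted",
                                        "deaths_averted",
                                        "deaths_averted_released",
                                        "deaths_total"),
                            n_base = 128L, base_seed = 1L, replicates = 2L,
                            engine = c("cpp", "r"), verbose = FALSE) {
  outcome <- match.arg(outcome)
  engine <- match.arg(engine)
  scenario <- as_scenario(scenario)
  design <- saltelli_design(ranges, n_base, seed = base_seed)
  d <- length(design$parameters)
  needs_baseline <- outcome != "deaths_total"
  seeds <- vapply(seq_len(replicates),
                  function(r) derive_seed(base_seed, 0L, r), integer(1))

  eval_point <- function(x) {
    cfg_x <- apply_draw(cfg, stats::setNames(as.list(x), design$parameters))
    vals <- vapply(seeds, function(s) {
      run <- run_simulation(cfg_x, scenario, s, engine)
      base <- if (needs_baseline)
        run_simulation(cfg_x, c(0, 0, 0), s, engine) else NULL
      .outcome_from_cell(outcome, run, base, cfg$scale)
    }, numeric(1))
    # a replicate whose baseline records no (subgroup) deaths has nothing to
    # avert: it contributes zero, not a missing value
    v <- mean(vals, na.rm = TRUE)
    if (is.finite(v)) v else 0
  }
  eval_matrix <- function(m, label) {
    y <- vapply(seq_len(nrow(m)), function(i) eval_point(m[i, ]), numeric(1))
    if (verbose) message("evaluated ", label, " (", nrow(m), " points)")
    y
  }
  yA <- eval_matrix(design$A, "A")
  yB <- eval_matrix(design$B, "B")
  yAB <- lapply(seq_len(d), function(i)
    eval_matrix(design$AB[[i]], paste0("AB_", design$parameters[i])))
  out <- sobol_indices(yA, yB, yAB, parameters = design$parameters)
  attr(out, "outcome") <- outcome
  attr(out, "n_base") <- as.integer(n_base)
  attr(out, "replicates") <- as.integer(replicates)
  out
}
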