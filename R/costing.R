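#' Mistimed-birth cost adjustment
#'
#' Down-weights the unit cost of a live birth for the fraction `f` of
#' unintended births that are mistimed rather than unwanted: a mistimed birth
#' would have occurred anyway after a delay of `d` years, so only the
#' discounted difference is attributable to the contraceptive failure.
#' The adjusted cost is `cost * (1 - f / (1 + disc_rate)^delay_years)`.
#'
#' @param cost Unadjusted birth cost in USD (> 0); vectorised, so a whole
#'   (median, min, max) summary can be adjusted at once.
#' @param adj A [birth_adjustment()].
#' @return Adjusted cost, strictly below `cost` whenever `f > 0`.
#' @examples
#' adjust_birth_cost(12953, birth_adjustment(0.60, 0.03, 2))  # 5627.3
#' @export
adjust_birth_cost <- function(cost, adj) {
  if (any(!is.finite(cost)) || any(cost <= 0))
    stop("cost must be finite and > 0")
  stop_on_violations(validate_birth_adjustment(adj))
  cost * (1 - adj$f / (1 + adj$disc_rate)^adj$delay_years)
}

#' Total direct costs from expected event counts
#'
#' Multiplies unrounded expected outcome counts by per-outcome unit costs,
#' independently for the median, minimum and maximum columns, and sums over
#' outcomes. In adjusted mode the birth unit costs (median, min and max) are
#' each passed through [adjust_birth_cost()] before multiplication; the
#' published pre-tabulated `birth_adjusted` summary in the configuration is
#' never used here. Costs are not discounted within the horizon.
#'
#' @param events An `event_counts` from [expected_events()].
#' @param costs Named list of [cost_summary()] objects covering the four
#'   outcome states (extra keys such as `birth_adjusted` are ignored).
#' @param mode `"unadjusted"` or `"adjusted"` birth costing.
#' @param adj A [birth_adjustment()]; required in adjusted mode.
#' @return A `cost_totals` object: 5x3 matrix (four outcome rows plus
#'   `total`, columns median/min/max, 2020 USD) with attribute `mode`.
#' @export
total_costs <- function(events, costs,
                        mode = c("unadjusted", "adjusted"), adj = NULL) {
  mode <- match.arg(mode)
  missing_keys <- setdiff(OUTCOME_STATES, names(costs))
  if (length(missing_keys))
    stop("missing cost entries for outcome(s): ",
         paste(missing_keys, collapse = ", "))
  unit <- t(vapply(OUTCOME_STATES,
                   function(nm) unclass(costs[[nm]])[c("median", "min", "max")],
                   numeric(3)))
  if (mode == "adjusted") {
    if (is.null(adj)) stop("adjusted mode requires adjustment parameters")
    unit["birth", ] <- adjust_birth_cost(unit["birth", ], adj)
  }
  per_outcome <- unit * events$outcomes[OUTCOME_STATES]
  totals <- rbind(per_outcome, total = colSums(per_outcome))
  structure(totals, class = c("cost_totals", "matrix"), mode = mode)
}

#' Evaluate one strategy column
#'
#' Composes the full pipeline for one strategy at one failure-rate variant:
#' [rate_to_prob()] on the chosen rate, [build_transition_matrix()],
#' [run_cohort_trace()], [expected_events()] and [total_costs()] in both
#' costing modes. One call corresponds to one column of the base-case
#' results table.
#'
#' @param spec A [strategy_spec()].
#' @param variant Which rate to use: `"point"`, or `"low"`/`"high"` for the
#'   95% CI bounds (an error if the spec carries no bounds).
#' @param cfg A [model_config()].
#' @return A `strategy_result`: list with `strategy`, `variant`, `rate`,
#'   `events`, `costs_unadjusted`, `costs_adjusted`, `trace`.
#' @examples
#' cfg <- load_config(ddi_example_config())
#' res <- evaluate_strategy(cfg$strategies[[2]], "point", cfg)
#' res$events$display$total_up  # 23
#' @export
evaluate_strategy <- function(spec, variant = c("point", "low", "high"), cfg) {
  variant <- match.arg(variant)
  rate <- switch(variant, point = spec$rate_point, low = spec$rate_low,
                 high = spec$rate_high)
  if (is.null(rate))
    stop("strategy '", spec$name, "' has no ", variant, " rate variant")
  p_fail <- rate_to_prob(rate, cfg$settings$cycle_length)
  m <- build_transition_matrix(p_fail, cfg$outcomes)
  trace <- run_cohort_trace(m, cfg$settings)
  events <- expected_events(trace)
  structure(
    list(strategy = spec$name, variant = variant, rate = rate,
         events = events,
         costs_unadjusted = total_costs(events, cfg$costs, "unadjusted"),
         costs_adjusted = total_costs(events, cfg$costs, "adjusted",
                                      cfg$adjustment),
         trace = trace),
    class = "strategy_result")
}

#' Evaluate every available rate variant of a strategy
#'
#' @param spec A [strategy_spec()].
#' @param cfg A [model_config()].
#' @return Named list of `strategy_result` objects (`point`, plus `low` and
#'   `high` when the spec carries CI bounds), of class `strategy_bundle`.
#' @export
evaluate_strategy_bundle <- function(spec, cfg) {
  variants <- c("point",
                if (!is.null(spec$rate_low)) "low",
                if (!is.null(spec$rate_high)) "high")
  structure(lapply(stats::setNames(variants, variants), evaluate_strategy,
                   spec = spec, cfg = cfg),
            class = "strategy_bundle")
}

#' Incremental burden between two strategies
#'
#' Bound-for-bound deterministic interval propagation, in the comparator
#' minus reference direction:
#' \itemize{
#'   \item count difference: displayed (integer-rounded) total unintended
#'     pregnancies at point-estimate rates;
#'   \item median difference: median cost totals at point-estimate rates;
#'   \item lower bound: comparator's minimum-unit-cost total at its lowest
#'     available rate variant minus the reference's at its lowest;
#'   \item upper bound: maximum-unit-cost totals at the highest available
#'     rate variants, differenced the same way.
#' }
#' These are worst/best-case envelopes, not probabilistic intervals.
#' Swapping comparator and reference negates every entry.
#'
#' @param comparator,reference `strategy_bundle`s (or single
#'   `strategy_result`s, treated as point-only bundles) computed under the
#'   same configuration.
#' @return An `incremental_result`: list with the two strategy names,
#'   `delta_up`, and per costing mode a named vector
#'   `c(median, min, max)` of cost differences in 2020 USD, plus
#'   `delta_up_range` (count differences at the bound variants).
#' @examples
#' cfg <- load_config(ddi_example_config())
#' b <- lapply(cfg$strategies, evaluate_strategy_bundle, cfg = cfg)
#' compare_strategies(b[[2]], b[[1]])$delta_up  # 20
#' @export
compare_strategies <- function(comparator, reference) {
  comparator <- as_bundle(comparator)
  reference <- as_bundle(reference)
  lo <- function(b) if (!is.null(b$low)) b$low else b$point
  hi <- function(b) if (!is.null(b$high)) b$high else b$point

  delta_mode <- function(slot) {
    c(median = comparator$point[[slot]]["total", "median"] -
        reference$point[[slot]]["total", "median"],
      min = lo(comparator)[[slot]]["total", "min"] -
        lo(reference)[[slot]]["total", "min"],
      max = hi(comparator)[[slot]]["total", "max"] -
        hi(reference)[[slot]]["total", "max"])
  }
  disp_up <- function(res) res$events$display$total_up

  structure(
    list(comparator = comparator$point$strategy,
         reference = reference$point$strategy,
         delta_up = disp_up(comparator$point) - disp_up(reference$point),
         delta_up_range = c(min = disp_up(lo(comparator)) -
                              disp_up(lo(reference)),
                            max = disp_up(hi(comparator)) -
                              disp_up(hi(reference))),
         unadjusted = delta_mode("costs_unadjusted"),
         adjusted = delta_mode("costs_adjusted")),
    class = "incremental_result")
}

as_bundle <- function(x) {
  if (inherits(x, "strategy_result"))
    return(structure(list(point = x), class = "strategy_bundle"))
  if (!inherits(x, "strategy_bundle"))
    stop("expected a strategy_result or strategy_bundle")
  x
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  additional unintended pregnancies: %d (range %d-%d)\n",
              as.integer(x$delta_up), as.integer(x$delta_up_range["min"]),
              as.integer(x$delta_up_range["max"])))
  for (mode in c("unadjusted", "adjusted"))
    cat(sprintf("  additional cost, %s: %s (%s-%s) USD\n", mode,
                format_dollar(x[[mode]]["median"]),
                format_dollar(x[[mode]]["min"]),
                format_dollar(x[[mode]]["max"])))
  invisible(x)
}

format_dollar <- function(x) {
  format(round_half_up(x), big.mark = ",", scientific = FALSE, trim = TRUE)
}
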