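#' Individual-level stochastic microsimulation
#'
#' Simulates each woman independently, month by month, under the same
#' process the deterministic cohort trace propagates in expectation:
#' contraceptive failure in each cycle with the per-cycle probability
#' implied by the strategy's annual rate, a categorical outcome draw at
#' failure, and a unit-cost draw for the outcome. It serves as an
#' independent convergence oracle for the deterministic engine (double
#' implementation of the same model).
#'
#' Each woman consumes exactly three uniform variates from a single seeded
#' stream — failure timing (geometric inverse-CDF), outcome category, and
#' cost draw — so results are bit-reproducible given `(seed, n_women)` and
#' independent of evaluation order.
#'
#' @param cfg A [model_config()].
#' @param strategy A [strategy_spec()] (one of `cfg$strategies`, typically).
#' @param variant Rate variant, as in [evaluate_strategy()].
#' @param n_women Number of women to simulate (default: configured cohort
#'   size).
#' @param seed Integer seed (default: configured seed).
#' @param cost_sampling `"median"` (point mass at the median unit cost,
#'   matching the deterministic engine's median pathway) or `"triangular"`
#'   (triangular(min, median, max) spread; an exploratory extension).
#' @param cost_mode `"unadjusted"` or `"adjusted"` birth costing.
#' @return A `sim_result`: list with `counts` (integer events per outcome),
#'   `total_up`, `total_cost`, `seed`, `n_women`, `rate`, and `roster`
#'   (data frame: `id`, `failure_cycle`, `outcome`, `cost_draw`; NA for
#'   women without failure).
#' @examples
#' cfg <- load_config(ddi_example_config())
#' sim <- simulate_cohort(cfg, cfg$strategies[[2]], n_women = 2000, seed = 7)
#' sim$total_up
#' @export
simulate_cohort <- function(cfg, strategy, variant = "point",
                            n_women = cfg$settings$cohort_size,
                            seed = cfg$settings$seed,
                            cost_sampling = c("median", "triangular"),
                            cost_mode = c("unadjusted", "adjusted")) {
  cost_sampling <- match.arg(cost_sampling)
  cost_mode <- match.arg(cost_mode)
  if (!is_scalar_number(n_women) || n_women < 1)
    stop("n_women must be >= 1")
  n_women <- as.integer(n_women)
  rate <- switch(variant, point = strategy$rate_point,
                 low = strategy$rate_low, high = strategy$rate_high,
                 stop("unknown variant: ", variant))
  if (is.null(rate))
    stop("strategy '", strategy$name, "' has no ", variant, " rate variant")
  p <- rate_to_prob(rate, cfg$settings$cycle_length)
  n_cycles <- cfg$settings$n_cycles

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  u_fail <- stats::runif(n_women)
  u_outcome <- stats::runif(n_women)
  u_cost <- stats::runif(n_women)

  # geometric inverse-CDF: cycle of first failure; Inf when p == 0
  fail_cycle <- if (p == 0) rep(Inf, n_women)
                else if (p == 1) rep(1, n_women)
                else ceiling(log1p(-u_fail) / log1p(-p))
  failed <- fail_cycle <= n_cycles

  cum <- cumsum(unclass(cfg$outcomes))
  outcome_idx <- findInterval(u_outcome, cum, left.open = TRUE) + 1L
  outcome_idx[outcome_idx > 4L] <- 4L  # guard against rounding at u ~ 1

  unit <- t(vapply(OUTCOME_STATES,
                   function(nm) unclass(cfg$costs[[nm]])[c("median", "min",
                                                           "max")],
                   numeric(3)))
  if (cost_mode == "adjusted")
    unit["birth", ] <- adjust_birth_cost(unit["birth", ], cfg$adjustment)
  cost_draw <- if (cost_sampling == "median") {
    unit[outcome_idx, "median"]
  } else {
    qtriangular(u_cost, unit[outcome_idx, "min"], unit[outcome_idx, "median"],
                unit[outcome_idx, "max"])
  }

  roster <- data.frame(
    id = seq_len(n_women),
    failure_cycle = ifelse(failed, fail_cycle, NA_integer_),
    outcome = ifelse(failed, OUTCOME_STATES[outcome_idx], NA_character_),
    cost_draw = ifelse(failed, cost_draw, NA_real_),
    stringsAsFactors = FALSE)

  counts <- vapply(OUTCOME_STATES,
                   function(nm) sum(roster$outcome == nm, na.rm = TRUE),
                   integer(1))
  structure(
    list(counts = counts, total_up = sum(counts),
         total_cost = sum(roster$cost_draw, na.rm = TRUE),
         seed = as.integer(seed), n_women = n_women, rate = rate,
         cost_sampling = cost_sampling, cost_mode = cost_mode,
         roster = roster),
    class = "sim_result")
}

# triangular quantile function, vectorised; mode = median of the summary
qtriangular <- function(u, lo, mode, hi) {
  fc <- (mode - lo) / (hi - lo)
  left <- u < fc
  out <- numeric(length(u))
  out[left] <- lo[left] + sqrt(u[left] * (hi[left] - lo[left]) *
                                 (mode[left] - lo[left]))
  out[!left] <- hi[!left] - sqrt((1 - u[!left]) * (hi[!left] - lo[!left]) *
                                   (hi[!left] - mode[!left]))
  degenerate <- hi == lo
  out[degenerate] <- lo[degenerate]
  out
}

#' Compare a microsimulation against deterministic expectations
#'
#' For the total number of unintended pregnancies, each outcome count, and
#' (when unit costs are supplied and costs were sampled as a point mass at
#' the median) the total cost, computes
#' `z = (observed - expected_scaled) / SE`, where `expected_scaled` rescales
#' the deterministic expectation from the configured cohort size to the
#' simulated `n_women` and the SE comes from the binomial/multinomial model
#' implied by independent women. Zero-variance quantities with zero
#' discrepancy report `z = 0`. `|z| > 3` flags a quantity as inconsistent.
#'
#' @param sim A `sim_result` from [simulate_cohort()].
#' @param events An `event_counts` from the deterministic engine, computed
#'   under the same parameters.
#' @param cohort_size Cohort size the deterministic expectations refer to.
#' @param unit_costs Optional named vector of per-outcome unit costs (the
#'   costs the simulation drew from, e.g. medians) enabling the total-cost
#'   row.
#' @return Data frame with columns `quantity`, `observed`, `expected`, `se`,
#'   `z`, `flag`.
#' @export
convergence_report <- function(sim, events, cohort_size,
                               unit_costs = NULL) {
  scale <- sim$n_women / cohort_size
  zrow <- function(quantity, observed, expected, se) {
    z <- if (se > 0) (observed - expected) / se
         else if (abs(observed - expected) < 1e-12) 0
         else Inf
    data.frame(quantity = quantity, observed = observed, expected = expected,
               se = se, z = z, flag = abs(z) > 3, stringsAsFactors = FALSE)
  }
  p_up <- events$total_up / cohort_size
  out <- zrow("total_up", sim$total_up, events$total_up * scale,
              sqrt(sim$n_women * p_up * (1 - p_up)))
  for (nm in OUTCOME_STATES) {
    p_i <- events$outcomes[[nm]] / cohort_size
    out <- rbind(out, zrow(nm, sim$counts[[nm]],
                           events$outcomes[[nm]] * scale,
                           sqrt(sim$n_women * p_i * (1 - p_i))))
  }
  if (!is.null(unit_costs)) {
    u <- unit_costs[OUTCOME_STATES]
    p_i <- events$outcomes[OUTCOME_STATES] / cohort_size
    mu <- sum(p_i * u)                       # per-woman mean cost
    sigma2 <- sum(p_i * u^2) - mu^2          # per-woman cost variance
    out <- rbind(out, zrow("total_cost", sim$total_cost, mu * sim$n_women,
                           sqrt(sim$n_women * sigma2)))
  }
  out
}

#' Export a simulation roster to CSV
#'
#' @param sim A `sim_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster_csv <- function(sim, path) {
  utils::write.csv(sim$roster, path, row.names = FALSE)
  invisible(path)
}

#' Simulation summary as JSON
#'
#' @param sim A `sim_result`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when `path` is given).
#' @export
sim_summary_json <- function(sim, path = NULL) {
  summary <- list(seed = sim$seed, n_women = sim$n_women, rate = sim$rate,
                  total_up = sim$total_up,
                  counts = as.list(sim$counts),
                  total_cost = sim$total_cost,
                  cost_sampling = sim$cost_sampling,
                  cost_mode = sim$cost_mode)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
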