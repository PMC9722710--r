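#' Convert an annual failure rate to a per-period probability
#'
#' Converts a constant annual failure rate expressed per 100 woman-years
#' (Pearl index) into the probability of failure over a period of `t` years
#' under an exponential (constant-hazard) model:
#' `p = 1 - exp(-(rate/100) * t)`.
#'
#' @param rate Annual failures per 100 woman-years (>= 0); vectorised.
#' @param t Period length in years (> 0).
#' @return Per-period failure probability in \[0, 1).
#' @examples
#' rate_to_prob(2.3, 1 / 12)  # monthly probability for 2.3/100WY
#' @export
rate_to_prob <- function(rate, t) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("rate must be finite and >= 0")
  if (any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0")
  1 - exp(-(rate / 100) * t)
}

#' Build the five-state absorbing transition matrix
#'
#' One transient "initial method" state and four absorbing outcome states.
#' A woman who experiences contraceptive failure in a cycle moves directly
#' to her terminal pregnancy-outcome state: the transition probability into
#' each outcome is the product of the per-cycle failure probability and the
#' outcome share (e.g. `p_fail * p_birth` for birth). Unintended pregnancy
#' itself is not a state.
#'
#' @param p_fail Per-cycle failure probability in \[0, 1\].
#' @param outcomes An [outcome_distribution()].
#' @return 5x5 row-stochastic matrix with dimnames [MODEL_STATES]; rows 2-5
#'   are identity rows (absorbing states).
#' @export
build_transition_matrix <- function(p_fail, outcomes) {
  if (!is_scalar_number(p_fail) || p_fail < 0 || p_fail > 1)
    stop("p_fail must be a probability in [0, 1]")
  stop_on_violations(validate_outcome_distribution(outcomes))
  m <- diag(5)
  dimnames(m) <- list(MODEL_STATES, MODEL_STATES)
  m[1, 1] <- 1 - p_fail
  m[1, OUTCOME_STATES] <- p_fail * unclass(outcomes)
  m
}

#' Run the deterministic cohort trace
#'
#' Propagates a closed cohort through the transition matrix: the whole
#' cohort starts in the initial state and each cycle applies
#' `row[c + 1] = row[c] %*% m`. No half-cycle correction is applied:
#' transitions are whole-cycle jumps, so the cumulative failure after
#' `n_cycles` equals the closed form `1 - exp(-r * n_cycles * cycle_length)`.
#'
#' @param m Transition matrix from [build_transition_matrix()].
#' @param settings A [run_settings()] (cohort size and number of cycles).
#' @return A `cohort_trace`: `(n_cycles + 1) x 5` matrix of expected state
#'   occupancy in women, with the cycle-0 row the initial distribution and
#'   attribute `cohort_size`.
#' @export
run_cohort_trace <- function(m, settings) {
  stopifnot(is.matrix(m), all(dim(m) == c(5L, 5L)))
  if (any(m < 0) || any(m > 1) || any(abs(rowSums(m) - 1) > 1e-12))
    stop("m must be a row-stochastic matrix with entries in [0, 1]")
  stop_on_violations(validate_run_settings(settings))
  n <- settings$n_cycles
  trace <- matrix(0, nrow = n + 1L, ncol = 5L,
                  dimnames = list(0:n, MODEL_STATES))
  trace[1L, "initial"] <- settings$cohort_size
  for (cyc in seq_len(n))
    trace[cyc + 1L, ] <- trace[cyc, ] %*% m
  structure(trace, class = c("cohort_trace", "matrix"),
            cohort_size = settings$cohort_size)
}

#' Cohort trace as a data frame
#'
#' @param trace A `cohort_trace`.
#' @return Data frame with a `cycle` column followed by the five occupancy
#'   columns, suitable for CSV export.
#' @export
trace_as_df <- function(trace) {
  data.frame(cycle = as.integer(rownames(trace)),
             unclass(trace)[, , drop = FALSE], row.names = NULL)
}

#' Export a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace_as_df(trace), path, row.names = FALSE)
  invisible(path)
}

#' Expected event counts from a cohort trace
#'
#' Reads the absorbing-state occupancies at the final cycle: the expected
#' number of women whose unintended pregnancy ended in each outcome, plus
#' their sum (total expected unintended pregnancies). Expectations are
#' real-valued and carried unrounded through all cost computations; the
#' `display` forms round half-away-from-zero for presentation only.
#'
#' @param trace A `cohort_trace` from [run_cohort_trace()].
#' @return An `event_counts` object: list with `outcomes` (named numeric,
#'   expected women per outcome), `total_up` (their sum), and `display`
#'   (integer-rounded forms, `outcomes` and `total_up`).
#' @examples
#' cfg <- load_config(ddi_example_config())
#' p <- rate_to_prob(2.3, cfg$settings$cycle_length)
#' m <- build_transition_matrix(p, cfg$outcomes)
#' expected_events(run_cohort_trace(m, cfg$settings))
#' @export
expected_events <- function(trace) {
  last <- unclass(trace)[nrow(trace), ]
  outcomes <- last[OUTCOME_STATES]
  structure(
    list(outcomes = outcomes,
         total_up = sum(outcomes),
         display = list(outcomes = round_half_up(outcomes),
                        total_up = round_half_up(sum(outcomes)))),
    class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat("Expected unintended pregnancies:",
      format(x$total_up, digits = 6),
      sprintf("(displayed %d)\n", as.integer(x$display$total_up)))
  for (nm in names(x$outcomes))
    cat(sprintf("  %-22s %10.4f  (displayed %d)\n", nm, x$outcomes[[nm]],
                as.integer(x$display$outcomes[[nm]])))
  invisible(x)
}

#' Closed-form expected unintended pregnancies
#'
#' Analytic counterpart of the cohort trace. With a single transient state
#' and constant hazard, the cumulative failure probability over the horizon
#' is `1 - exp(-(rate/100) * n_cycles * cycle_length)`; multiplied by the
#' cohort size this must equal the trace-based total to within 1e-9 relative
#' error, which makes it an independent oracle for [run_cohort_trace()].
#'
#' @param rate Annual failures per 100 woman-years (>= 0).
#' @param settings A [run_settings()].
#' @return Expected number of unintended pregnancies (women).
#' @examples
#' closed_form_up(2.3, run_settings())  # 22.7375...
#' @export
closed_form_up <- function(rate, settings) {
  stop_on_violations(validate_run_settings(settings))
  horizon <- settings$n_cycles * settings$cycle_length
  settings$cohort_size * rate_to_prob(rate, horizon)
}

#' Round half away from zero
#'
#' Display rounding for expected counts (base R's `round()` rounds half to
#' even). Expected counts stay unrounded in all cost arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
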