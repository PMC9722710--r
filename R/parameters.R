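#' Model states
#'
#' Fixed state order used by every matrix, trace and result in the package:
#' the transient "initial method" (on contraception, not pregnant) state
#' followed by the four absorbing unintended-pregnancy outcome states.
#'
#' @format Character vector of length 5.
#' @export
MODEL_STATES <- c("initial", "birth", "induced_abortion",
                  "spontaneous_abortion", "ectopic")

#' Absorbing outcome states
#'
#' The four unintended-pregnancy outcomes, in canonical order.
#'
#' @format Character vector of length 4.
#' @export
OUTCOME_STATES <- MODEL_STATES[-1]

#' Contraceptive strategy specification
#'
#' A named contraceptive-failure setting: an annual failure rate per 100
#' woman-years (Pearl index) with optional 95% confidence bounds on the same
#' scale. Rates are stored exactly as published, per 100 woman-years; the
#' division by 100 happens only inside [rate_to_prob()].
#'
#' @param name Strategy label, e.g. `"OC + enzyme inducer"`.
#' @param rate_point Annual failure rate per 100 woman-years (>= 0).
#' @param rate_low,rate_high Optional 95% CI bounds, same units, satisfying
#'   `0 <= rate_low <= rate_point <= rate_high`.
#' @return An object of class `strategy_spec`.
#' @examples
#' strategy_spec("OC + enzyme inducer", 2.3, 1.9, 2.8)
#' @export
strategy_spec <- function(name, rate_point, rate_low = NULL, rate_high = NULL) {
  x <- structure(
    list(name = as.character(name),
         rate_point = as.numeric(rate_point),
         rate_low = if (!is.null(rate_low)) as.numeric(rate_low),
         rate_high = if (!is.null(rate_high)) as.numeric(rate_high)),
    class = "strategy_spec")
  stop_on_violations(validate_strategy_spec(x, field = name))
  x
}

validate_strategy_spec <- function(x, field = x$name) {
  v <- violations()
  if (!is.character(x$name) || length(x$name) != 1L || !nzchar(x$name))
    v <- add_violation(v, paste0("strategies[", field, "].name"),
                       "non-empty label required", x$name)
  if (!is_scalar_number(x$rate_point) || x$rate_point < 0)
    v <- add_violation(v, paste0("strategies[", field, "].rate_point"),
                       "rate_point must be a number >= 0", x$rate_point)
  has_low <- !is.null(x$rate_low); has_high <- !is.null(x$rate_high)
  if (has_low != has_high)
    v <- add_violation(v, paste0("strategies[", field, "]"),
                       "rate_low and rate_high must be given together",
                       if (has_low) x$rate_low else x$rate_high)
  if (has_low && has_high &&
      !(is_scalar_number(x$rate_low) && is_scalar_number(x$rate_high) &&
        0 <= x$rate_low && x$rate_low <= x$rate_point &&
        x$rate_point <= x$rate_high))
    v <- add_violation(v, paste0("strategies[", field, "]"),
                       "requires 0 <= rate_low <= rate_point <= rate_high",
                       paste(x$rate_low, x$rate_point, x$rate_high))
  v
}

#' Unintended-pregnancy outcome distribution
#'
#' Probabilities that an unintended pregnancy ends in each of the four
#' outcomes. Must sum to 1 (tolerance 1e-9).
#'
#' @param birth,induced_abortion,spontaneous_abortion,ectopic Outcome
#'   probabilities in \[0, 1\].
#' @return An object of class `outcome_distribution`: a named numeric vector
#'   in the canonical [OUTCOME_STATES] order.
#' @examples
#' outcome_distribution(0.492, 0.350, 0.153, 0.005)
#' @export
outcome_distribution <- function(birth, induced_abortion,
                                 spontaneous_abortion, ectopic) {
  p <- c(birth = as.numeric(birth),
         induced_abortion = as.numeric(induced_abortion),
         spontaneous_abortion = as.numeric(spontaneous_abortion),
         ectopic = as.numeric(ectopic))
  x <- structure(p, class = "outcome_distribution")
  stop_on_violations(validate_outcome_distribution(x))
  x
}

validate_outcome_distribution <- function(x, field = "outcomes") {
  v <- violations()
  p <- unclass(x)
  if (length(p) != 4L || !all(names(p) == OUTCOME_STATES)) {
    return(add_violation(v, field, "must contain exactly the four outcomes",
                         paste(names(p), collapse = ",")))
  }
  for (nm in names(p))
    if (!is_scalar_number(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      v <- add_violation(v, paste0(field, ".", nm),
                         "probability must lie in [0, 1]", p[[nm]])
  if (all(is.finite(p)) && abs(sum(p) - 1) > 1e-9)
    v <- add_violation(v, field, "probabilities must sum to 1 (tol 1e-9)",
                       sum(p))
  v
}

#' Per-outcome unit-cost summary
#'
#' Direct medical cost of one event in 2020 USD, summarised across literature
#' sources as median with a minimum-maximum range.
#'
#' @param median,min,max Costs in 2020 USD, `0 < min <= median <= max`.
#' @return An object of class `cost_summary`.
#' @export
cost_summary <- function(median, min, max) {
  x <- structure(
    c(median = as.numeric(median), min = as.numeric(min),
      max = as.numeric(max)),
    class = "cost_summary")
  stop_on_violations(validate_cost_summary(x))
  x
}

validate_cost_summary <- function(x, field = "cost") {
  v <- violations()
  s <- unclass(x)
  if (!all(vapply(s, is_scalar_number, logical(1))))
    return(add_violation(v, field, "median/min/max must be numbers",
                         paste(s, collapse = ",")))
  if (s[["min"]] <= 0)
    v <- add_violation(v, paste0(field, ".min"), "must be > 0", s[["min"]])
  if (!(s[["min"]] <= s[["median"]] && s[["median"]] <= s[["max"]]))
    v <- add_violation(v, field, "requires min <= median <= max",
                       paste(s[["min"]], s[["median"]], s[["max"]]))
  v
}

#' Mistimed-birth cost-adjustment parameters
#'
#' Parameters of the adjustment that down-weights live-birth costs for the
#' fraction of unintended births that are mistimed rather than unwanted: a
#' mistimed birth is assumed to occur anyway after a delay of `delay_years`,
#' so only the discounted difference is attributed to the contraceptive
#' failure. The adjusted unit cost is
#' `cost * (1 - f / (1 + disc_rate)^delay_years)`; see [adjust_birth_cost()].
#'
#' @param f Fraction of unintended births that are mistimed, in \[0, 1\].
#' @param disc_rate Annual discount rate (>= 0); used only inside this
#'   adjustment, never to discount within the model horizon.
#' @param delay_years Assumed delay of a mistimed birth, in years (>= 0).
#' @return An object of class `birth_adjustment`.
#' @export
birth_adjustment <- function(f = 0.60, disc_rate = 0.03, delay_years = 2) {
  x <- structure(
    list(f = as.numeric(f), disc_rate = as.numeric(disc_rate),
         delay_years = as.numeric(delay_years)),
    class = "birth_adjustment")
  stop_on_violations(validate_birth_adjustment(x))
  x
}

validate_birth_adjustment <- function(x, field = "adjustment") {
  v <- violations()
  if (!is_scalar_number(x$f) || x$f < 0 || x$f > 1)
    v <- add_violation(v, paste0(field, ".f"), "must lie in [0, 1]", x$f)
  if (!is_scalar_number(x$disc_rate) || x$disc_rate < 0)
    v <- add_violation(v, paste0(field, ".disc_rate"), "must be >= 0",
                       x$disc_rate)
  if (!is_scalar_number(x$delay_years) || x$delay_years < 0)
    v <- add_violation(v, paste0(field, ".delay_years"), "must be >= 0",
                       x$delay_years)
  v
}

#' Run settings
#'
#' Cohort size, cycle structure and seed for one model run. The base case is
#' a closed cohort of 1,000 women followed over 12 monthly cycles (one year).
#'
#' @param cohort_size Number of women in the closed cohort (integer >= 1).
#' @param cycle_length Length of one cycle in years (> 0); base case `1/12`.
#' @param n_cycles Number of cycles (integer >= 1); base case 12.
#' @param seed Integer seed for stochastic components.
#' @return An object of class `run_settings`.
#' @export
run_settings <- function(cohort_size = 1000, cycle_length = 1 / 12,
                         n_cycles = 12, seed = 1L) {
  x <- structure(
    list(cohort_size = as.numeric(cohort_size),
         cycle_length = as.numeric(cycle_length),
         n_cycles = as.integer(n_cycles),
         seed = as.integer(seed)),
    class = "run_settings")
  stop_on_violations(validate_run_settings(x))
  x
}

validate_run_settings <- function(x, field = "settings") {
  v <- violations()
  if (!is_scalar_number(x$cohort_size) || x$cohort_size < 1)
    v <- add_violation(v, paste0(field, ".cohort_size"), "must be >= 1",
                       x$cohort_size)
  if (!is_scalar_number(x$cycle_length) || x$cycle_length <= 0)
    v <- add_violation(v, paste0(field, ".cycle_length"), "must be > 0",
                       x$cycle_length)
  if (is.na(x$n_cycles) || x$n_cycles < 1L)
    v <- add_violation(v, paste0(field, ".n_cycles"), "must be >= 1",
                       x$n_cycles)
  v
}

#' Full model configuration
#'
#' Bundles every model input: the contraceptive strategies, the outcome
#' distribution, per-outcome unit costs, the mistimed-birth adjustment and
#' the run settings. The cost table carries one `cost_summary` per outcome
#' plus an optional `birth_adjusted` entry holding a pre-tabulated adjusted
#' birth-cost summary; the engine's adjusted mode always recomputes the
#' adjustment from the unadjusted `birth` entry via [adjust_birth_cost()],
#' and `birth_adjusted` is retained as documentation only.
#'
#' @param strategies List of [strategy_spec()] objects (at least one).
#' @param outcomes An [outcome_distribution()].
#' @param costs Named list of [cost_summary()] objects with keys exactly
#'   [OUTCOME_STATES], optionally plus `birth_adjusted`.
#' @param adjustment A [birth_adjustment()].
#' @param settings A [run_settings()].
#' @param scenarios Optional named list of [scenario_spec()] objects.
#' @return An object of class `model_config`.
#' @seealso [load_config()], [validate_config()]
#' @export
model_config <- function(strategies, outcomes, costs,
                         adjustment = birth_adjustment(),
                         settings = run_settings(),
                         scenarios = NULL) {
  x <- structure(
    list(schema_version = 1L, strategies = strategies, outcomes = outcomes,
         costs = costs, adjustment = adjustment, settings = settings,
         scenarios = scenarios),
    class = "model_config")
  stop_on_violations(validate_config(x))
  x
}

#' Validate a model configuration
#'
#' Checks every invariant of a [model_config()] and reports all violations
#' rather than stopping at the first. Constructors call this internally; it
#' is exported so configurations assembled by hand or loaded with
#' `check = FALSE` can be audited.
#'
#' @param cfg A `model_config` (or a structurally similar list).
#' @return A data frame with columns `field`, `rule`, `value`; zero rows iff
#'   the configuration is valid.
#' @examples
#' cfg <- load_config(ddi_example_config())
#' nrow(validate_config(cfg)) == 0
#' @export
validate_config <- function(cfg) {
  v <- violations()
  if (length(cfg$strategies) < 1L)
    v <- add_violation(v, "strategies", "at least one strategy required", 0)
  for (i in seq_along(cfg$strategies))
    v <- rbind(v, validate_strategy_spec(
      cfg$strategies[[i]],
      field = if (!is.null(cfg$strategies[[i]]$name)) cfg$strategies[[i]]$name
              else i))
  v <- rbind(v, validate_outcome_distribution(cfg$outcomes))
  cost_keys <- setdiff(names(cfg$costs), "birth_adjusted")
  if (!setequal(cost_keys, OUTCOME_STATES))
    v <- add_violation(v, "costs",
                       "keys must be exactly the four outcome states",
                       paste(names(cfg$costs), collapse = ","))
  for (nm in names(cfg$costs))
    v <- rbind(v, validate_cost_summary(cfg$costs[[nm]],
                                        field = paste0("costs.", nm)))
  v <- rbind(v, validate_birth_adjustment(cfg$adjustment))
  v <- rbind(v, validate_run_settings(cfg$settings))
  for (nm in names(cfg$scenarios))
    v <- rbind(v, validate_scenario_spec(cfg$scenarios[[nm]],
                                         field = paste0("scenarios.", nm)))
  v
}

#' Path to the shipped base-case configuration
#'
#' Convenience accessor for the YAML file holding the published base case:
#' three strategies (perfect-use OC alone 0.3; OC + enzyme inducer 2.3,
#' 95% CI 1.9-2.8; OC + enzyme-neutral drug 1.6, 95% CI 1.4-1.8 failures per
#' 100 woman-years), the four-way outcome distribution, 2020-USD unit costs,
#' the mistimed-birth adjustment (f = 0.60, 3% discount, 2-year delay) and a
#' 1,000-woman, 12-cycle run.
#'
#' @return File path to `basecase.yaml` inside the installed package.
#' @export
ddi_example_config <- function() {
  system.file("extdata", "basecase.yaml", package = "ddiburden",
              mustWork = TRUE)
}

CONFIG_TOP_KEYS <- c("schema_version", "strategies", "outcomes", "costs",
                     "adjustment", "settings", "scenarios")

#' Load a model configuration from file
#'
#' Reads a YAML (or JSON) configuration conforming to the documented schema,
#' builds a [model_config()] and validates every invariant. Unknown keys are
#' rejected to prevent silently ignored typos. `cycle_length` may be written
#' as the string `"1/12"` to express a monthly cycle exactly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param check If `TRUE` (default) stop on any invariant violation;
#'   `FALSE` returns the (possibly invalid) object for use with
#'   [validate_config()].
#' @return A `model_config`.
#' @examples
#' cfg <- load_config(ddi_example_config())
#' cfg$strategies[[2]]$rate_point  # 2.3
#' @export
load_config <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(raw, check = check)
}

config_from_list <- function(raw, check = TRUE) {
  unknown <- setdiff(names(raw), CONFIG_TOP_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(CONFIG_TOP_KEYS, names(raw))
  if (length(missing))
    stop("missing configuration keys: ", paste(missing, collapse = ", "))
  if (!identical(as.integer(raw$schema_version), 1L))
    stop("unsupported schema_version: ", raw$schema_version)

  strategies <- lapply(raw$strategies, function(s) {
    unknown <- setdiff(names(s), c("name", "rate_point", "rate_low",
                                   "rate_high"))
    if (length(unknown))
      stop("unknown strategy keys: ", paste(unknown, collapse = ", "))
    structure(list(name = s$name, rate_point = as.numeric(s$rate_point),
                   rate_low = if (!is.null(s$rate_low)) as.numeric(s$rate_low),
                   rate_high = if (!is.null(s$rate_high))
                     as.numeric(s$rate_high)),
              class = "strategy_spec")
  })

  ro <- raw$outcomes
  unknown <- setdiff(names(ro), OUTCOME_STATES)
  if (length(unknown))
    stop("unknown outcome keys: ", paste(unknown, collapse = ", "))
  outcomes <- structure(
    vapply(OUTCOME_STATES, function(nm) as.numeric(ro[[nm]]), numeric(1)),
    class = "outcome_distribution")

  unknown <- setdiff(names(raw$costs), c(OUTCOME_STATES, "birth_adjusted"))
  if (length(unknown))
    stop("unknown cost keys: ", paste(unknown, collapse = ", "))
  costs <- lapply(raw$costs, function(cs) {
    structure(c(median = as.numeric(cs$median), min = as.numeric(cs$min),
                max = as.numeric(cs$max)),
              class = "cost_summary")
  })

  ra <- raw$adjustment
  adjustment <- structure(
    list(f = as.numeric(ra$f), disc_rate = as.numeric(ra$disc_rate),
         delay_years = as.numeric(ra$delay_years)),
    class = "birth_adjustment")

  scenarios <- if (!is.null(raw$scenarios)) {
    if (is.null(names(raw$scenarios)))
      stop("scenarios must be a named mapping")
    lapply(raw$scenarios, scenario_spec_from_list)
  }

  rs <- raw$settings
  cl <- rs$cycle_length
  if (is.character(cl)) {   # allow exact fractions such as "1/12"
    parts <- strsplit(cl, "/", fixed = TRUE)[[1]]
    cl <- if (length(parts) == 2L)
      as.numeric(parts[1]) / as.numeric(parts[2]) else as.numeric(cl)
  }
  settings <- structure(
    list(cohort_size = as.numeric(rs$cohort_size),
         cycle_length = as.numeric(cl),
         n_cycles = as.integer(rs$n_cycles),
         seed = as.integer(if (is.null(rs$seed)) 1L else rs$seed)),
    class = "run_settings")

  cfg <- structure(
    list(schema_version = 1L, strategies = strategies, outcomes = outcomes,
         costs = costs, adjustment = adjustment, settings = settings,
         scenarios = scenarios),
    class = "model_config")
  if (check) stop_on_violations(validate_config(cfg))
  cfg
}

#' Write a model configuration to file
#'
#' Serialises a [model_config()] to YAML so that
#' `load_config(write_config(cfg, path))` round-trips losslessly.
#'
#' @param cfg A `model_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- list(
    schema_version = cfg$schema_version,
    strategies = lapply(cfg$strategies, function(s)
      Filter(Negate(is.null),
             list(name = s$name, rate_point = s$rate_point,
                  rate_low = s$rate_low, rate_high = s$rate_high))),
    outcomes = as.list(unclass(cfg$outcomes)),
    costs = lapply(cfg$costs, function(cs) as.list(unclass(cs))),
    adjustment = list(f = cfg$adjustment$f,
                      disc_rate = cfg$adjustment$disc_rate,
                      delay_years = cfg$adjustment$delay_years),
    settings = list(cohort_size = cfg$settings$cohort_size,
                    cycle_length = cfg$settings$cycle_length,
                    n_cycles = cfg$settings$n_cycles,
                    seed = cfg$settings$seed))
  if (!is.null(cfg$scenarios))
    out$scenarios <- lapply(cfg$scenarios, scenario_spec_as_list)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model configuration (schema v", x$schema_version, ")\n", sep = "")
  for (s in x$strategies) {
    ci <- if (!is.null(s$rate_low))
      sprintf(" (95%% CI %g-%g)", s$rate_low, s$rate_high) else ""
    cat(sprintf("  %-28s %g%s per 100 woman-years\n", s$name, s$rate_point,
                ci))
  }
  cat("  outcome shares:",
      paste(sprintf("%s=%g", names(x$outcomes), unclass(x$outcomes)),
            collapse = " "), "\n")
  cat(sprintf("  cohort %g, %d cycles of %.6f years\n",
              x$settings$cohort_size, x$settings$n_cycles,
              x$settings$cycle_length))
  invisible(x)
}

# ---- violation bookkeeping ----

violations <- function() {
  data.frame(field = character(), rule = character(), value = character(),
             stringsAsFactors = FALSE)
}

add_violation <- function(v, field, rule, value) {
  rbind(v, data.frame(field = field, rule = rule,
                      value = paste(format(value), collapse = " "),
                      stringsAsFactors = FALSE))
}

stop_on_violations <- function(v) {
  if (nrow(v))
    stop("invalid configuration:\n",
         paste0("  - ", v$field, ": ", v$rule, " (got ", v$value, ")",
                collapse = "\n"),
         call. = FALSE)
  invisible(NULL)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
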