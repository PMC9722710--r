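#' Scenario specification
#'
#' A named scenario-analysis block: one of the three supported parameter
#' transformations feeding the unchanged engine.
#'
#' @param kind `"typical_use"` (raise failure rates from perfect to typical
#'   use), `"abortion_shift"` (set the induced-abortion outcome share), or
#'   `"age_specific"` (run one outcome mix per age group).
#' @param ... Kind-specific parameters: `typical` and `perfect` rates per
#'   100 woman-years for `typical_use`; `target_share` for `abortion_shift`;
#'   `mixes` (named list of [outcome_distribution()]s) for `age_specific`.
#' @return An object of class `scenario_spec`.
#' @seealso [run_scenario()]
#' @export
scenario_spec <- function(kind = c("typical_use", "abortion_shift",
                                   "age_specific"), ...) {
  kind <- match.arg(kind)
  x <- structure(c(list(kind = kind), list(...)), class = "scenario_spec")
  stop_on_violations(validate_scenario_spec(x))
  x
}

validate_scenario_spec <- function(x, field = "scenario") {
  v <- violations()
  if (!x$kind %in% c("typical_use", "abortion_shift", "age_specific"))
    return(add_violation(v, field, "unknown scenario kind", x$kind))
  if (x$kind == "typical_use") {
    ok <- is_scalar_number(x$typical) && is_scalar_number(x$perfect) &&
      x$perfect >= 0 && x$typical >= x$perfect
    if (!ok)
      v <- add_violation(v, field, "requires typical >= perfect >= 0",
                         paste(x$typical, x$perfect))
  } else if (x$kind == "abortion_shift") {
    if (!is_scalar_number(x$target_share) || x$target_share < 0 ||
        x$target_share > 1)
      v <- add_violation(v, field, "target_share must lie in [0, 1]",
                         x$target_share)
  } else {
    if (!is.list(x$mixes) || is.null(names(x$mixes)) || !length(x$mixes))
      v <- add_violation(v, field, "age_specific requires named mixes",
                         length(x$mixes))
    else for (nm in names(x$mixes))
      v <- rbind(v, validate_outcome_distribution(
        x$mixes[[nm]], field = paste0(field, ".mixes.", nm)))
  }
  v
}

scenario_spec_from_list <- function(raw) {
  if (is.null(raw$kind)) stop("scenario block lacks a 'kind'")
  if (identical(raw$kind, "age_specific")) {
    mixes <- lapply(raw$mixes, function(m)
      structure(vapply(OUTCOME_STATES, function(nm) as.numeric(m[[nm]]),
                       numeric(1)),
                class = "outcome_distribution"))
    scenario_spec("age_specific", mixes = mixes)
  } else if (identical(raw$kind, "typical_use")) {
    scenario_spec("typical_use", typical = as.numeric(raw$typical),
                  perfect = as.numeric(raw$perfect))
  } else if (identical(raw$kind, "abortion_shift")) {
    scenario_spec("abortion_shift",
                  target_share = as.numeric(raw$target_share))
  } else stop("unknown scenario kind: ", raw$kind)
}

scenario_spec_as_list <- function(x) {
  if (x$kind == "age_specific")
    list(kind = x$kind, mixes = lapply(x$mixes, function(m)
      as.list(unclass(m))))
  else if (x$kind == "typical_use")
    list(kind = x$kind, typical = x$typical, perfect = x$perfect)
  else list(kind = x$kind, target_share = x$target_share)
}

#' Run a scenario analysis
#'
#' Applies a scenario's parameter transformation to the configuration and
#' re-runs the unchanged engine. Scenario transformations are pure: the input
#' configuration is never modified.
#'
#' @param cfg A [model_config()].
#' @param scenario A [scenario_spec()], or the name of a scenario block in
#'   `cfg$scenarios`.
#' @return For `typical_use` and `abortion_shift`, a `report_bundle` over the
#'   transformed configuration (see [run_base_case()]); for `age_specific`,
#'   the per-label result list of [age_specific_runs()].
#' @examples
#' cfg <- load_config(ddi_example_config())
#' sc1 <- run_scenario(cfg, "typical_use")
#' @export
run_scenario <- function(cfg, scenario) {
  if (is.character(scenario)) {
    if (is.null(cfg$scenarios[[scenario]]))
      stop("no scenario named '", scenario, "' in the configuration")
    scenario <- cfg$scenarios[[scenario]]
  }
  stop_on_violations(validate_scenario_spec(scenario))
  if (scenario$kind == "typical_use") {
    cfg2 <- cfg
    cfg2$strategies <- typical_use_rates(cfg$strategies, scenario$typical,
                                         scenario$perfect)
    run_base_case(cfg2)
  } else if (scenario$kind == "abortion_shift") {
    cfg2 <- cfg
    cfg2$outcomes <- abortion_shift(cfg$outcomes, scenario$target_share)
    run_base_case(cfg2)
  } else {
    age_specific_runs(scenario$mixes, cfg)
  }
}

#' Shift failure rates from perfect to typical use
#'
#' Scenario transformation replacing the perfect-use OC-alone failure rate
#' with the typical-use rate, and raising every co-medication strategy's rate
#' (point estimate and both CI bounds alike, preserving CI widths) by the
#' typical-minus-perfect increment. Inputs are not modified.
#'
#' @param strategies List of [strategy_spec()] objects.
#' @param typical Typical-use OC-alone failure rate per 100 woman-years.
#' @param perfect Perfect-use OC-alone failure rate per 100 woman-years;
#'   must not exceed `typical`.
#' @param oc_alone Index or name of the OC-alone strategy within
#'   `strategies` (default: the first).
#' @return A new list of `strategy_spec`s with shifted rates.
#' @examples
#' s <- list(strategy_spec("OC alone", 0.3),
#'           strategy_spec("OC + enzyme inducer", 2.3, 1.9, 2.8))
#' typical_use_rates(s, typical = 7.2, perfect = 0.3)[[2]]$rate_point  # 9.2
#' @export
typical_use_rates <- function(strategies, typical, perfect, oc_alone = 1L) {
  if (!is_scalar_number(typical) || !is_scalar_number(perfect) ||
      perfect < 0 || typical < perfect)
    stop("requires typical >= perfect >= 0")
  idx <- if (is.character(oc_alone)) {
    match(oc_alone, vapply(strategies, `[[`, character(1), "name"))
  } else as.integer(oc_alone)
  if (is.na(idx) || idx < 1L || idx > length(strategies))
    stop("oc_alone does not identify a strategy")
  increment <- typical - perfect
  out <- lapply(seq_along(strategies), function(i) {
    s <- strategies[[i]]
    if (i == idx) {
      strategy_spec(s$name, typical, s$rate_low, s$rate_high)
    } else {
      strategy_spec(s$name, s$rate_point + increment,
                    if (!is.null(s$rate_low)) s$rate_low + increment,
                    if (!is.null(s$rate_high)) s$rate_high + increment)
    }
  })
  out
}

#' Shift the induced-abortion share of pregnancy outcomes
#'
#' Scenario transformation setting the induced-abortion share to a target
#' value (e.g. the share observed in a given US state) while holding the
#' spontaneous-abortion and ectopic shares at their base values; the birth
#' share absorbs the remainder. The same hold-constant redistribution rule
#' is used for the age-specific mixes of [age_specific_runs()].
#'
#' @param base An [outcome_distribution()].
#' @param target_abortion_share New induced-abortion share; together with the
#'   base spontaneous and ectopic shares it must not exceed 1.
#' @return A new, valid `outcome_distribution`.
#' @examples
#' base <- outcome_distribution(0.492, 0.350, 0.153, 0.005)
#' abortion_shift(base, 0.50)
#' @export
abortion_shift <- function(base, target_abortion_share) {
  stop_on_violations(validate_outcome_distribution(base))
  if (!is_scalar_number(target_abortion_share) ||
      target_abortion_share < 0 || target_abortion_share > 1)
    stop("target_abortion_share must lie in [0, 1]")
  held <- base[["spontaneous_abortion"]] + base[["ectopic"]]
  if (target_abortion_share + held > 1 + 1e-12)
    stop("infeasible share: target + spontaneous + ectopic exceeds 1")
  outcome_distribution(
    birth = 1 - target_abortion_share - held,
    induced_abortion = target_abortion_share,
    spontaneous_abortion = base[["spontaneous_abortion"]],
    ectopic = base[["ectopic"]])
}

#' Run the model under age-specific outcome mixes
#'
#' Scenario analysis over age-group-specific birth/abortion splits: each mix
#' replaces the configuration's outcome distribution (with spontaneous
#' abortion and ectopic pregnancy required to stay at base-case levels) and
#' every strategy is evaluated at its point-estimate rate for the same fixed
#' cohort, as if all women belonged to one age group at a time. Because the
#' outcome split does not enter the failure dynamics, total unintended
#' pregnancies are identical across mixes; only the outcome composition and
#' costs differ.
#'
#' @param mixes Named list of [outcome_distribution()]s, one per age group.
#' @param cfg A [model_config()].
#' @param allow_held_override If `TRUE`, a mix that alters the spontaneous or
#'   ectopic shares is accepted with a warning instead of an error.
#' @return Named list (one element per mix label) of lists of
#'   `strategy_result`s, one per strategy, point variant.
#' @export
age_specific_runs <- function(mixes, cfg, allow_held_override = FALSE) {
  if (is.null(names(mixes)) || any(!nzchar(names(mixes))))
    stop("mixes must be a named list (one label per age group)")
  base <- cfg$outcomes
  lapply(mixes, function(mix) {
    stop_on_violations(validate_outcome_distribution(mix))
    held_changed <-
      abs(mix[["spontaneous_abortion"]] - base[["spontaneous_abortion"]]) >
        1e-9 || abs(mix[["ectopic"]] - base[["ectopic"]]) > 1e-9
    if (held_changed) {
      if (!allow_held_override)
        stop("age-specific mix must hold spontaneous and ectopic shares ",
             "at base-case values (set allow_held_override = TRUE to force)")
      warning("age-specific mix overrides held spontaneous/ectopic shares")
    }
    cfg_mix <- cfg
    cfg_mix$outcomes <- mix
    lapply(cfg$strategies, evaluate_strategy, variant = "point",
           cfg = cfg_mix)
  })
}
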