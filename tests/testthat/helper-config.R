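# Shared fixtures, built in code.

base_cfg <- function() load_config(ddi_example_config())

# one-strategy config with arbitrary rate, used by property tests
tiny_cfg <- function(rate = 2.3, cohort = 1000, n_cycles = 12,
                     outcomes = outcome_distribution(0.492, 0.350, 0.153,
                                                     0.005)) {
  model_config(
    strategies = list(strategy_spec("test", rate)),
    outcomes = outcomes,
    costs = list(
      birth = cost_summary(12953, 5270, 28664),
      induced_abortion = cost_summary(940, 601, 4233),
      spontaneous_abortion = cost_summary(1121, 601, 3594),
      ectopic = cost_summary(6174, 2840, 15943)),
    adjustment = birth_adjustment(0.60, 0.03, 2),
    settings = run_settings(cohort, 1 / 12, n_cycles, seed = 1L))
}

events_for_rate <- function(rate, cfg = base_cfg()) {
  p <- rate_to_prob(rate, cfg$settings$cycle_length)
  m <- build_transition_matrix(p, cfg$outcomes)
  expected_events(run_cohort_trace(m, cfg$settings))
}
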