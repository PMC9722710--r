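test_that("rate_to_prob implements the constant-hazard transform", {
  expect_equal(rate_to_prob(0, 1 / 12), 0)
  expect_equal(rate_to_prob(0, 5), 0)
  # frozen from 30-digit evaluation of 1 - exp(-0.023/12)
  expect_equal(rate_to_prob(2.3, 1 / 12), 0.00191483103406367798,
               tolerance = 1e-12)
  expect_equal(1000 * rate_to_prob(2.3, 1), 22.737516226722927,
               tolerance = 1e-12)
  expect_equal(round_half_up(1000 * rate_to_prob(2.3, 1)), 23)

  # monotone increasing in both arguments
  rates <- seq(0, 100, by = 2.5)
  expect_true(all(diff(rate_to_prob(rates, 1 / 12)) > 0))
  expect_true(all(diff(rate_to_prob(2.3, c(1 / 12, 0.5, 1, 2, 10))) > 0))
  expect_true(all(rate_to_prob(rates, 1) >= 0 & rate_to_prob(rates, 1) < 1))

  expect_error(rate_to_prob(-0.1, 1), ">= 0")
  expect_error(rate_to_prob(2.3, 0), "> 0")
})

test_that("transition matrix has the absorbing five-state structure", {
  cfg <- base_cfg()
  expect_equal(build_transition_matrix(0, cfg$outcomes),
               diag(5), ignore_attr = TRUE)

  m <- build_transition_matrix(1, outcome_distribution(1, 0, 0, 0))
  expect_equal(unname(m[1, ]), c(0, 1, 0, 0, 0))

  # frozen elementwise products p_fail * shares (30-digit evaluation)
  m <- build_transition_matrix(0.00191483103406367798, cfg$outcomes)
  expect_equal(unname(m[1, -1]),
               c(9.42096868759329566e-4, 6.70190861922287293e-4,
                 2.92969148211742731e-4, 9.57415517031838990e-6),
               tolerance = 1e-12)
  expect_equal(rowSums(m), rep(1, 5), ignore_attr = TRUE)
  expect_equal(m[2:5, 2:5], diag(4), ignore_attr = TRUE)
  expect_true(all(m >= 0 & m <= 1))

  expect_error(build_transition_matrix(1.2, cfg$outcomes), "\\[0, 1\\]")
})

test_that("cohort trace conserves women and decays the initial state", {
  cfg <- base_cfg()

  trace <- run_cohort_trace(diag(5), cfg$settings)
  expect_true(all(trace[, "initial"] == 1000))

  p <- rate_to_prob(2.3, cfg$settings$cycle_length)
  m <- build_transition_matrix(p, cfg$outcomes)
  trace <- run_cohort_trace(m, cfg$settings)
  # closed-form geometric decay of the transient state
  expect_equal(trace[13, "initial"], 977.262483773277,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rowSums(trace)), rep(1000, 13), tolerance = 1e-12)

  # absorbing occupancies non-decreasing, initial non-increasing
  for (nm in OUTCOME_STATES)
    expect_true(all(diff(trace[, nm]) >= 0))
  expect_true(all(diff(trace[, "initial"]) <= 0))
})

test_that("trace equals the closed form over randomized rates and horizons", {
  set.seed(101)
  for (i in 1:25) {
    rate <- runif(1, 0, 100)
    n_cycles <- sample(1:120, 1)
    settings <- run_settings(1000, 1 / 12, n_cycles)
    m <- build_transition_matrix(
      rate_to_prob(rate, settings$cycle_length),
      outcome_distribution(0.492, 0.350, 0.153, 0.005))
    trace <- run_cohort_trace(m, settings)
    up_trace <- expected_events(trace)$total_up
    up_closed <- closed_form_up(rate, settings)
    expect_equal(up_trace, up_closed, tolerance = 1e-9)
    expect_equal(unname(rowSums(trace)), rep(1000, n_cycles + 1),
                 tolerance = 1e-9)
  }
})

test_that("outcome shares of absorbed women are cycle-invariant", {
  cfg <- base_cfg()
  m <- build_transition_matrix(rate_to_prob(2.3, 1 / 12), cfg$outcomes)
  trace <- run_cohort_trace(m, cfg$settings)
  absorbed <- rowSums(trace[-1, OUTCOME_STATES])
  for (nm in OUTCOME_STATES)
    expect_equal(unname(trace[-1, nm] / absorbed),
                 rep(cfg$outcomes[[nm]], 12), tolerance = 1e-9)
})

test_that("expected events match the published display counts", {
  e2 <- events_for_rate(2.3)
  expect_equal(e2$outcomes[["birth"]], 11.18685798, tolerance = 1e-7)
  expect_equal(e2$display$outcomes[["birth"]], 11)
  expect_equal(e2$display$outcomes[["ectopic"]], 0)
  expect_gt(e2$outcomes[["ectopic"]], 0.11)

  expect_equal(events_for_rate(0.3)$display$total_up, 3)
  expect_equal(events_for_rate(1.6)$display$total_up, 16)
  expect_equal(closed_form_up(1.6, run_settings()), 15.8726799447149,
               tolerance = 1e-12)
  expect_equal(closed_form_up(0, run_settings()), 0)

  # outcome expectations always sum to the total
  for (rate in c(0.3, 2.3, 9.2, 55))
    expect_equal(sum(events_for_rate(rate)$outcomes),
                 events_for_rate(rate)$total_up, tolerance = 1e-9)
})

test_that("expected unintended pregnancies increase strictly with the rate", {
  ups <- vapply(c(0.1, 0.3, 1.4, 1.6, 1.9, 2.3, 2.8, 7.2, 9.2, 50),
                function(r) events_for_rate(r)$total_up, numeric(1))
  expect_true(all(diff(ups) > 0))
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -2.5, 11.19, 3.48)),
               c(1, 2, 3, -1, -3, 11, 3))
  expect_equal(round_half_up(3.846, 1), 3.8)
})

test_that("trace exports to a tidy cycle-by-state table", {
  cfg <- base_cfg()
  m <- build_transition_matrix(rate_to_prob(2.3, 1 / 12), cfg$outcomes)
  trace <- run_cohort_trace(m, cfg$settings)
  df <- trace_as_df(trace)
  expect_equal(names(df), c("cycle", MODEL_STATES))
  expect_equal(df$cycle, 0:12)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back$initial, unname(trace[, "initial"]), tolerance = 1e-9)
})
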