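test_that("mistimed-birth adjustment follows the discount formula", {
  adj <- birth_adjustment(0.60, 0.03, 2)
  expect_equal(adjust_birth_cost(1000, birth_adjustment(0, 0.03, 2)), 1000)
  # frozen from 30-digit evaluation of cost * (1 - 0.6/1.03^2)
  expect_equal(adjust_birth_cost(28664, adj), 12452.8585163540,
               tolerance = 1e-12)
  expect_equal(adjust_birth_cost(12953, adj), 5627.33311339429,
               tolerance = 1e-12)
  # vectorised over a whole cost summary
  expect_equal(adjust_birth_cost(c(12953, 5270, 28664), adj),
               c(12953, 5270, 28664) * (1 - 0.6 / 1.03^2))
  expect_error(adjust_birth_cost(0, adj), "> 0")

  # adjusted cost strictly inside (0, unadjusted) whenever f > 0
  set.seed(7)
  for (i in 1:20) {
    a <- birth_adjustment(runif(1, 0.01, 1), runif(1, 0, 0.2), runif(1, 0, 5))
    x <- adjust_birth_cost(12953, a)
    expect_gt(x, 0)
    expect_lt(x, 12953)
  }
})

test_that("cost totals multiply unrounded counts by unit costs per bound", {
  cfg <- base_cfg()
  events <- events_for_rate(2.3)
  tot <- total_costs(events, cfg$costs, "unadjusted")

  expect_equal(tot["birth", "median"], 144903, tolerance = 1e-3)
  expect_equal(tot["birth", "min"], 58955, tolerance = 1e-3)
  expect_equal(tot["birth", "max"], 320660, tolerance = 1e-3)
  # non-zero ectopic cost even though the displayed count is 0
  expect_equal(tot["ectopic", "median"], 702, tolerance = 1e-3)
  expect_equal(events$display$outcomes[["ectopic"]], 0)

  expect_equal(unname(tot["total", ]), unname(colSums(tot[OUTCOME_STATES, ])))
  expect_true(all(tot[, "min"] <= tot[, "median"] &
                    tot[, "median"] <= tot[, "max"]))

  zero <- events_for_rate(0)
  expect_true(all(total_costs(zero, cfg$costs, "unadjusted") == 0))

  expect_error(total_costs(events, cfg$costs[c("birth", "ectopic")],
                           "unadjusted"), "missing cost entries")
  expect_error(total_costs(events, cfg$costs, "adjusted"),
               "requires adjustment")
})

test_that("adjusted totals never exceed unadjusted except on birth-free slices", {
  cfg <- base_cfg()
  events <- events_for_rate(2.3)
  unadj <- total_costs(events, cfg$costs, "unadjusted")
  adj <- total_costs(events, cfg$costs, "adjusted", cfg$adjustment)
  expect_true(all(adj["birth", ] < unadj["birth", ]))
  expect_true(all(adj["total", ] < unadj["total", ]))
  expect_equal(adj[setdiff(OUTCOME_STATES, "birth"), ],
               unadj[setdiff(OUTCOME_STATES, "birth"), ])

  no_birth <- tiny_cfg(outcomes = outcome_distribution(0, 0.7, 0.295, 0.005))
  ev <- events_for_rate(2.3, no_birth)
  expect_equal(
    unname(total_costs(ev, no_birth$costs, "adjusted",
                       no_birth$adjustment)["total", ]),
    unname(total_costs(ev, no_birth$costs, "unadjusted")["total", ]))
})

test_that("evaluate_strategy composes the full pipeline per variant", {
  cfg <- base_cfg()
  inducer <- cfg$strategies[[2]]

  low <- evaluate_strategy(inducer, "low", cfg)
  expect_equal(low$rate, 1.9)
  expect_equal(low$events$display$total_up, 19)

  s1 <- evaluate_strategy(cfg$strategies[[1]], "point", cfg)
  expect_equal(s1$costs_unadjusted["total", "median"], 20682,
               tolerance = 1e-3)

  zero <- evaluate_strategy(strategy_spec("none", 0), "point", cfg)
  expect_equal(zero$events$total_up, 0)
  expect_true(all(zero$costs_unadjusted == 0))
  expect_true(all(zero$costs_adjusted == 0))

  expect_error(evaluate_strategy(cfg$strategies[[1]], "low", cfg),
               "no low rate variant")
})

test_that("cost totals and counts scale linearly", {
  cfg <- base_cfg()
  events <- events_for_rate(2.3)
  doubled_costs <- lapply(cfg$costs, function(cs)
    structure(unclass(cs) * 2, class = "cost_summary"))
  expect_equal(unclass(total_costs(events, doubled_costs, "unadjusted")),
               unclass(total_costs(events, cfg$costs, "unadjusted")) * 2,
               ignore_attr = TRUE)

  big <- tiny_cfg(rate = 2.3, cohort = 2000)
  ev_big <- events_for_rate(2.3, big)
  expect_equal(ev_big$total_up, 2 * events$total_up, tolerance = 1e-12)
  expect_equal(
    unclass(total_costs(ev_big, big$costs, "unadjusted")),
    unclass(total_costs(events, cfg$costs, "unadjusted")) * 2,
    ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("incremental comparison propagates bounds and is antisymmetric", {
  cfg <- base_cfg()
  bundles <- lapply(cfg$strategies, evaluate_strategy_bundle, cfg = cfg)

  inc <- compare_strategies(bundles[[2]], bundles[[1]])
  expect_equal(inc$delta_up, 20)
  expect_equal(inc$adjusted[["median"]], 65146, tolerance = 1e-3)
  expect_equal(inc$unadjusted[["median"]], 136304, tolerance = 1e-3)

  inc23 <- compare_strategies(bundles[[2]], bundles[[3]])
  expect_equal(inc23$delta_up, 7)
  expect_equal(inc23$unadjusted[["min"]], 14309, tolerance = 1e-3)
  expect_equal(inc23$unadjusted[["max"]], 158452, tolerance = 1e-3)

  # self-comparison is all zero
  self <- compare_strategies(bundles[[2]], bundles[[2]])
  expect_equal(self$delta_up, 0)
  expect_equal(unname(self$unadjusted), c(0, 0, 0))
  expect_equal(unname(self$adjusted), c(0, 0, 0))

  # swapping comparator and reference negates every delta
  rev <- compare_strategies(bundles[[1]], bundles[[2]])
  expect_equal(rev$delta_up, -inc$delta_up)
  expect_equal(rev$unadjusted, -inc$unadjusted)
  expect_equal(rev$adjusted, -inc$adjusted)
  expect_equal(rev$delta_up_range[["min"]], -inc$delta_up_range[["min"]])

  # single results are treated as point-only bundles
  single <- compare_strategies(bundles[[2]]$point, bundles[[1]]$point)
  expect_equal(single$delta_up, 20)
})
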