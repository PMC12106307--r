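test_that("time grid derives cycle counts from the horizon", {
  g <- time_grid()
  expect_equal(g$n_cycles, 72L)
  expect_equal(g$cycles_per_year, 12)
  expect_equal(time_grid(horizon_years = 2)$n_cycles, 24L)
  expect_error(time_grid(cycle_length_months = 0.5), "cycle_length")
  expect_error(time_grid(horizon_years = 1, cycle_length_months = 5),
               "whole number")
})

test_that("sparse entries build a row-stochastic matrix via diagonal closure", {
  sts <- gd_states()
  # no events: identity
  tm <- build_transition_matrix(NULL, sts)
  expect_equal(unname(tm$probs), diag(8))

  # everything dies within one cycle
  live <- setdiff(sts, "death")
  all_die <- build_transition_matrix(
    data.frame(from = live, to = "death", prob = 1), sts
  )
  expect_equal(unname(all_die$probs[, "death"]), rep(1, 8))

  # closure fills the diagonal with the remaining mass
  tm2 <- build_transition_matrix(
    data.frame(from = sts[1], to = c(sts[2], "death"), prob = c(0.2, 0.1)),
    sts
  )
  expect_equal(tm2$probs[sts[1], sts[1]], 0.7)
  expect_equal(rowSums(tm2$probs), setNames(rep(1, 8), sts))
})

test_that("malformed entry sets are rejected", {
  sts <- c("A", "B", "death")
  expect_error(
    build_transition_matrix(
      data.frame(from = "A", to = c("death", "B"), prob = c(0.6, 0.5)), sts
    ),
    "over-specified"
  )
  expect_error(
    build_transition_matrix(
      data.frame(from = c("A", "A"), to = c("B", "B"), prob = c(0.1, 0.2)),
      sts
    ),
    "duplicate"
  )
  expect_error(
    build_transition_matrix(
      data.frame(from = "A", to = "C", prob = 0.1), sts
    ),
    "unknown states"
  )
  expect_error(
    build_transition_matrix(
      data.frame(from = "death", to = "A", prob = 0.1), sts
    ),
    "absorbing"
  )
  adj <- gd_adjacency(sts)
  expect_error(
    build_transition_matrix(
      data.frame(from = "B", to = "A", prob = 0.1), sts, adjacency = adj
    ),
    "adjacency"
  )
})

test_that("cohort propagation matches the closed-form geometric decay", {
  grid <- time_grid()
  tm <- two_state_matrix(0.1)
  trace <- run_cohort(tm, c(alive = 1, death = 0), grid)
  expect_equal(unname(trace[, "alive"]), 0.9^(0:72), tolerance = 1e-12)
  expect_equal(rowSums(trace), rep(1, 73), tolerance = 1e-9,
               ignore_attr = TRUE)

  # identity matrix: occupancy constant
  id <- build_transition_matrix(NULL, gd_states())
  init <- c(1, rep(0, 7))
  tr2 <- run_cohort(id, init, grid)
  expect_true(all(apply(tr2, 1, function(r) identical(unname(r), init))))

  # everything absorbed after one cycle
  all_die <- two_state_matrix(1)
  tr3 <- run_cohort(all_die, c(alive = 1, death = 0), grid)
  expect_equal(unname(tr3[2, "death"]), 1)
})

test_that("cohort propagation rejects invalid initial distributions", {
  tm <- two_state_matrix(0.1)
  expect_error(run_cohort(tm, c(0.5, 0.2)), "distribution")
  expect_error(run_cohort(tm, c(1, 0, 0)), "length")
  expect_error(run_cohort(tm, c(alive = 1, elsewhere = 0)), "match")
})

test_that("discount factors follow the end-of-cycle convention", {
  expect_equal(discount_factors(0), rep(1, 72))
  d <- discount_factors(0.05)
  expect_equal(d[12], 1 / 1.05, tolerance = 1e-12)
  expect_equal(d[72], 1.05^-6, tolerance = 1e-12)
  expect_error(discount_factors(-0.01), ">= 0")
})

test_that("accumulation matches an independent per-cycle summation oracle", {
  grid <- time_grid()
  tm <- two_state_matrix(0.1)
  trace <- run_cohort(tm, c(alive = 1, death = 0), grid)
  cost <- c(alive = 1000, death = 0)
  util <- c(alive = 0.86, death = 0)
  for (w in c("half", "end", "start")) {
    for (rate in c(0, 0.05, 0.12)) {
      got <- accumulate_outcomes(trace, cost, util, annual_rate = rate,
                                 grid = grid, weighting = w)
      want <- oracle_totals(unclass(trace), cost, util, rate, weighting = w)
      expect_equal(got$cost, want$cost, tolerance = 1e-9)
      expect_equal(got$qalys, want$qalys, tolerance = 1e-9)
    }
  }
  # oracle equivalence on a three-state short-horizon model
  sts <- c("A", "B", "death")
  tm3 <- build_transition_matrix(
    data.frame(from = c("A", "A", "B"), to = c("B", "death", "death"),
               prob = c(0.3, 0.05, 0.2)), sts
  )
  g3 <- time_grid(horizon_years = 1)
  tr3 <- run_cohort(tm3, c(A = 1, B = 0, death = 0), g3)
  got <- accumulate_outcomes(tr3, c(A = 500, B = 2000, death = 0),
                             c(A = 0.9, B = 0.4, death = 0),
                             annual_rate = 0.05, grid = g3)
  want <- oracle_totals(unclass(tr3), c(500, 2000, 0), c(0.9, 0.4, 0), 0.05)
  expect_equal(got$cost, want$cost, tolerance = 1e-9)
  expect_equal(got$qalys, want$qalys, tolerance = 1e-9)
})

test_that("degenerate rewards and immortal cohorts accumulate exactly", {
  grid <- time_grid()
  tm <- two_state_matrix(0.1)
  trace <- run_cohort(tm, c(alive = 1, death = 0), grid)
  zero <- accumulate_outcomes(trace, c(alive = 0, death = 0),
                              c(alive = 0, death = 0), 0.05, grid)
  expect_equal(zero$cost, 0)
  expect_equal(zero$qalys, 0)

  immortal <- run_cohort(two_state_matrix(0), c(alive = 1, death = 0), grid)
  out <- accumulate_outcomes(immortal, c(alive = 0, death = 0),
                             c(alive = 1, death = 0), 0, grid)
  expect_equal(out$qalys, 6)
})

test_that("half-cycle totals are bracketed by start- and end-weighted totals", {
  grid <- time_grid()
  cost <- c(alive = 1000, death = 0)
  util <- c(alive = 0.86, death = 0)
  set.seed(101)
  for (p in runif(10, 0.01, 0.5)) {
    trace <- run_cohort(two_state_matrix(p), c(alive = 1, death = 0), grid)
    vals <- sapply(c("start", "half", "end"), function(w) {
      unlist(accumulate_outcomes(trace, cost, util, 0.05, grid,
                                 weighting = w))
    })
    expect_true(all(vals[, "half"] >= vals[, "end"] - 1e-12))
    expect_true(all(vals[, "half"] <= vals[, "start"] + 1e-12))
  }
})

test_that("discounted totals are non-increasing in the discount rate", {
  grid <- time_grid()
  trace <- run_cohort(two_state_matrix(0.07), c(alive = 1, death = 0), grid)
  cost <- c(alive = 1000, death = 0)
  util <- c(alive = 0.86, death = 0)
  rates <- c(0, 0.02, 0.05, 0.1, 0.3)
  totals <- t(sapply(rates, function(r) {
    unlist(accumulate_outcomes(trace, cost, util, r, grid))
  }))
  expect_true(all(diff(totals[, "cost"]) <= 0))
  expect_true(all(diff(totals[, "qalys"]) <= 0))
  # upper bound: QALYs never exceed horizon x max utility
  expect_true(all(totals[, "qalys"] <= 6 * 0.86 + 1e-12))
})

test_that("traces conserve mass and death is monotone for random matrices", {
  adj <- gd_adjacency()
  grid <- time_grid()
  init <- c(1, rep(0, 7))
  set.seed(2024)
  for (i in 1:200) {
    tm <- random_structural_matrix(adj, concentration = runif(1, 0.3, 3))
    trace <- run_cohort(tm, init, grid)
    expect_true(max(abs(rowSums(trace) - 1)) < 1e-9)
    expect_true(all(diff(trace[, "death"]) >= -1e-12))
    expect_true(all(trace >= -1e-12 & trace <= 1 + 1e-12))
  }
})

test_that("trace export writes one row per cycle boundary", {
  trace <- run_cohort(two_state_matrix(0.1), c(alive = 1, death = 0),
                      time_grid())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, path)
  got <- read.csv(path)
  expect_equal(names(got), c("cycle", "alive", "death"))
  expect_equal(nrow(got), 73)
  expect_equal(got$alive, unname(trace[, "alive"]), tolerance = 1e-12)
  expect_equal(got$cycle, 0:72)
})
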