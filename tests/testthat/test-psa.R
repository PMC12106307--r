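test_that("beta shapes recover the requested mean and standard error", {
  expect_equal(beta_from_mean_se(0.5, 0.1), c(alpha = 12, beta = 12),
               tolerance = 1e-12)
  ab <- beta_from_mean_se(0.86, 0.086)
  expect_equal(unname(ab), c(13.1400, 2.1391), tolerance = 1e-4)
  # the implied distribution has the requested moments
  for (m in c(0.1, 0.5, 0.86)) {
    ab <- beta_from_mean_se(m, 0.1 * m)
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    expect_equal(a / (a + b), m, tolerance = 1e-12)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), 0.1 * m,
                 tolerance = 1e-12)
  }
  expect_error(beta_from_mean_se(0.5, 0.6), "infeasible")
  expect_error(beta_from_mean_se(1.2, 0.1), "\\(0, 1\\)")
})

test_that("sampled beta draws reproduce the target moments", {
  set.seed(99)
  ab <- beta_from_mean_se(0.86, 0.086)
  x <- rbeta(10000, ab[["alpha"]], ab[["beta"]])
  mc_se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.86), 3 * mc_se)
  # SE of the sample SD for a 3-sigma band
  sd_se <- sd(x) / sqrt(2 * (length(x) - 1))
  expect_lt(abs(sd(x) - 0.086), 3 * sd_se)
})

test_that("cost draws are normal truncated at zero by rejection", {
  set.seed(5)
  x <- rnorm_nonneg(1000, 21870, 2187)
  expect_lt(abs(mean(x) - 21870), 3 * 2187 / sqrt(1000))
  y <- rnorm_nonneg(500, 0, 1)
  expect_true(all(y >= 0))
  expect_error(rnorm_nonneg(10, 1, 0), "> 0")
})

test_that("zero variance reproduces the base parameter set and base case", {
  params <- fixture_params()
  expect_identical(sample_parameter_set(params, se_fraction = 0), params)
  draws <- run_psa(params, n_draws = 1, seed = 1, se_fraction = 0)
  base <- run_base_case(params)
  expect_equal(draws$cost_mono, base$arms$cost[1], tolerance = 1e-12)
  expect_equal(draws$qalys_combo, base$arms$qalys[2], tolerance = 1e-12)
  expect_equal(draws$incr_cost, base$incr_cost, tolerance = 1e-12)
})

test_that("sampled parameter sets are valid and arm-shared values coincide", {
  params <- fixture_params()
  set.seed(31)
  for (i in 1:100) {
    sp <- sample_parameter_set(params, sample_transitions = TRUE)
    live <- setdiff(sp$states, "death")
    expect_true(all(sp$utilities[live] > 0 & sp$utilities[live] < 1))
    expect_equal(unname(sp$utilities["death"]), 0)
    expect_true(all(sp$drugs$imiglucerase$pack_price > 0,
                    sp$drugs$ambroxol$pack_price > 0))
    for (arm in c("mono", "combo")) {
      tm <- build_transition_matrix(sp$transitions[[arm]], sp$states,
                                    sp$adjacency)
      expect_true(max(abs(rowSums(tm$probs) - 1)) < 1e-9)
    }
  }
})

test_that("seeded PSA runs are reproducible draw for draw", {
  params <- fixture_params()
  a <- run_psa(params, n_draws = 25, seed = 123)
  b <- run_psa(params, n_draws = 25, seed = 123)
  expect_identical(a, b)
  c <- run_psa(params, n_draws = 25, seed = 124)
  expect_false(isTRUE(all.equal(a$incr_cost, c$incr_cost)))
})

test_that("PSA means agree with the deterministic base case", {
  params <- fixture_params()
  base <- run_base_case(params)
  draws <- run_psa(params, n_draws = 400, seed = 2)
  n <- nrow(draws)
  se_cost <- sd(draws$incr_cost) / sqrt(n)
  se_q <- sd(draws$incr_qalys) / sqrt(n)
  expect_lt(abs(mean(draws$incr_cost) - base$incr_cost), 3 * se_cost)
  expect_lt(abs(mean(draws$incr_qalys) - base$incr_qalys), 3 * se_q)
})

test_that("the acceptability curve is the NMB exceedance fraction", {
  draws <- structure(
    data.frame(incr_cost = c(100, 300, 200), incr_qalys = c(1, 1, -1)),
    class = c("psa_draws", "data.frame")
  )
  expect_equal(ceac(draws, 150)$prob_combo_ce, 1 / 3)
  expect_equal(ceac(draws, 0)$prob_combo_ce, 0)
  pos <- structure(
    data.frame(incr_cost = c(100, 300, 200), incr_qalys = c(1, 2, 1)),
    class = c("psa_draws", "data.frame")
  )
  expect_equal(ceac(pos, 1e9)$prob_combo_ce, 1)
  # strict inequality: a draw sitting exactly on the threshold does not count
  max_icer <- max(pos$incr_cost / pos$incr_qalys)
  expect_equal(ceac(pos, max_icer)$prob_combo_ce, 2 / 3)
  expect_equal(ceac(pos, max_icer + 1e-6)$prob_combo_ce, 1)
  expect_error(ceac(pos[0, ], 100), "draw")
})

test_that("the CEAC is non-decreasing in WTP when every draw gains QALYs", {
  params <- fixture_params()
  draws <- run_psa(params, n_draws = 200, seed = 8)
  expect_true(all(draws$incr_qalys > 0))
  curve <- ceac(draws, default_wtp_grid(params))
  expect_equal(nrow(curve), 21)
  expect_true(all(diff(curve$prob_combo_ce) >= 0))
})

test_that("plane summaries count quadrants and fit a covariance ellipse", {
  ne <- structure(
    data.frame(incr_cost = c(10, 20, 30, 40), incr_qalys = c(1, 2, 1, 3)),
    class = c("psa_draws", "data.frame")
  )
  s <- ce_plane_summary(ne)
  expect_equal(unname(s$quadrants), c(4, 0, 0, 0))
  expect_equal(sum(s$quadrants), nrow(ne))
  expect_error(ce_plane_summary(ne[1:2, ]), "at least 3")

  mixed <- structure(
    data.frame(incr_cost = c(10, 5, -3), incr_qalys = c(1, -2, 0.5)),
    class = c("psa_draws", "data.frame")
  )
  expect_equal(unname(ce_plane_summary(mixed)$quadrants), c(1, 1, 1, 0))

  flat <- structure(
    data.frame(incr_cost = c(1, 1, 1), incr_qalys = c(2, 2, 2)),
    class = c("psa_draws", "data.frame")
  )
  expect_warning(s2 <- ce_plane_summary(flat), "degenerate")
  expect_null(s2$ellipse)
})

test_that("an isotropic cloud yields a near-circular confidence ellipse", {
  set.seed(17)
  iso <- structure(
    data.frame(incr_cost = rnorm(2000), incr_qalys = rnorm(2000)),
    class = c("psa_draws", "data.frame")
  )
  s <- ce_plane_summary(iso)
  expect_lt(abs(s$ellipse$axes[1] / s$ellipse$axes[2] - 1), 0.15)
  expect_equal(unname(s$ellipse$axes[1]), sqrt(qchisq(0.95, 2)),
               tolerance = 0.1)
})

test_that("PSA and CEAC exports round-trip through CSV", {
  params <- fixture_params()
  draws <- run_psa(params, n_draws = 5, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_psa_csv(draws, p1)
  got <- read.csv(p1)
  expect_equal(names(got),
               c("draw", "cost_mono", "qalys_mono", "cost_combo",
                 "qalys_combo", "incr_cost", "incr_qalys"))
  expect_equal(got$incr_cost, draws$incr_cost, tolerance = 1e-12)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ceac_csv(ceac(draws, c(89358, 268074)), p2)
  expect_equal(names(read.csv(p2)), c("wtp", "prob_combo_ce"))
})
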