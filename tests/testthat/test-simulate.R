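test_that("cluster effects: degenerate components return the mean exactly", {
  set.seed(1)
  ab <- draw_cluster_effects(make_covariance(1), c(log(6.61), log(0.32)), 50)
  expect_equal(unname(ab[, "b"]), rep(log(0.32), 50))  # zero period variance
  expect_gt(stats::sd(ab[, "a"]), 0)

  ab0 <- draw_cluster_effects(matrix(0, 2, 2), c(1.5, -0.5), 10)
  expect_equal(unname(ab0[, "a"]), rep(1.5, 10))
  expect_equal(unname(ab0[, "b"]), rep(-0.5, 10))
})

test_that("cluster effects reproduce the scenario-4 covariance in large samples", {
  set.seed(42)
  ab <- draw_cluster_effects(make_covariance(4), c(log(6.61), log(0.32)), 1e5)
  expect_equal(unname(stats::cov(ab)), matrix(c(1.81, -0.94, -0.94, 1.89), 2, 2),
               tolerance = 0.05 / 1.81)
  expect_equal(mean(ab[, "a"]), log(6.61), tolerance = 0.02)
  expect_error(draw_cluster_effects(matrix(c(1, 2, 2, 1), 2, 2), c(0, 0), 5),
               "positive semidefinite")
})

test_that("varying intervention effects inflate period-2 between-cluster variance", {
  # treated clusters carry the extra independent intervention-effect variance
  set.seed(7)
  n <- 1e5
  ab <- draw_cluster_effects(make_covariance(4), c(log(6.61), log(0.32)), n)
  theta <- draw_intervention_effects(intervention_scenario("varying"), rep(2L, n))
  lo_untreated <- ab[, "a"] + ab[, "b"]
  lo_treated <- lo_untreated + theta
  expect_equal(stats::var(lo_treated) - stats::var(lo_untreated), 0.3,
               tolerance = 0.05 / 0.3)
  # independence of theta from the (intercept, period) pair
  expect_lt(abs(stats::cor(theta, ab[, "a"])), 0.02)
})

test_that("intervention effects: common is exact, study 2 overrides group 2", {
  groups <- rep(1:3, each = 4)
  common <- draw_intervention_effects(intervention_scenario("common"), groups)
  expect_equal(common, rep(0.41, 12))
  expect_equal(exp(mean(common)), 1.5, tolerance = 0.005)  # geometric mean OR

  null_eff <- draw_intervention_effects(
    intervention_scenario("common", mean_log_or = 0), groups)
  expect_equal(null_eff, rep(0, 12))

  s2 <- intervention_scenario("common", group2_mean_log_or = 1.5)
  th <- draw_intervention_effects(s2, groups)
  expect_equal(th[groups == 1], rep(0.41, 4))
  expect_equal(th[groups == 2], rep(1.5, 4))

  # dispersion readings: variance (default) vs sd
  set.seed(11)
  v1 <- draw_intervention_effects(intervention_scenario("varying"), rep(1L, 2e4))
  expect_equal(stats::var(v1), 0.3, tolerance = 0.02)
  set.seed(11)
  v2 <- draw_intervention_effects(
    intervention_scenario("varying", dispersion_is = "sd"), rep(1L, 2e4))
  expect_equal(stats::sd(v2), 0.3, tolerance = 0.02)
})

test_that("cluster sizes are rounded log-normals floored at one", {
  # with zero log-scale SD every size is round(exp(6.9)) = 992
  d0 <- trial_design(size_log_sd = 0)
  expect_equal(draw_cluster_sizes(d0, 5), rep(992L, 5))

  set.seed(3)
  sizes <- draw_cluster_sizes(trial_design(), 2e4)
  expect_equal(exp(mean(log(sizes))), 992, tolerance = 0.02)
  expect_true(all(sizes >= 1))

  tiny <- trial_design(size_log_mean = -2, size_log_sd = 1)
  expect_true(all(draw_cluster_sizes(tiny, 1000) >= 1))
})

test_that("a simulated trial has the stepped wedge structure", {
  tr <- simulate_trial(scenario_spec(3, "varying"), seed = 5)
  rec <- tr$records
  expect_equal(nrow(rec), 150)
  expect_equal(length(unique(rec$cluster_id)), 75)
  expect_true(all(table(rec$cluster_id) == 2))
  expect_true(all(rec$n_events >= 0 & rec$n_events <= rec$n_obs))
  expect_equal(rec$treated, treatment_indicator(rec$group, rec$period))
  expect_equal(unique(rec$group[rec$cluster_id <= 25]), 1L)
  expect_equal(unique(rec$group[rec$cluster_id > 50]), 3L)
  # truth block carries the realized effects
  expect_length(tr$truth$a, 75)
  expect_length(tr$truth$theta, 75)
})

test_that("the seed-to-trial map is a pure function", {
  spec <- scenario_spec(4, "varying")
  t1 <- simulate_trial(spec, 99)
  t2 <- simulate_trial(spec, 99)
  t3 <- simulate_trial(spec, 100)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$truth$theta, t2$truth$theta)
  expect_false(identical(t1$records$n_events, t3$records$n_events))
})

test_that("degenerate variances and huge sizes pin the marginal log-odds", {
  # all variances zero, null effect, one million observations per
  # cluster-period: the empirical log-odds must sit on the generative means
  des <- trial_design(size_log_mean = log(1e6), size_log_sd = 0)
  spec <- scenario_spec(period_scenario(1), intervention_scenario("common", 0),
                        effect = 0, design = des)
  spec$period_scenario$sigma_u2 <- 0  # fully degenerate cluster law
  tr <- simulate_trial(spec, 8)
  rec <- tr$records
  lo <- function(p) {
    sub <- rec[rec$period == p, ]
    log(sum(sub$n_events) / (sum(sub$n_obs) - sum(sub$n_events)))
  }
  expect_equal(lo(1), log(6.61), tolerance = 0.01)
  expect_equal(lo(2), log(6.61 * 0.32), tolerance = 0.01)
  # odds 2.12 in period 2, proportion ~68%
  expect_equal(exp(lo(2)), 2.12, tolerance = 0.01)
})

test_that("trial CSV round-trips and the truth sidecar is valid JSON", {
  tr <- simulate_trial(scenario_spec(2, "common"), 17)
  csv <- file.path(tempdir(), "trial.csv")
  write_trial_data(tr, csv)
  back <- read_trial_data(csv)
  expect_equal(back$records, tr$records)
  truth <- jsonlite::read_json(file.path(tempdir(), "trial.truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 17)
  expect_equal(truth$period_scenario, 2)
  expect_equal(truth$theta, unname(tr$truth$theta))
  unlink(c(csv, file.path(tempdir(), "trial.truth.json")))
})
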