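test_that("cluster marginal log-likelihood matches dense brute-force quadrature", {
  rec <- one_cluster_records()
  fixed <- c(1.6, -0.9, 0.4)

  # 1-D random intercept, a few variance values (absolute 1e-6 agreement)
  for (s2 in c(0.25, 1.81)) {
    ours <- cluster_marginal_loglik(fixed, matrix(s2, 1, 1), rec, "standard")
    expect_lt(abs(ours - brute_loglik_1d(fixed, s2, rec)), 1e-6)
  }

  # 2-D random period and random intervention with correlated effects; a
  # small-count cluster is the least-Gaussian case, so the order knob is
  # raised above the large-count default
  Sig <- matrix(c(1.2, -0.5, -0.5, 0.9), 2, 2)
  for (fid in c("random_period", "random_intervention")) {
    ours <- cluster_marginal_loglik(fixed, Sig, rec, fid, quad_order = 11)
    expect_lt(abs(ours - brute_loglik_2d(fixed, Sig, rec, fid)), 1e-6)
  }

  # several-cluster dataset: contributions are additive over clusters
  rec2 <- one_cluster_records(40, 31, 28, 15, group = 3L)
  rec2$cluster_id <- 2L
  ll_sep <- cluster_marginal_loglik(fixed, Sig, rec, "random_period",
                                    quad_order = 11) +
    cluster_marginal_loglik(fixed, Sig, rec2, "random_period",
                            quad_order = 11)
  oracle2 <- brute_loglik_2d(fixed, Sig, rec, "random_period") +
    brute_loglik_2d(fixed, Sig, rec2, "random_period")
  expect_lt(abs(ll_sep - oracle2), 2e-6)
})

test_that("a vanishing random-effect variance recovers the fixed-effect likelihood", {
  rec <- one_cluster_records()
  fixed <- c(1.9, -1.1, 0.41)
  eta <- fixed[1] + fixed[2] * (rec$period == 2) + fixed[3] * rec$treated
  fixed_ll <- sum(dbinom(rec$n_events, rec$n_obs, plogis(eta), log = TRUE))
  ours1 <- cluster_marginal_loglik(fixed, matrix(1e-12, 1, 1), rec, "standard")
  expect_equal(ours1, fixed_ll, tolerance = 1e-6)
  ours2 <- cluster_marginal_loglik(fixed, diag(1e-12, 2), rec, "random_period")
  expect_equal(ours2, fixed_ll, tolerance = 1e-6)
})

test_that("aggregated counts are sufficient: splitting a record shifts only the binomial constant", {
  rec <- one_cluster_records(30, 24, 35, 20)
  split <- rec[c(1, 1, 2), ]
  split$n_obs <- c(14, 16, 35)
  split$n_events <- c(11, 13, 20)
  fixed <- c(1.6, -0.9, 0.4)
  Sig <- matrix(c(1.2, -0.5, -0.5, 0.9), 2, 2)
  for (fid in c("standard", "random_period")) {
    S <- if (fid == "standard") matrix(1.2, 1, 1) else Sig
    ll_agg <- cluster_marginal_loglik(fixed, S, rec, fid)
    ll_split <- cluster_marginal_loglik(fixed, S, split, fid)
    expect_equal(ll_agg - lchoose_sum(rec), ll_split - lchoose_sum(split),
                 tolerance = 1e-9)
  }
})

test_that("fit_glmm agrees with an independent glmer fit", {
  skip_if_not_installed("lme4")
  tr <- simulate_trial(scenario_spec(3, "common"), 42)
  d <- tr$records
  d$z <- as.numeric(d$period == 2)

  f_std <- fit_glmm(tr, "standard")
  g_std <- lme4::glmer(cbind(n_events, n_obs - n_events) ~ z + treated +
                         (1 | cluster_id),
                       data = d, family = binomial, nAGQ = 9)
  expect_equal(unname(f_std$estimates), unname(lme4::fixef(g_std)),
               tolerance = 1e-3)
  expect_equal(unname(f_std$varcomp[1, 1]),
               unname(as.numeric(lme4::VarCorr(g_std)$cluster_id)),
               tolerance = 1e-2)
  # glmer with nAGQ = 1 reports the full log-likelihood, constants included
  g_lap <- lme4::glmer(cbind(n_events, n_obs - n_events) ~ z + treated +
                         (1 | cluster_id), data = d, family = binomial)
  expect_equal(f_std$loglik, as.numeric(stats::logLik(g_lap)), tolerance = 1e-4)

  f_rp <- fit_glmm(tr, "random_period")
  g_rp <- lme4::glmer(cbind(n_events, n_obs - n_events) ~ z + treated +
                        (1 + z | cluster_id), data = d, family = binomial)
  expect_equal(unname(f_rp$estimates), unname(lme4::fixef(g_rp)),
               tolerance = 5e-3)
  expect_equal(unname(f_rp$varcomp),
               unname(matrix(as.numeric(lme4::VarCorr(g_rp)$cluster_id), 2, 2)),
               tolerance = 2e-2)
  # our tensor AGQ must not fall below glmer's Laplace approximation
  expect_gte(f_rp$loglik, as.numeric(stats::logLik(g_rp)) - 1e-3)
})

test_that("estimates are invariant to disaggregating every cluster-period", {
  tr <- simulate_trial(scenario_spec(1, "common",
                                     design = small_design()), 12)
  rec <- tr$records
  half <- rec
  half$n_obs <- rec$n_obs %/% 2
  half$n_events <- pmin(rec$n_events %/% 2, half$n_obs)
  rest <- rec
  rest$n_obs <- rec$n_obs - half$n_obs
  rest$n_events <- rec$n_events - half$n_events
  split <- rbind(half, rest)
  f1 <- fit_glmm(rec, "standard")
  f2 <- fit_glmm(split, "standard")
  expect_equal(f1$estimates, f2$estimates, tolerance = 5e-4)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-3)
})

test_that("the random period likelihood nests the standard one", {
  for (seed in 1:3) {
    tr <- simulate_trial(scenario_spec(3, "common", design = small_design()),
                         seed)
    f_std <- fit_glmm(tr, "standard")
    f_rp <- fit_glmm(tr, "random_period")
    expect_gte(f_rp$loglik, f_std$loglik - 1e-4)
  }
})

test_that("theta is flagged unidentifiable on all-treated data", {
  tr <- simulate_trial(scenario_spec(1, "common"), 3)
  treated_only <- tr$records[tr$records$treated == 1, ]
  expect_error(fit_glmm(treated_only, "standard"), "not identifiable")
})

test_that("fitting a truly common period effect drives the period variance to the boundary", {
  hits <- 0L
  for (seed in 1:8) {
    tr <- simulate_trial(scenario_spec(1, "common", design = small_design()),
                         seed + 100)
    f <- fit_glmm(tr, "random_period")
    if (f$boundary || f$varcomp[2, 2] < 1e-3) hits <- hits + 1L
  }
  expect_gte(hits, 1L)
})

test_that("Wald intervals and p-values follow the normal reference", {
  fit <- fake_fit(est = 0.41, se = 0.1)
  ci <- wald_interval(fit, "intervention", 0.95)
  expect_equal(unname(ci), c(0.41 - qnorm(0.975) * 0.1,
                             0.41 + qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(unname(round(ci, 3)), c(0.214, 0.606))
  wider <- wald_interval(fit, "intervention", 0.999)
  expect_lt(wider[1], ci[1])
  expect_gt(wider[2], ci[2])

  expect_equal(wald_pvalue(fake_fit(est = 0, se = 0.3)), 1)
  expect_lt(wald_pvalue(fake_fit(est = 0.5, se = 0.1)), 0.001)

  bad <- fake_fit(converged = FALSE)
  expect_error(wald_interval(bad), "converged")
  expect_error(wald_pvalue(bad), "converged")
})

test_that("the variance-component LRT uses the 50:50 chi-square mixture", {
  red <- fake_fit(loglik = -100)
  full0 <- fake_fit(loglik = -100)
  full0$form <- model_form("random_period")
  expect_equal(lrt_variance_component(full0, red), 1)

  lr_p <- function(lr) {
    full <- fake_fit(loglik = -100 + lr / 2)
    full$form <- model_form("random_period")
    lrt_variance_component(full, red)
  }
  expect_equal(lr_p(3), 0.5 * pchisq(3, 1, lower.tail = FALSE) +
                 0.5 * pchisq(3, 2, lower.tail = FALSE))
  expect_gt(lr_p(2), lr_p(5))  # p decreases as the LR grows

  worse <- fake_fit(loglik = -105)
  worse$form <- model_form("random_period")
  expect_error(lrt_variance_component(worse, red), "failure")
  expect_error(lrt_variance_component(red, red), "reduced model")
})

test_that("the LRT detects a strongly varying period effect", {
  tr <- simulate_trial(scenario_spec(4, "common", design = small_design()), 21)
  f_std <- fit_glmm(tr, "standard")
  f_rp <- fit_glmm(tr, "random_period")
  expect_lt(lrt_variance_component(f_rp, f_std), 0.001)
})
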