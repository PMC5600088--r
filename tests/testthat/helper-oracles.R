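# Brute-force dense-grid quadrature oracles for the marginal likelihood of a
# single cluster, independent of the package's adaptive Gauss-Hermite path.
# Integration is over the random-effect scale r ~ N(0, Sigma) on a wide
# trapezoid grid.

record_eta <- function(fixed, records, r, form_id) {
  z <- as.numeric(records$period == 2)
  x <- as.numeric(records$treated)
  t_j <- if (form_id == "random_intervention") x else z
  if (length(r) == 1L) {
    fixed[1] + fixed[2] * z + fixed[3] * x + r
  } else {
    fixed[1] + fixed[2] * z + fixed[3] * x + r[1] + r[2] * t_j
  }
}

brute_loglik_1d <- function(fixed, sigma2, records, npts = 20001, width = 10) {
  s <- sqrt(sigma2)
  u <- seq(-width * s, width * s, length.out = npts)
  lint <- dnorm(u, 0, s, log = TRUE)
  for (j in seq_len(nrow(records))) {
    eta <- record_eta(fixed, records[j, , drop = FALSE], 0, "standard") + u
    lint <- lint + dbinom(records$n_events[j], records$n_obs[j],
                          plogis(eta), log = TRUE)
  }
  m <- max(lint)
  m + log(sum(exp(lint - m)) * (u[2] - u[1]))
}

brute_loglik_2d <- function(fixed, Sigma, records, form_id, npts = 401,
                            width = 8) {
  s1 <- sqrt(Sigma[1, 1]); s2 <- sqrt(Sigma[2, 2])
  u <- seq(-width * s1, width * s1, length.out = npts)
  v <- seq(-width * s2, width * s2, length.out = npts)
  grid <- expand.grid(u = u, v = v)
  Sinv <- solve(Sigma)
  quad <- Sinv[1, 1] * grid$u^2 + 2 * Sinv[1, 2] * grid$u * grid$v +
    Sinv[2, 2] * grid$v^2
  lint <- -0.5 * quad - log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1]
  z <- as.numeric(records$period == 2)
  x <- as.numeric(records$treated)
  t_j <- if (form_id == "random_intervention") x else z
  for (j in seq_len(nrow(records))) {
    eta <- fixed[1] + fixed[2] * z[j] + fixed[3] * x[j] + grid$u + grid$v * t_j[j]
    lint <- lint + dbinom(records$n_events[j], records$n_obs[j],
                          plogis(eta), log = TRUE)
  }
  m <- max(lint)
  m + log(sum(exp(lint - m)) * (u[2] - u[1]) * (v[2] - v[1]))
}

lchoose_sum <- function(records) sum(lchoose(records$n_obs, records$n_events))

# a single-cluster fixture: two periods of one treated-in-period-2 cluster
one_cluster_records <- function(n1 = 30, y1 = 24, n2 = 35, y2 = 20,
                                group = 2L) {
  data.frame(cluster_id = 1L, group = group, period = 1:2,
             treated = treatment_indicator(group, 1:2),
             n_obs = c(n1, n2), n_events = c(y1, y2))
}

# a reduced-size design for fast fitting tests: 3 x 8 clusters, cluster
# periods of a few dozen observations
small_design <- function() {
  trial_design(clusters_per_group = 8L, size_log_mean = log(80),
               size_log_sd = 0.3)
}

fake_fit <- function(est = 0.41, se = 0.1, converged = TRUE,
                     boundary = FALSE, loglik = -100, vc = matrix(1, 1, 1)) {
  structure(list(
    estimates = c(intercept = 1.9, period = -1.1, intervention = est),
    std_errors = c(intercept = 0.2, period = 0.2, intervention = se),
    varcomp = vc, loglik = loglik, converged = converged,
    boundary = boundary, n_iter = 10L, form = model_form("standard")),
    class = "swt_fit")
}
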