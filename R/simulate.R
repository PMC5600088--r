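#' Draw per-cluster (intercept, period-effect) pairs
#'
#' Cluster-level period-1 control log-odds `a_i` and period-effect log odds
#' ratios `b_i` are drawn jointly from a bivariate normal law. Degenerate
#' (zero-variance) components return the mean exactly, so a common period
#' effect is literally common.
#'
#' @param cov 2x2 positive semidefinite covariance matrix
#' @param means length-2 vector `(mu, beta)` of the cluster-level means
#' @param n_clusters number of clusters to draw
#' @return matrix with `n_clusters` rows and columns `a` and `b`
#' @export
draw_cluster_effects <- function(cov, means, n_clusters) {
  stopifnot(is.matrix(cov), all(dim(cov) == 2L), length(means) == 2L,
            n_clusters >= 1L)
  if (abs(cov[1, 2] - cov[2, 1]) > 1e-12) stop("covariance matrix not symmetric")
  eg <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("covariance matrix is not positive semidefinite")
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2L)
  zmat <- matrix(stats::rnorm(2L * n_clusters), nrow = 2L)
  out <- t(means + L %*% zmat)
  colnames(out) <- c("a", "b")
  out
}

group_mean_log_or <- function(intervention, group) {
  means <- rep(intervention$mean_log_or, length(group))
  if (!is.null(intervention$group2_mean_log_or))
    means[group == 2L] <- intervention$group2_mean_log_or
  means
}

#' Draw per-cluster intervention effects
#'
#' Common effects equal the cluster's group mean exactly; varying effects are
#' drawn from a normal law around the group mean, independently across
#' clusters and independently of the cluster's (intercept, period) pair.
#'
#' @param intervention a `swt_intervention_scenario`
#' @param groups per-cluster group labels in 1..3
#' @return numeric vector of per-cluster intervention log odds ratios
#' @export
draw_intervention_effects <- function(intervention, groups) {
  stopifnot(inherits(intervention, "swt_intervention_scenario"),
            all(groups %in% 1:3))
  means <- group_mean_log_or(intervention, groups)
  if (intervention$kind == "common") return(means)
  sd <- if (intervention$dispersion_is == "variance")
    sqrt(intervention$dispersion) else intervention$dispersion
  stats::rnorm(length(groups), mean = means, sd = sd)
}

#' Draw cluster-period sizes
#'
#' Sizes are log-normal: `round(exp(N(size_log_mean, size_log_sd)))`,
#' floored at 1. A fresh size is drawn for every cluster-period, so the two
#' periods of a cluster differ in size.
#'
#' @param design a `swt_design`
#' @param n_draws number of sizes to draw
#' @return positive integer vector
#' @export
draw_cluster_sizes <- function(design, n_draws) {
  stopifnot(inherits(design, "swt_design"), n_draws >= 1L)
  raw <- round(exp(stats::rnorm(n_draws, design$size_log_mean,
                                design$size_log_sd)))
  as.integer(pmax(raw, 1))
}

#' Simulate one stepped wedge trial
#'
#' For cluster i in period j the outcome log-odds is
#' `a_i + b_i * Z_j + theta_i * X_ij` with `Z_j` the period-2 indicator and
#' `X_ij` the treatment indicator; event counts are binomial given the
#' cluster-period size, independent within cluster-periods (cross-sectional
#' sampling). The returned object keeps the realized per-cluster effects so
#' parameter-recovery checks can compare estimates against the truth.
#'
#' @param spec a `swt_scenario_spec`
#' @param seed integer seed; the map from seed to data is a pure function
#' @return an object of class `swt_trial`: a list with `records` (data frame
#'   with one row per cluster-period: `cluster_id`, `group`, `period`,
#'   `treated`, `n_obs`, `n_events`) and `truth` (the scenario, the seed, and the
#'   realized `a`, `b`, `theta` per cluster)
#' @export
simulate_trial <- function(spec, seed) {
  stopifnot(inherits(spec, "swt_scenario_spec"))
  des <- spec$design
  n_cl <- des$n_groups * des$clusters_per_group
  set.seed(as.integer(seed))

  # cluster ids are group-blocked: 1-25 group 1, 26-50 group 2, 51-75 group 3
  group <- rep(seq_len(des$n_groups), each = des$clusters_per_group)
  cov <- make_covariance(spec$period_scenario)
  ab <- draw_cluster_effects(cov, c(des$mu, des$beta), n_cl)
  theta <- draw_intervention_effects(spec$intervention, group)

  records <- data.frame(
    cluster_id = rep(seq_len(n_cl), times = des$n_periods),
    group = rep(group, times = des$n_periods),
    period = rep(seq_len(des$n_periods), each = n_cl)
  )
  records <- records[order(records$cluster_id, records$period), ]
  rownames(records) <- NULL
  records$treated <- treatment_indicator(records$group, records$period)
  records$n_obs <- draw_cluster_sizes(des, nrow(records))
  z <- as.numeric(records$period == 2L)
  eta <- ab[records$cluster_id, "a"] + ab[records$cluster_id, "b"] * z +
    theta[records$cluster_id] * records$treated
  records$n_events <- stats::rbinom(nrow(records), records$n_obs,
                                    stats::plogis(eta))

  trial <- list(
    records = records,
    truth = list(spec = spec, seed = as.integer(seed),
                 a = ab[, "a"], b = ab[, "b"], theta = theta)
  )
  class(trial) <- "swt_trial"
  trial
}

#' @export
print.swt_trial <- function(x, ...) {
  cat(sprintf("Simulated stepped wedge trial: %d cluster-period records, %d clusters\n",
              nrow(x$records), length(unique(x$records$cluster_id))))
  cat(sprintf("  events/persons: %d/%d (crude proportion %.3f)\n",
              sum(x$records$n_events), sum(x$records$n_obs),
              sum(x$records$n_events) / sum(x$records$n_obs)))
  invisible(x)
}

#' Write / read a simulated trial
#'
#' The cluster-period table is written as CSV with header
#' `cluster_id,group,period,treated,n_obs,n_events`; the generative truth
#' (per-cluster effects, scenario echo, seed) goes to a JSON sidecar.
#'
#' @param trial a `swt_trial`
#' @param path CSV path
#' @param truth_path optional JSON sidecar path (default: `path` with
#'   extension `.truth.json`); `NULL` skips the sidecar
#' @return `path`, invisibly
#' @export
write_trial_data <- function(trial, path,
                             truth_path = paste0(sub("\\.csv$", "", path),
                                                 ".truth.json")) {
  stopifnot(inherits(trial, "swt_trial"))
  utils::write.csv(trial$records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    tr <- trial$truth
    payload <- list(
      seed = tr$seed,
      period_scenario = tr$spec$period_scenario$id,
      intervention = tr$spec$intervention$kind,
      mean_log_or = tr$spec$intervention$mean_log_or,
      study = tr$spec$study,
      a = tr$a, b = tr$b, theta = tr$theta
    )
    jsonlite::write_json(payload, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  records <- utils::read.csv(path)
  needed <- c("cluster_id", "group", "period", "treated", "n_obs", "n_events")
  if (!all(needed %in% names(records)))
    stop("trial CSV must have columns ", paste(needed, collapse = ", "))
  trial <- list(records = records[, needed], truth = NULL)
  class(trial) <- "swt_trial"
  trial
}
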