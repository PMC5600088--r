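#' Trial design constants for the two-period, three-group stepped wedge layout
#'
#' The design has three groups of clusters followed for two periods: group 1
#' is under intervention in both periods, group 2 crosses over at the start of
#' period 2, and group 3 never receives the intervention (an incomplete
#' stepped wedge). Defaults emulate a large school-based trial:
#' 25 clusters per group (75 in total), mean control-condition odds 6.61 in
#' period 1, period-effect odds ratio 0.32, and cluster-period sizes drawn
#' log-normally with log-scale mean 6.9 and SD 0.74.
#'
#' @param n_groups number of randomised groups (fixed design: 3)
#' @param clusters_per_group clusters per group (default 25)
#' @param n_periods number of time periods (fixed design: 2)
#' @param mu control-condition log-odds of the outcome in period 1
#'   (default `log(6.61)`)
#' @param beta period-effect log odds ratio, period 2 vs period 1
#'   (default `log(0.32)`)
#' @param size_log_mean,size_log_sd parameters (natural-log scale) of the
#'   log-normal law for cluster-period sizes
#' @return an object of class `swt_design`
#' @export
trial_design <- function(n_groups = 3L, clusters_per_group = 25L,
                         n_periods = 2L,
                         mu = log(6.61), beta = log(0.32),
                         size_log_mean = 6.9, size_log_sd = 0.74) {
  stopifnot(n_groups == 3L, n_periods == 2L, clusters_per_group >= 1L,
            size_log_sd >= 0)
  design <- list(
    n_groups = as.integer(n_groups),
    clusters_per_group = as.integer(clusters_per_group),
    n_periods = as.integer(n_periods),
    mu = mu, beta = beta,
    size_log_mean = size_log_mean, size_log_sd = size_log_sd
  )
  class(design) <- "swt_design"
  design
}

#' Treatment indicator of the stepped wedge layout
#'
#' Group 1 is treated in both periods, group 2 in period 2 only, group 3
#' never. Treatment is monotone within each group: once a group crosses to
#' the intervention it stays under it.
#'
#' @param group group label(s) in 1..3
#' @param period period label(s) in 1..2
#' @return 0/1 integer vector
#' @export
treatment_indicator <- function(group, period) {
  stopifnot(all(group %in% 1:3), all(period %in% 1:2))
  as.integer(group == 1L | (group == 2L & period == 2L))
}

#' Between-cluster covariance scenarios for (intercept, period effect)
#'
#' Four scenarios for the joint law of a cluster's period-1 control log-odds
#' and its period-effect log odds ratio: (1) common period effect with high
#' between-cluster variability (intercept variance 1.81), (2) common period
#' effect with low variability (0.25), (3) period effect varying between
#' clusters with decreasing variability (variances 1.81 and 1.89, covariance
#' -1.72, so period-2 variance collapses to 0.26), and (4) varying period
#' effect with stable variability (covariance -0.94, period-2 variance 1.82).
#'
#' @param id scenario number, 1 to 4
#' @return an object of class `swt_period_scenario` with fields `id`,
#'   `sigma_u2`, `sigma_v2`, `sigma_uv`
#' @export
period_scenario <- function(id) {
  if (length(id) != 1L || !id %in% 1:4)
    stop("unknown period scenario id: ", paste(id, collapse = ","))
  params <- switch(as.character(id),
    "1" = c(1.81, 0,    0),
    "2" = c(0.25, 0,    0),
    "3" = c(1.81, 1.89, -1.72),
    "4" = c(1.81, 1.89, -0.94))
  scn <- list(id = as.integer(id), sigma_u2 = params[1],
              sigma_v2 = params[2], sigma_uv = params[3])
  class(scn) <- "swt_period_scenario"
  scn
}

#' Covariance matrix of a period scenario
#'
#' @param scenario a `swt_period_scenario` (or a scenario id 1-4)
#' @return the symmetric 2x2 matrix
#'   `[[sigma_u2, sigma_uv], [sigma_uv, sigma_v2]]`
#' @export
make_covariance <- function(scenario) {
  if (is.numeric(scenario)) scenario <- period_scenario(scenario)
  stopifnot(inherits(scenario, "swt_period_scenario"))
  cov <- matrix(c(scenario$sigma_u2, scenario$sigma_uv,
                  scenario$sigma_uv, scenario$sigma_v2), 2L, 2L)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("period-scenario covariance matrix is not positive semidefinite")
  dimnames(cov) <- list(c("intercept", "period"), c("intercept", "period"))
  cov
}

#' Intervention-effect scenario
#'
#' The intervention log odds ratio is either common to all clusters or drawn
#' per cluster from a normal law centred at the group mean, independently of
#' the (intercept, period-effect) pair. The default effect is log-OR 0.41
#' (odds ratio 1.5); null configurations use 0. The cluster-varying law
#' N(0.41, 0.3) is read with 0.3 as the variance (SD ~ 0.548) to match the
#' usual sigma^2 notation for random effects; set `dispersion_is = "sd"` for
#' the other reading. A study-2 probe of horizontal (within-cluster)
#' comparisons raises the group-2 mean to log-OR 1.5 while group 1 keeps
#' 0.41.
#'
#' @param kind "common" or "varying"
#' @param mean_log_or mean intervention log odds ratio (0.41, or 0 for null)
#' @param dispersion second parameter of the normal law for varying effects
#' @param dispersion_is whether `dispersion` is the "variance" (default) or
#'   the "sd" of the cluster-level law
#' @param group2_mean_log_or optional group-2 override (1.5 in study 2)
#' @return an object of class `swt_intervention_scenario`
#' @export
intervention_scenario <- function(kind = c("common", "varying"),
                                  mean_log_or = 0.41,
                                  dispersion = 0.3,
                                  dispersion_is = c("variance", "sd"),
                                  group2_mean_log_or = NULL) {
  kind <- match.arg(kind)
  dispersion_is <- match.arg(dispersion_is)
  stopifnot(dispersion >= 0)
  scn <- list(kind = kind, mean_log_or = mean_log_or,
              dispersion = dispersion, dispersion_is = dispersion_is,
              group2_mean_log_or = group2_mean_log_or)
  class(scn) <- "swt_intervention_scenario"
  scn
}

#' Full generative configuration for one simulated trial
#'
#' @param period_scenario a `swt_period_scenario` or id 1-4
#' @param intervention a `swt_intervention_scenario`, or "common"/"varying"
#'   to take the defaults
#' @param effect mean intervention log odds ratio (shortcut that overrides
#'   `intervention$mean_log_or`; use 0 for null configurations)
#' @param study 1 for a common group mean, 2 for the horizontal-weight probe
#'   with group-2 mean log-OR 1.5
#' @param design a `swt_design`
#' @return an object of class `swt_scenario_spec`
#' @export
scenario_spec <- function(period_scenario = 1, intervention = "common",
                          effect = 0.41, study = 1L,
                          design = trial_design()) {
  if (is.numeric(period_scenario))
    period_scenario <- swtsim::period_scenario(period_scenario)
  if (is.character(intervention))
    intervention <- intervention_scenario(kind = intervention)
  stopifnot(inherits(period_scenario, "swt_period_scenario"),
            inherits(intervention, "swt_intervention_scenario"),
            inherits(design, "swt_design"),
            study %in% 1:2)
  if (!missing(effect)) intervention$mean_log_or <- effect
  if (study == 2L) {
    if (is.null(intervention$group2_mean_log_or))
      intervention$group2_mean_log_or <- 1.5
    if (intervention$mean_log_or == 0)
      stop("the study-2 horizontal-weight probe has no null configuration")
  }
  spec <- list(design = design, period_scenario = period_scenario,
               intervention = intervention, study = as.integer(study))
  class(spec) <- "swt_scenario_spec"
  spec
}

#' @export
print.swt_scenario_spec <- function(x, ...) {
  cat("Stepped wedge generative scenario\n")
  cat(sprintf("  period scenario %d: var(intercept)=%.2f var(period)=%.2f cov=%.2f\n",
              x$period_scenario$id, x$period_scenario$sigma_u2,
              x$period_scenario$sigma_v2, x$period_scenario$sigma_uv))
  cat(sprintf("  intervention: %s, mean log-OR %.2f%s\n", x$intervention$kind,
              x$intervention$mean_log_or,
              if (x$intervention$kind == "varying")
                sprintf(", %s %.2f", x$intervention$dispersion_is,
                        x$intervention$dispersion) else ""))
  if (x$study == 2L)
    cat(sprintf("  study 2: group-2 mean log-OR %.2f\n",
                x$intervention$group2_mean_log_or))
  cat(sprintf("  %d clusters in %d groups, %d periods\n",
              x$design$n_groups * x$design$clusters_per_group,
              x$design$n_groups, x$design$n_periods))
  invisible(x)
}
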