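#' Percentage bias of intervention-effect estimates
#'
#' `100 * (mean(estimates) - truth) / truth`, computed over converged fits.
#' Undefined for a null truth (use [type1_error()] for null configurations).
#'
#' @param estimates intervention log-OR estimates from converged fits
#' @param truth true (mean) intervention log odds ratio; must be non-zero
#' @return percentage bias
#' @export
percentage_bias <- function(estimates, truth) {
  if (length(estimates) < 1L) stop("no estimates supplied")
  if (truth == 0) stop("percentage bias is undefined for a null truth")
  100 * (mean(estimates) - truth) / truth
}

#' Coverage of confidence intervals
#'
#' Percentage of intervals containing the truth; endpoints count as covered.
#' In cluster-varying effect scenarios the truth is the generative mean
#' log odds ratio.
#'
#' @param intervals two-column matrix (or data frame) of `(lower, upper)`
#'   interval endpoints, one row per replicate, converged fits only
#' @param truth true (mean) intervention log odds ratio
#' @return coverage in percent
#' @export
coverage <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) < 1L) stop("no intervals supplied")
  stopifnot(ncol(intervals) == 2L)
  100 * mean(intervals[, 1] <= truth & truth <= intervals[, 2])
}

#' Type I error rate
#'
#' Percentage of replicates with two-sided p strictly below 0.05, for
#' configurations whose generative mean effect is null (OR = 1).
#'
#' @param pvalues per-replicate p-values for H0: OR = 1, converged fits only
#' @param truth the generative mean log odds ratio; must be 0
#' @param alpha rejection threshold
#' @return rejection rate in percent
#' @export
type1_error <- function(pvalues, truth = 0, alpha = 0.05) {
  if (truth != 0)
    stop("type I error is defined only for null configurations")
  if (length(pvalues) < 1L) stop("no p-values supplied")
  100 * mean(pvalues < alpha)
}

#' Ratios of estimate dispersion and mean standard error between two models
#'
#' @param summary_a,summary_b `swt_scenario_summary` rows (see
#'   [summarize_scenario()]) for the same data configuration fitted with two
#'   different model forms
#' @return named vector `(sd_ratio, se_ratio)` of `a / b` ratios
#' @export
dispersion_and_se_ratios <- function(summary_a, summary_b) {
  if (summary_b$sd_est == 0 || summary_b$mean_se == 0)
    stop("zero dispersion in the denominator summary")
  c(sd_ratio = summary_a$sd_est / summary_b$sd_est,
    se_ratio = summary_a$mean_se / summary_b$mean_se)
}

#' Monte-Carlo performance summary of one scenario-model cell
#'
#' Filters the replicate fits to converged, non-boundary ones (boundary
#' variance estimates are bookkept as non-convergence and excluded from all
#' performance statistics, with both tallies reported), then computes the
#' summary measures: mean, SD and IQR of the intervention-effect estimates,
#' percentage bias (non-null truth), 95% CI coverage of the generative mean
#' effect, type I error (null truth), mean Wald SE, the average estimated
#' random-effect covariance, and for study-2 configurations the gap between
#' the mean estimate and the horizontal-comparison expectation log-OR 1.5.
#'
#' @param fits list of `swt_fit` objects, one per replicate
#' @param spec the generative `swt_scenario_spec`
#' @param form the model form the fits used
#' @param level confidence level for coverage
#' @return a one-row data frame of class `swt_scenario_summary`; the average
#'   varcomp matrix is attached as attribute `mean_varcomp`
#' @export
summarize_scenario <- function(fits, spec, form, level = 0.95) {
  form <- as_model_form(form)
  stopifnot(inherits(spec, "swt_scenario_spec"), length(fits) >= 1L)
  n_reps <- length(fits)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  bound <- vapply(fits, function(f) isTRUE(f$boundary), logical(1))
  keep <- conv & !bound
  if (!any(keep))
    stop("no usable fits: ", sum(!conv), " failed to converge, ",
         sum(bound), " at a variance boundary out of ", n_reps)
  used <- fits[keep]

  est <- vapply(used, function(f) f$estimates[["intervention"]], numeric(1))
  se <- vapply(used, function(f) f$std_errors[["intervention"]], numeric(1))
  truth <- spec$intervention$mean_log_or
  ints <- t(vapply(used, wald_interval, numeric(2), which = "intervention",
                   level = level))
  iqr <- unname(stats::quantile(est, c(0.25, 0.75), type = 7))

  vcs <- lapply(used, function(f) f$varcomp)
  mean_vc <- Reduce(`+`, vcs) / length(vcs)

  out <- data.frame(
    period_scn = spec$period_scenario$id,
    int_scn = spec$intervention$kind,
    effect = truth,
    study = spec$study,
    model = form$id,
    n_reps = n_reps,
    n_converged = sum(keep),
    n_optim_failed = sum(!conv),
    n_boundary = sum(bound & conv),
    mean_est = mean(est),
    sd_est = stats::sd(est),
    iqr_lo = iqr[1],
    iqr_hi = iqr[2],
    pct_bias = if (truth != 0) percentage_bias(est, truth) else NA_real_,
    coverage = if (truth != 0) coverage(ints, truth) else NA_real_,
    type1 = if (truth == 0) {
      p <- vapply(used, wald_pvalue, numeric(1), which = "intervention")
      type1_error(p, truth)
    } else NA_real_,
    mean_se = mean(se),
    var_intercept = mean_vc[1, 1],
    horizontal_gap = if (spec$study == 2L) abs(mean(est) - 1.5) else NA_real_,
    stringsAsFactors = FALSE
  )
  attr(out, "mean_varcomp") <- mean_vc
  class(out) <- c("swt_scenario_summary", class(out))
  out
}
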