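#' Analysis model forms for stepped wedge data
#'
#' Three logistic mixed models for the cluster-period event counts, all with
#' fixed effects for the intercept, the period and the intervention:
#' * `standard`: a random cluster intercept only (the Hussey-Hughes model);
#' * `random_period`: random intercept plus a correlated random deviation of
#'   the period effect (a cluster-period interaction), free 2x2 covariance;
#' * `random_intervention`: random intercept plus a correlated random
#'   deviation of the intervention effect, free 2x2 covariance.
#'
#' @param id one of "standard", "random_period", "random_intervention"
#' @return an object of class `swt_model_form`
#' @export
model_form <- function(id = c("standard", "random_period",
                              "random_intervention")) {
  id <- match.arg(id)
  form <- list(
    id = id,
    code = match(id, c("standard", "random_period", "random_intervention")) - 1L,
    n_ranef = if (id == "standard") 1L else 2L,
    n_varpar = if (id == "standard") 1L else 3L
  )
  class(form) <- "swt_model_form"
  form
}

as_model_form <- function(form) {
  if (inherits(form, "swt_model_form")) form else model_form(form)
}

# order records by cluster and build the index slices the C++ code expects
prepare_records <- function(records) {
  needed <- c("cluster_id", "period", "treated", "n_obs", "n_events")
  stopifnot(all(needed %in% names(records)))
  records <- records[order(records$cluster_id, records$period), , drop = FALSE]
  cl <- match(records$cluster_id, unique(records$cluster_id))
  runs <- rle(cl)$lengths
  list(
    y = as.numeric(records$n_events),
    n = as.numeric(records$n_obs),
    z = as.numeric(records$period == max(records$period)),
    x = as.numeric(records$treated),
    cl_start = as.integer(cumsum(c(0L, runs[-length(runs)]))),
    cl_len = as.integer(runs),
    lchoose_const = sum(lchoose(records$n_obs, records$n_events))
  )
}

# log-Cholesky encoding of the random-effect covariance
encode_varcomp <- function(Sigma, form) {
  if (form$n_ranef == 1L) {
    0.5 * log(max(Sigma[1, 1], 1e-14))
  } else {
    L11 <- sqrt(max(Sigma[1, 1], 1e-14))
    c21 <- Sigma[2, 1] / L11
    L22sq <- max(Sigma[2, 2] - c21^2, 1e-14)
    c(log(L11), c21, 0.5 * log(L22sq))
  }
}

decode_varcomp <- function(vpar, form) {
  if (form$n_ranef == 1L) {
    vc <- matrix(exp(2 * vpar[1]), 1L, 1L)
    dimnames(vc) <- list("intercept", "intercept")
  } else {
    L <- matrix(c(exp(vpar[1]), vpar[2], 0, exp(vpar[3])), 2L, 2L)
    vc <- L %*% t(L)
    slope <- if (form$id == "random_period") "period" else "intervention"
    dimnames(vc) <- list(c("intercept", slope), c("intercept", slope))
  }
  vc
}

default_quad_order <- function(form) if (form$n_ranef == 1L) 9L else 7L

#' Marginal log-likelihood contribution of one cluster
#'
#' Computes `log integral prod_j Binomial(y_j | n_j, expit(eta_j(r)))
#' phi(r; 0, Sigma) dr` for the records of a single cluster, where
#' `eta_j(r) = mu + beta Z_j + theta X_j + w_j . r` and `w_j` is the model
#' form's random-effect design (intercept, and period or treatment slope).
#' Integration is mode-centred adaptive Gauss-Hermite over 1 or 2 dimensions.
#' The additive binomial coefficient `log choose(n_j, y_j)` is included.
#'
#' @param fixed length-3 vector `(mu, beta, theta)` of fixed effects
#' @param Sigma random-effect covariance: 1x1 (standard) or 2x2 matrix; must
#'   be positive semidefinite
#' @param records data frame of the cluster's cluster-period rows (columns
#'   `cluster_id`, `period`, `treated`, `n_obs`, `n_events`)
#' @param form a model form (see [model_form()])
#' @param quad_order Gauss-Hermite order per axis
#' @return the scalar log-likelihood contribution
#' @export
cluster_marginal_loglik <- function(fixed, Sigma, records,
                                    form = "standard",
                                    quad_order = NULL) {
  form <- as_model_form(form)
  stopifnot(length(fixed) == 3L)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != form$n_ranef || ncol(Sigma) != form$n_ranef)
    stop("Sigma must be ", form$n_ranef, "x", form$n_ranef,
         " for the ", form$id, " form")
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("Sigma is not positive semidefinite")
  if (is.null(quad_order)) quad_order <- default_quad_order(form)
  if (length(unique(records$cluster_id)) != 1L)
    stop("records must belong to a single cluster")
  dat <- prepare_records(records)
  gh <- gauss_hermite(quad_order)
  par <- c(fixed, encode_varcomp(Sigma, form))
  ll <- agq_cluster_logliks(par, dat$y, dat$n, dat$z, dat$x,
                            dat$cl_start, dat$cl_len, form$code,
                            gh$nodes, gh$logw, TRUE)
  sum(ll)
}

# deterministic perturbations tried when the first optimisation attempt fails
restart_offsets <- function(npar) {
  nv <- npar - 3L
  list(
    c(rep(0, 3L), rep(0.7, nv) * c(1, rep(0, nv - 1L))[seq_len(nv)]),
    c(rep(0, 3L), rep(-1.5, nv)),
    c(rep(0.2, 3L), rep(0.7, nv))
  )
}

#' Fit a logistic mixed model to stepped wedge data by exact marginal
#' maximum likelihood
#'
#' Maximizes the binomial-logit marginal likelihood, integrating the
#' cluster-level random effects out by mode-centred adaptive Gauss-Hermite
#' quadrature (tensor grid for the two-dimensional forms). The random-effect
#' covariance is parameterized by its log-Cholesky factor, so the search is
#' unconstrained and the fitted covariance is always positive semidefinite.
#' The likelihood is evaluated on the aggregated cluster-period counts;
#' under within-cluster-period exchangeability these are sufficient, so the
#' fit is identical (up to an additive constant absorbed into `loglik`) to
#' one on fully disaggregated Bernoulli observations.
#'
#' Estimates with any random-effect variance below `boundary_tol` are flagged
#' `boundary`; performance summaries treat boundary fits as non-converged and
#' exclude them, since a variance estimated at the edge of the parameter
#' space is the usual footprint of fitting a random effect whose true
#' variance is zero.
#'
#' @param data a `swt_trial` or a data frame of cluster-period records
#' @param form a model form (see [model_form()]) or its id string
#' @param quad_order Gauss-Hermite order per axis (default 9 for the
#'   one-dimensional standard form, 7 per axis for the two-dimensional
#'   forms; the cluster-period counts are large, so the mode-centred
#'   integrand is close to Gaussian and these orders are already accurate to
#'   well below the Monte-Carlo noise)
#' @param boundary_tol variance (log-odds^2 scale) below which a
#'   random-effect variance is flagged as a boundary estimate
#' @param start optional full start vector `(mu, beta, theta, varpar...)`
#' @param max_restarts deterministic perturbed restarts tried if the first
#'   attempt does not converge
#' @param maxit optimizer iteration cap
#' @return an object of class `swt_fit` with fields `estimates` (named
#'   `intercept`, `period`, `intervention`), `std_errors`, `varcomp`,
#'   `loglik`, `converged`, `boundary`, `n_iter`, `form`
#' @export
fit_glmm <- function(data, form = "standard", quad_order = NULL,
                     boundary_tol = 1e-4, start = NULL,
                     max_restarts = 3L, maxit = 500L) {
  form <- as_model_form(form)
  records <- if (inherits(data, "swt_trial")) data$records else data
  if (is.null(quad_order)) quad_order <- default_quad_order(form)
  dat <- prepare_records(records)
  if (all(dat$x == 1) || all(dat$x == 0))
    stop("intervention effect not identifiable: data contain only ",
         if (all(dat$x == 1)) "treated" else "untreated", " records")
  gh <- gauss_hermite(quad_order)

  obj <- function(par) agq_nll(par, dat$y, dat$n, dat$z, dat$x,
                               dat$cl_start, dat$cl_len, form$code,
                               gh$nodes, gh$logw)
  gr <- function(par) agq_nll_grad(par, dat$y, dat$n, dat$z, dat$x,
                                   dat$cl_start, dat$cl_len, form$code,
                                   gh$nodes, gh$logw)

  npar <- 3L + form$n_varpar
  if (is.null(start)) start <- default_start(dat, form)
  stopifnot(length(start) == npar)
  lower <- c(rep(-30, 3L), if (form$n_ranef == 1L) -7 else c(-7, -25, -7))
  upper <- c(rep(30, 3L), if (form$n_ranef == 1L) 3 else c(3, 25, 3))

  tries <- c(list(numeric(npar)), restart_offsets(npar)[seq_len(max_restarts)])
  best <- NULL
  for (off in tries) {
    st <- pmin(pmax(start + off, lower + 1e-3), upper - 1e-3)
    opt <- tryCatch(
      stats::nlminb(st, obj, gradient = gr, lower = lower, upper = upper,
                    control = list(iter.max = maxit, eval.max = 2L * maxit,
                                   rel.tol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    ok <- opt$convergence == 0L
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && opt$objective < best$opt$objective - 1e-8)) {
      best <- list(opt = opt, ok = ok)
    }
    if (ok) break
  }
  if (is.null(best)) stop("all optimisation attempts failed")
  opt <- best$opt
  par <- opt$par
  vc <- decode_varcomp(par[-(1:3)], form)
  boundary <- any(diag(vc) < boundary_tol)

  # observed information of the full parameter vector (central differences of
  # the analytic-free gradient); SEs for fixed effects from its inverse
  H <- matrix(NA_real_, npar, npar)
  for (i in seq_len(npar)) {
    h <- 1e-4 * max(1, abs(par[i]))
    pp <- par; pp[i] <- par[i] + h; g1 <- gr(pp)
    pp[i] <- par[i] - h; g0 <- gr(pp)
    H[i, ] <- (g1 - g0) / (2 * h)
  }
  H <- (H + t(H)) / 2
  vcov_full <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  fe_ok <- TRUE
  if (is.null(vcov_full)) {
    # at a boundary the variance-parameter block of the information can be
    # singular; fall back to the fixed-effect block
    vcov_fe <- tryCatch(chol2inv(chol(H[1:3, 1:3])), error = function(e) NULL)
    if (is.null(vcov_fe)) {
      fe_ok <- FALSE
      se <- rep(NA_real_, 3L)
    } else se <- sqrt(diag(vcov_fe))
  } else {
    se <- sqrt(diag(vcov_full)[1:3])
  }

  est <- par[1:3]
  names(est) <- names(se) <- c("intercept", "period", "intervention")
  fit <- list(
    estimates = est,
    std_errors = se,
    varcomp = vc,
    loglik = -opt$objective + dat$lchoose_const,
    converged = best$ok && fe_ok,
    boundary = boundary,
    n_iter = opt$iterations,
    message = opt$message,
    form = form,
    quad_order = quad_order,
    boundary_tol = boundary_tol,
    n_clusters = length(dat$cl_len),
    par = par
  )
  class(fit) <- "swt_fit"
  fit
}

# fixed effects from an unclustered binomial GLM; intercept variance from
# half the between-cluster dispersion of empirical-logit residuals
default_start <- function(dat, form) {
  fe <- tryCatch({
    g <- stats::glm(cbind(dat$y, dat$n - dat$y) ~ dat$z + dat$x,
                    family = stats::binomial())
    unname(stats::coef(g))
  }, error = function(e) c(0, 0, 0))
  if (any(!is.finite(fe))) fe <- c(0, 0, 0)
  elogit <- qlogis((dat$y + 0.5) / (dat$n + 1))
  resid <- elogit - (fe[1] + fe[2] * dat$z + fe[3] * dat$x)
  cl <- rep(seq_along(dat$cl_len), dat$cl_len)
  clmean <- tapply(resid, cl, mean)
  v <- max(0.5 * stats::var(clmean), 0.05)
  if (form$n_ranef == 1L) {
    c(fe, 0.5 * log(v))
  } else {
    c(fe, 0.5 * log(v), 0, 0.5 * log(max(v / 2, 0.05)))
  }
}

#' @export
print.swt_fit <- function(x, ...) {
  cat(sprintf("Logistic mixed model (%s), marginal ML by adaptive GH quadrature\n",
              x$form$id))
  cat(sprintf("  logLik %.3f | converged: %s | boundary: %s | %d iterations\n",
              x$loglik, x$converged, x$boundary, x$n_iter))
  tab <- cbind(estimate = x$estimates, std.error = x$std_errors)
  print(round(tab, 4))
  cat("Random-effect covariance:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' Wald confidence interval for a fixed effect
#'
#' Normal-reference interval `estimate +/- z * SE` on the log odds (ratio)
#' scale.
#'
#' @param fit a converged `swt_fit`
#' @param which fixed effect: "intervention" (default), "period", "intercept"
#' @param level confidence level
#' @return named vector `(lower, upper)`
#' @export
wald_interval <- function(fit, which = "intervention", level = 0.95) {
  stopifnot(inherits(fit, "swt_fit"), level > 0, level < 1)
  if (!isTRUE(fit$converged)) stop("Wald interval requires a converged fit")
  which <- match.arg(which, names(fit$estimates))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$estimates[[which]]
  se <- fit$std_errors[[which]]
  c(lower = est - z * se, upper = est + z * se)
}

#' Two-sided Wald p-value for a fixed effect
#'
#' @inheritParams wald_interval
#' @param null null value on the log scale (default 0, i.e. OR = 1)
#' @return the p-value
#' @export
wald_pvalue <- function(fit, which = "intervention", null = 0) {
  stopifnot(inherits(fit, "swt_fit"))
  if (!isTRUE(fit$converged)) stop("Wald p-value requires a converged fit")
  which <- match.arg(which, names(fit$estimates))
  z <- (fit$estimates[[which]] - null) / fit$std_errors[[which]]
  2 * stats::pnorm(-abs(z))
}

#' Likelihood-ratio test of a variance component
#'
#' Compares a two-random-effect model (random period or random intervention)
#' against the nested random-intercept model. Because the null puts one
#' variance on the boundary of the parameter space and removes one
#' covariance, the reference distribution is the 50:50 mixture of chi-squared
#' distributions with 1 and 2 degrees of freedom.
#'
#' @param fit_full converged fit of the larger model
#' @param fit_reduced converged fit of the nested random-intercept model on
#'   the same data
#' @return the mixture p-value
#' @export
lrt_variance_component <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "swt_fit"), inherits(fit_reduced, "swt_fit"))
  if (fit_reduced$form$id != "standard" || fit_full$form$id == "standard")
    stop("the reduced model must be the standard form nested in the full model")
  if (!isTRUE(fit_full$converged) || !isTRUE(fit_reduced$converged))
    stop("both fits must have converged")
  lr <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (lr < -1e-4)
    stop("full-model log-likelihood below reduced-model log-likelihood: ",
         "optimisation failure")
  lr <- max(lr, 0)
  0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(lr, df = 2, lower.tail = FALSE)
}
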