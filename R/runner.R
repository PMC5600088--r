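# deterministic 31-bit seed per (master, cell, replicate): a polynomial
# rolling hash so replicates are independent of execution order and the grid
# can be parallelised per replicate
derive_seed <- function(master_seed, cell_key, rep_index) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master_seed) %% m
  for (ch in utf8ToInt(paste0(cell_key, "#", rep_index))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

cell_key <- function(spec) {
  sprintf("study%d:p%d:%s:%g", spec$study, spec$period_scenario$id,
          spec$intervention$kind, spec$intervention$mean_log_or)
}

#' Simulate and fit one scenario cell
#'
#' Draws `n_reps` independent trials from the scenario and fits each with the
#' requested model forms (the same simulated datasets are analysed by every
#' form, as when several analysis models are compared on one simulation
#' stream). Per-replicate seeds are derived deterministically from
#' `master_seed` and the cell's labels, so cells and replicates are
#' independent and reproducible in any execution order.
#'
#' @param spec a `swt_scenario_spec`
#' @param models character vector of model-form ids to fit
#' @param n_reps number of simulation replicates
#' @param master_seed master seed for the whole run
#' @param quad_order optional Gauss-Hermite order override
#' @param boundary_tol boundary tolerance passed to [fit_glmm()]
#' @return list with `spec`, `fits` (a list per model id of per-replicate
#'   `swt_fit` objects) and `replicates` (a long data frame, one row per
#'   replicate x model, with the estimate, SE, log-likelihood, variance
#'   components and flags)
#' @export
run_cell <- function(spec, models = c("standard", "random_period",
                                      "random_intervention"),
                     n_reps = 500L, master_seed = 20170528L,
                     quad_order = NULL, boundary_tol = 1e-4) {
  stopifnot(inherits(spec, "swt_scenario_spec"), n_reps >= 1L)
  key <- cell_key(spec)
  fits <- stats::setNames(vector("list", length(models)), models)
  for (mm in models) fits[[mm]] <- vector("list", n_reps)
  rows <- vector("list", n_reps * length(models))
  ri <- 0L
  # fit the 1-D standard form first; its solution warm-starts the 2-D forms
  models <- unique(models)
  if ("standard" %in% models)
    models <- c("standard", setdiff(models, "standard"))
  for (r in seq_len(n_reps)) {
    trial <- simulate_trial(spec, derive_seed(master_seed, key, r))
    std_par <- NULL
    for (mm in models) {
      start <- if (!is.null(std_par) && mm != "standard")
        c(std_par[1:3], std_par[4], 0, 0.5 * log(0.2)) else NULL
      fit <- fit_glmm(trial, mm, quad_order = quad_order,
                      boundary_tol = boundary_tol, start = start)
      if (mm == "standard" && isTRUE(fit$converged)) std_par <- fit$par
      fits[[mm]][[r]] <- fit
      vc <- fit$varcomp
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        rep = r, model = mm,
        est = fit$estimates[["intervention"]],
        se = fit$std_errors[["intervention"]],
        est_intercept = fit$estimates[["intercept"]],
        est_period = fit$estimates[["period"]],
        loglik = fit$loglik,
        var_intercept = vc[1, 1],
        var_slope = if (nrow(vc) == 2L) vc[2, 2] else NA_real_,
        cov_is = if (nrow(vc) == 2L) vc[2, 1] else NA_real_,
        converged = fit$converged, boundary = fit$boundary,
        stringsAsFactors = FALSE)
    }
  }
  list(spec = spec, fits = fits,
       replicates = do.call(rbind, rows[seq_len(ri)]))
}

study1_configs <- function() {
  grid <- expand.grid(period = 1:4, kind = c("common", "varying"),
                      effect = c(0.41, 0), stringsAsFactors = FALSE)
  grid$study <- 1L
  grid
}

study2_configs <- function() {
  grid <- expand.grid(period = 1:4, kind = c("common", "varying"),
                      stringsAsFactors = FALSE)
  grid$effect <- 0.41
  grid$study <- 2L
  grid
}

#' Run the full simulation grid
#'
#' Iterates over the scenario grid — study 1: period scenarios 1-4 x
#' intervention common/varying x mean effect 0.41/0; study 2 (horizontal
#' probe, no null arm): period scenarios 1-4 x common/varying with group-2
#' mean log-OR 1.5 — simulating `n_reps` trials per data configuration and
#' fitting each requested analysis model. Completed cells found in
#' `out_dir` with a matching configuration checksum are skipped, so an
#' interrupted run resumes where it stopped.
#'
#' @param n_reps replicates per cell (500 reproduces the reference grid)
#' @param master_seed master seed; the whole grid is a pure function of it
#' @param studies which studies to run (subset of 1:2)
#' @param periods period scenarios to run (subset of 1:4)
#' @param kinds intervention kinds to run
#' @param effects mean effects to run (subset of c(0.41, 0))
#' @param models model forms to fit
#' @param quad_order optional quadrature order override
#' @param out_dir optional directory for per-cell replicate CSVs and the
#'   summary table; `NULL` keeps everything in memory
#' @param verbose print per-cell progress to stderr
#' @return data frame of scenario summaries, one row per cell x model
#' @export
run_grid <- function(n_reps = 500L, master_seed = 20170528L,
                     studies = 1:2, periods = 1:4,
                     kinds = c("common", "varying"),
                     effects = c(0.41, 0),
                     models = c("standard", "random_period",
                                "random_intervention"),
                     quad_order = NULL, out_dir = NULL, verbose = TRUE) {
  configs <- rbind(study1_configs(), study2_configs())
  configs <- configs[configs$study %in% studies & configs$period %in% periods &
                       configs$kind %in% kinds & configs$effect %in% effects, ]
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  summaries <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    spec <- scenario_spec(cfg$period, cfg$kind, effect = cfg$effect,
                          study = cfg$study)
    key <- cell_key(spec)
    stamp <- sprintf("%s|reps%d|seed%d|%s", key, n_reps, master_seed,
                     paste(models, collapse = "+"))
    cell_file <- if (!is.null(out_dir))
      file.path(out_dir, paste0(gsub("[:.]", "_", stamp), ".csv")) else NULL
    if (!is.null(cell_file) && file.exists(cell_file)) {
      reps <- utils::read.csv(cell_file)
      if (verbose) message("cell ", key, ": found on disk, skipping")
      summaries[[i]] <- summarize_cell_table(reps, spec, models)
      next
    }
    if (verbose) message("cell ", key, ": ", n_reps, " replicates ...")
    cell <- run_cell(spec, models = models, n_reps = n_reps,
                     master_seed = master_seed, quad_order = quad_order)
    if (!is.null(cell_file))
      utils::write.csv(cell$replicates, cell_file, row.names = FALSE)
    summaries[[i]] <- do.call(rbind, lapply(models, function(mm)
      summarize_scenario(cell$fits[[mm]], spec, mm)))
  }
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "scenario_summaries.csv"),
                     row.names = FALSE)
  out
}

# rebuild summaries from a persisted replicate table (resume path)
summarize_cell_table <- function(reps, spec, models) {
  do.call(rbind, lapply(models, function(mm) {
    sub <- reps[reps$model == mm, ]
    fits <- lapply(seq_len(nrow(sub)), function(k) {
      vc <- if (is.na(sub$var_slope[k])) {
        matrix(sub$var_intercept[k], 1, 1)
      } else {
        matrix(c(sub$var_intercept[k], sub$cov_is[k],
                 sub$cov_is[k], sub$var_slope[k]), 2, 2)
      }
      structure(list(
        estimates = c(intercept = sub$est_intercept[k],
                      period = sub$est_period[k],
                      intervention = sub$est[k]),
        std_errors = c(intercept = NA_real_, period = NA_real_,
                       intervention = sub$se[k]),
        varcomp = vc, loglik = sub$loglik[k],
        converged = sub$converged[k], boundary = sub$boundary[k],
        form = as_model_form(mm)), class = "swt_fit")
    })
    summarize_scenario(fits, spec, mm)
  }))
}

#' Reference Monte-Carlo results reproduced by the default grid
#'
#' Published headline values from the simulation study these defaults
#' emulate, with the grid cell each one summarizes. Used by
#' [compare_to_paper()] to tabulate a freshly computed grid against them.
#'
#' @return data frame with one row per reference quantity
#' @export
reference_results <- function() {
  data.frame(
    quantity = c(
      "pct_bias_standard_p1_varying", "pct_bias_standard_p2_varying",
      "pct_bias_standard_varying_period_min",
      "coverage_random_intervention_p3", "coverage_random_intervention_p4",
      "coverage_random_period_p1_varying",
      "coverage_standard_misspecified_max",
      "sd_ratio_standard_vs_random_period_p3",
      "sd_ratio_standard_vs_random_intervention_p1_varying",
      "se_ratio_standard_vs_random_period_max",
      "mean_var_intercept_standard_p4"),
    value = c(-9, -16, -20, 74, 88, 86, 25, 3.6, 1.5, 0.33, 1.26),
    cmp = c("eq", "eq", "ge", "eq", "eq", "eq", "le", "eq", "eq", "le", "eq"),
    stringsAsFactors = FALSE
  )
}

grid_cell <- function(summaries, period, kind, model, effect = 0.41,
                      study = 1L) {
  sel <- summaries$period_scn == period & summaries$int_scn == kind &
    summaries$model == model & summaries$effect == effect &
    summaries$study == study
  if (!any(sel)) return(NULL)
  summaries[which(sel)[1], ]
}

# the six study-1 configurations in which the standard model is misspecified
misspecified_configs <- function() {
  rbind(expand.grid(period = 3:4, kind = c("common", "varying"),
                    stringsAsFactors = FALSE),
        data.frame(period = 1:2, kind = "varying"))
}

# compute the reference quantities from a summary grid; NA when cells missing
computed_reference_quantities <- function(summaries) {
  g <- function(...) grid_cell(summaries, ...)
  mis <- misspecified_configs()
  mis_rows <- lapply(seq_len(nrow(mis)), function(i)
    list(std = g(mis$period[i], mis$kind[i], "standard"),
         rp = g(mis$period[i], mis$kind[i], "random_period")))
  num_or_na <- function(x) if (is.null(x)) NA_real_ else x
  vp <- mis[mis$period %in% 3:4, ]
  vp_bias <- vapply(seq_len(nrow(vp)), function(i) {
    cell <- g(vp$period[i], vp$kind[i], "standard")
    num_or_na(cell$pct_bias)
  }, numeric(1))
  std_cov <- vapply(mis_rows, function(r) num_or_na(r$std$coverage), numeric(1))
  se_ratio <- vapply(mis_rows, function(r) {
    if (is.null(r$std) || is.null(r$rp)) return(NA_real_)
    dispersion_and_se_ratios(r$std, r$rp)[["se_ratio"]]
  }, numeric(1))
  sd9 <- if (!is.null(g(3, "common", "standard")) &&
             !is.null(g(3, "common", "random_period")))
    dispersion_and_se_ratios(g(3, "common", "standard"),
                             g(3, "common", "random_period"))[["sd_ratio"]]
    else NA_real_
  sd10 <- if (!is.null(g(1, "varying", "standard")) &&
              !is.null(g(1, "varying", "random_intervention")))
    dispersion_and_se_ratios(g(1, "varying", "standard"),
                             g(1, "varying", "random_intervention"))[["sd_ratio"]]
    else NA_real_
  c(
    pct_bias_standard_p1_varying = num_or_na(g(1, "varying", "standard")$pct_bias),
    pct_bias_standard_p2_varying = num_or_na(g(2, "varying", "standard")$pct_bias),
    pct_bias_standard_varying_period_min =
      if (all(is.na(vp_bias))) NA_real_ else min(vp_bias, na.rm = TRUE),
    coverage_random_intervention_p3 =
      num_or_na(g(3, "common", "random_intervention")$coverage),
    coverage_random_intervention_p4 =
      num_or_na(g(4, "common", "random_intervention")$coverage),
    coverage_random_period_p1_varying =
      num_or_na(g(1, "varying", "random_period")$coverage),
    coverage_standard_misspecified_max =
      if (all(is.na(std_cov))) NA_real_ else max(std_cov, na.rm = TRUE),
    sd_ratio_standard_vs_random_period_p3 = sd9,
    sd_ratio_standard_vs_random_intervention_p1_varying = sd10,
    se_ratio_standard_vs_random_period_max =
      if (all(is.na(se_ratio))) NA_real_ else max(se_ratio, na.rm = TRUE),
    mean_var_intercept_standard_p4 =
      num_or_na(g(4, "common", "standard")$var_intercept)
  )
}

#' Compare a computed summary grid against the reference results
#'
#' Tabulates each reference quantity against its freshly computed value with
#' a Monte-Carlo tolerance of three simulation standard errors, widened by
#' `sqrt(500 / n_reps)` when fewer than 500 replicates were run. Cells absent
#' from the grid are listed as not run.
#'
#' @param summaries a summary grid from [run_grid()]
#' @return data frame with columns `quantity`, `reference`, `computed`,
#'   `cmp`, `tolerance`, `status` ("pass", "fail" or "not run")
#' @export
compare_to_paper <- function(summaries) {
  ref <- reference_results()
  comp <- computed_reference_quantities(summaries)
  n_min <- min(summaries$n_converged)
  scale <- sqrt(500 / max(n_min, 1))
  # MC standard errors: coverage, binomial around the reference proportion;
  # bias, sd_est-based; ratios and variances, a 10% relative allowance
  tol <- vapply(seq_len(nrow(ref)), function(i) {
    v <- ref$value[i]
    q <- ref$quantity[i]
    if (grepl("^coverage", q)) {
      3 * sqrt(v / 100 * (1 - v / 100) / max(n_min, 1)) * 100
    } else if (grepl("^pct_bias", q)) {
      cells <- summaries[summaries$model == "standard" &
                           summaries$effect == 0.41 & summaries$study == 1L, ]
      sdm <- if (nrow(cells)) max(cells$sd_est) else 0.2
      3 * (sdm / sqrt(max(n_min, 1))) / 0.41 * 100
    } else {
      0.1 * abs(v) * scale + 0.05
    }
  }, numeric(1))
  status <- vapply(seq_len(nrow(ref)), function(i) {
    x <- comp[[ref$quantity[i]]]
    if (is.na(x)) return("not run")
    ok <- switch(ref$cmp[i],
                 eq = abs(x - ref$value[i]) <= tol[i],
                 ge = x >= ref$value[i] - tol[i],
                 le = x <= ref$value[i] + tol[i])
    if (ok) "pass" else "fail"
  }, character(1))
  data.frame(quantity = ref$quantity, reference = ref$value,
             computed = unname(comp[ref$quantity]), cmp = ref$cmp,
             tolerance = tol, status = status, stringsAsFactors = FALSE)
}
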