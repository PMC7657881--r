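# End-to-end orchestration: simulate -> fit -> compare -> summarize -> ROC,
# and the parameter-recovery study used to validate the pipeline.

#' Assemble an end-to-end run configuration
#'
#' @param design an [design_spec()].
#' @param params optional [generative_params()] ground truth (needed to
#'   simulate and for recovery studies).
#' @param models model levels to fit.
#' @param priors an [prior_spec()].
#' @param fit an [fit_config()].
#' @param output_dir directory for output files.
#' @param verbosity 0 silent, 1 progress messages.
#' @param seed master seed; every random stage derives its seed from it.
#' @return object of class `sdt_run_config`.
#' @export
run_config <- function(design = design_spec(), params = NULL, models = 0:4,
                       priors = prior_spec(), fit = fit_config(),
                       output_dir = tempfile("sdt_run_"), verbosity = 1,
                       seed = 1L) {
  stopifnot(all(models %in% 0:4))
  structure(list(design = design, params = params, models = as.integer(models),
                 priors = priors, fit = fit, output_dir = output_dir,
                 verbosity = verbosity, seed = as.integer(seed)),
            class = "sdt_run_config")
}

say <- function(config, ...) {
  if (config$verbosity > 0) message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Run the full analysis on a trial table
#'
#' Fits the requested models, compares them by PSIS-LOO, summarizes
#' criterion/sensitivity per condition from the best model, computes
#' condition-wise posterior AUC and posterior-mean ROC curves, and writes
#' the output bundle (comparison.csv, sdt_summary.csv, condition_rates.csv,
#' roc_points.csv, auc.csv, diagnostics.json, manifest.json) to
#' `config$output_dir`. Diagnostic failures are reported, not fatal.
#'
#' @param config an [run_config()].
#' @param trials trial table with responses (if `NULL`, simulated from
#'   `config$params` and `config$design`).
#' @return list with the fits, comparison, summary, AUC table and manifest.
#' @export
run_analysis <- function(config, trials = NULL) {
  stopifnot(inherits(config, "sdt_run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  sim_hash <- NULL
  if (is.null(trials)) {
    if (is.null(config$params)) stop("no trials supplied and no generative params in config")
    say(config, "simulating ", config$design$n_participants, " participants")
    params <- config$params
    params$seed <- config$seed
    design <- config$design
    design$seed <- config$seed
    trials <- simulate_responses(build_design(design), params)
    sim_hash <- object_hash(trials)
  }
  trials <- validate_trials(trials, require_response = TRUE)

  rates <- condition_rates(trials)
  utils::write.csv(rates, file.path(config$output_dir, "condition_rates.csv"),
                   row.names = FALSE)

  fits <- list()
  loos <- list()
  diag_report <- list()
  for (lv in config$models) {
    say(config, "fitting model ", lv)
    fc <- config$fit
    fc$seed <- config$seed + 100L * (lv + 1L)
    fit <- fit_probit(make_model(lv), trials, config$priors, fc)
    chk <- check_diagnostics(fit)
    if (!chk$pass) say(config, "model ", lv, " diagnostics flagged")
    fits[[paste0("model", lv)]] <- fit
    loos[[paste0("model", lv)]] <- loo(pointwise_loglik(fit))
    diag_report[[paste0("model", lv)]] <- list(
      pass = chk$pass, no_divergences = chk$no_divergences,
      rhat_ok = chk$rhat_ok, ess_ok = chk$ess_ok,
      learned_from_data = chk$learned_from_data,
      flagged_rhat = chk$flagged_rhat, flagged_ess = chk$flagged_ess)
  }

  comparison <- NULL
  best <- fits[[length(fits)]]
  if (length(loos) >= 2L) {
    comparison <- loo_compare(loos)
    write_comparison(comparison, file.path(config$output_dir, "comparison.csv"))
    best <- fits[[comparison$model[1]]]
  }

  say(config, "summarizing best model (level ", best$model$level, ")")
  summ <- sdt_summary(best)
  cells <- sdt_cells()
  auc_tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    a <- auc_posterior(best, trials, mode = cells$mode[i], speed = cells$speed[i])
    data.frame(mode = cells$mode[i], speed = cells$speed[i],
               auc = a$mean, auc_lo = a$lower, auc_hi = a$upper)
  }))
  write_sdt_table(summ, file.path(config$output_dir, "sdt_summary.csv"),
                  auc = auc_tab)
  utils::write.csv(auc_tab, file.path(config$output_dir, "auc.csv"),
                   row.names = FALSE)

  scored <- predict_probabilities(best, trials)
  roc_all <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- scored[scored$mode == cells$mode[i] & scored$speed == cells$speed[i], ]
    pts <- roc_points(sub)$points
    cbind(mode = cells$mode[i], speed = cells$speed[i],
          pts[, c("threshold", "sensitivity", "specificity")])
  }))
  utils::write.csv(roc_all, file.path(config$output_dir, "roc_points.csv"),
                   row.names = FALSE)

  jsonlite::write_json(diag_report,
                       file.path(config$output_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    seed = config$seed,
    models = config$models,
    config_hash = object_hash(list(design = config_to_list(config$design),
                                   priors = config_to_list(config$priors),
                                   fit = config_to_list(config$fit))),
    simulation_hash = sim_hash,
    n_trials = nrow(trials),
    package_version = as.character(utils::packageVersion("laughsdt")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(fits = fits, loos = loos, comparison = comparison,
                 summary = summ, auc = auc_tab, rates = rates,
                 manifest = manifest, output_dir = config$output_dir))
}

#' Parameter-recovery study
#'
#' Repeats simulate-then-fit from the configured ground truth and reports,
#' for every fixed effect, the bias and RMSE of the posterior mean and the
#' coverage of the 95% posterior interval; variance components (participant
#' sds, stimulus sd) are reported with posterior-mean bias only.
#'
#' @param config an [run_config()] with `params` set; `models` selects the
#'   fitted model (the highest level listed is used).
#' @param n_replicates number of simulate/fit replicates (>= 2).
#' @return data.frame of class `sdt_recovery`: one row per parameter with
#'   truth, mean estimate, bias, rmse and coverage (NA for components
#'   without interval bookkeeping).
#' @export
run_recovery <- function(config, n_replicates = 20) {
  stopifnot(inherits(config, "sdt_run_config"))
  if (is.null(config$params)) stop("recovery requires generative params in the config")
  if (n_replicates < 2) stop("need at least 2 replicates")
  level <- max(config$models)
  model <- make_model(level)
  terms <- model$fixed_terms
  truth_beta <- config$params$beta[terms]

  est <- matrix(NA_real_, n_replicates, length(terms),
                dimnames = list(NULL, terms))
  lo <- est; hi <- est
  sd_terms <- paste0("sd_participant__", sanitize_label(terms))
  est_sd <- matrix(NA_real_, n_replicates, length(terms) + 1L,
                   dimnames = list(NULL, c(sd_terms, "sd_stimulus__intercept")))

  for (r in seq_len(n_replicates)) {
    say(config, "recovery replicate ", r, "/", n_replicates)
    design <- config$design
    design$seed <- config$seed + 1000L * r
    params <- config$params
    params$seed <- config$seed + 1000L * r + 1L
    trials <- simulate_responses(build_design(design), params)
    fc <- config$fit
    fc$seed <- config$seed + 1000L * r + 2L
    fit <- fit_probit(model, trials, config$priors, fc)
    bcols <- paste0("b_", sanitize_label(terms))
    for (k in seq_along(terms)) {
      v <- fit$draws[, bcols[k]]
      est[r, k] <- mean(v)
      lo[r, k] <- quantile(v, 0.025, names = FALSE)
      hi[r, k] <- quantile(v, 0.975, names = FALSE)
    }
    est_sd[r, ] <- colMeans(fit$draws[, colnames(est_sd), drop = FALSE])
  }

  fixed <- data.frame(
    parameter = terms, kind = "fixed", truth = unname(truth_beta),
    estimate = colMeans(est),
    bias = colMeans(est) - unname(truth_beta),
    rmse = sqrt(colMeans(sweep(est, 2, truth_beta)^2)),
    coverage = vapply(seq_along(terms), function(k)
      mean(lo[, k] <= truth_beta[k] & truth_beta[k] <= hi[, k]), 0),
    stringsAsFactors = FALSE)
  truth_sd <- c(config$params$participant_sd[terms], config$params$stimulus_sd)
  comp <- data.frame(
    parameter = colnames(est_sd), kind = "variance", truth = unname(truth_sd),
    estimate = colMeans(est_sd),
    bias = colMeans(est_sd) - unname(truth_sd),
    rmse = sqrt(colMeans(sweep(est_sd, 2, truth_sd)^2)),
    coverage = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(fixed, comp)
  rownames(out) <- NULL
  class(out) <- c("sdt_recovery", "data.frame")
  out
}
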