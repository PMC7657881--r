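# Trial-table CSV schema and structured-config serialization.

trial_schema <- c("participant_id", "list_id", "trial_index", "stimulus_id",
                  "familiarity", "mode", "speed", "response")

#' Validate a trial table against the CSV schema
#'
#' Checks required columns, factor levels and the response coding,
#' reporting offending row numbers.
#'
#' @param trials data.frame.
#' @param require_response if `TRUE`, responses must be 0/1 and non-missing.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_trials <- function(trials, require_response = FALSE) {
  missing_cols <- setdiff(setdiff(trial_schema, "response"), names(trials))
  if (length(missing_cols))
    stop("trial table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_level <- function(col, levels) {
    rows <- which(!trials[[col]] %in% levels)
    if (length(rows))
      stop("invalid ", col, " value(s) at row(s) ",
           paste(head(rows, 5), collapse = ", "),
           if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5),
           "; allowed: ", paste(levels, collapse = ", "))
  }
  bad_level("familiarity", c("friends", "strangers"))
  bad_level("mode", c("colaughter", "cospeech"))
  bad_level("speed", c("original", "sped-up"))
  if (require_response) {
    rows <- which(!trials$response %in% c(0L, 1L))
    if (length(rows))
      stop("response must be 0 or 1; invalid at row(s) ",
           paste(head(rows, 5), collapse = ", "),
           if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5))
  }
  if ("liking" %in% names(trials)) {
    rows <- which(!is.na(trials$liking) & !trials$liking %in% 1:7)
    if (length(rows))
      stop("liking must be an integer 1-7; invalid at row(s) ",
           paste(head(rows, 5), collapse = ", "))
  }
  trials
}

#' Read a trial table from CSV
#'
#' @param path CSV file with a header row (UTF-8).
#' @return validated trial data.frame.
#' @export
read_trials <- function(path) {
  validate_trials(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a trial table to CSV
#'
#' @param trials trial data.frame.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  cols <- c(trial_schema, if ("liking" %in% names(trials)) "liking")
  utils::write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- structured configs (JSON, round-trip stable) -------------------------

config_to_list <- function(x) {
  if (inherits(x, "sdt_generative_params")) {
    list(beta = unname(x$beta), participant_sd = unname(x$participant_sd),
         participant_corr = unclass(x$participant_corr),
         stimulus_sd = x$stimulus_sd, seed = x$seed)
  } else {
    unclass(x)
  }
}

#' Serialize a run configuration to JSON
#'
#' @param config an [run_config()] object.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  payload <- list(design = config_to_list(config$design),
                  params = if (!is.null(config$params)) config_to_list(config$params),
                  models = config$models,
                  priors = config_to_list(config$priors),
                  fit = config_to_list(config$fit),
                  output_dir = config$output_dir,
                  verbosity = config$verbosity,
                  seed = config$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file written by [write_run_config()].
#' @return an [run_config()] object.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- NULL
  if (!is.null(x$params))
    params <- generative_params(beta = x$params$beta,
                                participant_sd = x$params$participant_sd,
                                participant_corr = x$params$participant_corr,
                                stimulus_sd = x$params$stimulus_sd,
                                seed = x$params$seed)
  run_config(design = do.call(design_spec, x$design[setdiff(names(x$design), character(0))]),
             params = params,
             models = x$models,
             priors = do.call(prior_spec, x$priors),
             fit = do.call(fit_config, x$fit),
             output_dir = x$output_dir,
             verbosity = x$verbosity,
             seed = x$seed)
}

#' Write the condition-summary table in the published layout
#'
#' @param summary result of [sdt_summary()].
#' @param path output CSV path.
#' @param auc optional data.frame with mode, speed, auc, auc_lo, auc_hi.
#' @export
write_sdt_table <- function(summary, path, auc = NULL) {
  out <- data.frame(
    condition = sprintf("%s (%s)", summary$mode, summary$speed),
    criterion_pct = round(summary$criterion_pct),
    criterion_z = round(summary$criterion_z, 2),
    criterion_ci = sprintf("(%.2f %.2f)", summary$criterion_lo, summary$criterion_hi),
    sensitivity_pct = round(summary$sensitivity_pct),
    sensitivity_z = round(summary$sensitivity_z, 2),
    sensitivity_ci = sprintf("(%.2f %.2f)", summary$sensitivity_lo, summary$sensitivity_hi),
    stringsAsFactors = FALSE)
  if (!is.null(auc)) {
    m <- match(paste(summary$mode, summary$speed),
               paste(auc$mode, auc$speed))
    out$auc <- round(auc$auc[m], 2)
    out$auc_ci <- sprintf("(%.2f %.2f)", auc$auc_lo[m], auc$auc_hi[m])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a model-comparison table to CSV
#'
#' @param comparison an [loo_compare()] result.
#' @param path output CSV path.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison)[, c("model", "looic", "elpd_diff",
                                                 "se_diff", "n_high_k")],
                   path, row.names = FALSE)
  invisible(path)
}
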