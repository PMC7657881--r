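#' Published condition-level estimates
#'
#' Reads the condition-level posterior summaries reported by the original
#' behavioural study of affiliation judgements from colaughter and cospeech:
#' criterion and sensitivity posterior means with 95% interval bounds on the
#' z scale, and AUC with 95% interval, for the four mode x speed conditions.
#' Shipped as plain text in `inst/extdata/condition_estimates.csv`.
#'
#' @return data.frame with one row per condition.
#' @export
reference_condition_estimates <- function() {
  path <- system.file("extdata", "condition_estimates.csv", package = "laughsdt",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Ground-truth parameters for the generative probit model
#'
#' @param beta numeric vector of length 8, ordered as [beta_labels()].
#' @param participant_sd non-negative standard deviations of the
#'   participant-varying effects (length 8, same order).
#' @param participant_corr 8x8 correlation matrix of the participant effects.
#' @param stimulus_sd non-negative sd of the stimulus-varying intercept.
#' @param seed integer seed for response simulation.
#' @return object of class `sdt_generative_params`.
#' @export
generative_params <- function(beta,
                              participant_sd = rep(0, 8),
                              participant_corr = diag(8),
                              stimulus_sd = 0,
                              seed = 1L) {
  beta <- as.numeric(beta)
  if (length(beta) != 8L) stop("beta must have length 8 (see beta_labels())")
  names(beta) <- beta_labels()
  participant_sd <- as.numeric(participant_sd)
  if (length(participant_sd) != 8L || any(participant_sd < 0))
    stop("participant_sd must be 8 non-negative values")
  names(participant_sd) <- beta_labels()
  C <- as.matrix(participant_corr)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10)) ||
      !isTRUE(all.equal(unname(diag(C)), rep(1, 8), tolerance = 1e-10)))
    stop("participant_corr must be a symmetric correlation matrix with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("participant_corr is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  if (stimulus_sd < 0) stop("stimulus_sd must be non-negative")
  structure(list(beta = beta, participant_sd = participant_sd,
                 participant_corr = C, stimulus_sd = stimulus_sd,
                 seed = as.integer(seed)),
            class = "sdt_generative_params")
}

#' @export
print.sdt_generative_params <- function(x, ...) {
  cat("Generative probit parameters (z scale):\n")
  print(round(x$beta, 3))
  cat("participant sds:", paste(round(x$participant_sd, 2), collapse = " "),
      "| stimulus sd:", round(x$stimulus_sd, 2), "\n")
  invisible(x)
}

#' Solve generative coefficients from condition-level z values
#'
#' Inverts the cell-combination map: given the criterion and sensitivity of
#' each mode x speed condition on the z scale, returns the unique
#' coefficient vector (reference coding) reproducing them.
#'
#' @param cells data.frame with columns mode, speed, criterion_z,
#'   sensitivity_z (one row per condition).
#' @return named numeric vector of length 8.
#' @export
params_from_cells <- function(cells) {
  need <- c("mode", "speed", "criterion_z", "sensitivity_z")
  if (!all(need %in% names(cells))) stop("cells must have columns ", paste(need, collapse = ", "))
  if (nrow(cells) != 4L) stop("cells must have one row per mode x speed condition")
  M <- matrix(0, 8, 8, dimnames = list(NULL, beta_labels()))
  z <- numeric(8)
  for (i in seq_len(4)) {
    M[i, ] <- cell_combination(cells$mode[i], cells$speed[i], "criterion")
    M[i + 4, ] <- cell_combination(cells$mode[i], cells$speed[i], "sensitivity")
    z[i] <- cells$criterion_z[i]
    z[i + 4] <- cells$sensitivity_z[i]
  }
  beta <- solve(M, z)
  names(beta) <- beta_labels()
  beta
}

#' Default generative ground truth
#'
#' Fixed effects are solved from the published condition-level estimates via
#' [params_from_cells()]; the random-effect scales are the package's chosen
#' study conditions: participant intercept sd 0.4, participant slope sds 0.2,
#' uncorrelated, stimulus intercept sd 0.5 (clips vary substantially in how
#' friendly they sound).
#'
#' @param seed integer simulation seed.
#' @return an [generative_params()] object.
#' @export
default_generative_params <- function(seed = 1L) {
  est <- reference_condition_estimates()
  beta <- params_from_cells(est)
  generative_params(beta = beta,
                    participant_sd = c(0.4, rep(0.2, 7)),
                    participant_corr = diag(8),
                    stimulus_sd = 0.5,
                    seed = seed)
}
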