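# Bernoulli-probit likelihood, numerically stable via the normal log-CDF.

#' Per-trial Bernoulli-probit log-likelihood
#'
#' \eqn{y \log\Phi(\eta) + (1-y)\log\Phi(-\eta)} computed with
#' `pnorm(log.p = TRUE)`, finite for |eta| well beyond 30.
#'
#' @param eta linear predictor(s).
#' @param y binary response(s) in \{0, 1\}.
#' @return numeric vector of log-likelihood contributions.
#' @export
bernoulli_probit_loglik <- function(eta, y) {
  if (any(!y %in% c(0, 1))) stop("responses must be 0 or 1")
  out <- numeric(length(eta))
  pos <- y == 1
  out[pos] <- pnorm(eta[pos], log.p = TRUE)
  out[!pos] <- pnorm(-eta[!pos], log.p = TRUE)
  out
}

#' Per-trial log-likelihood of a model at one parameter point
#'
#' The parameter point is a list with a named `beta` vector over the model's
#' fixed terms, and optionally `participant_effects` (matrix, one row per
#' participant level, columns = participant-varying terms) and
#' `stimulus_effects` (named or ordered vector over stimulus levels).
#'
#' @param model an [make_model()] spec.
#' @param point parameter point (list).
#' @param trials trial table with responses.
#' @return numeric vector, one entry per trial.
#' @export
log_likelihood <- function(model, point, trials) {
  X <- model_matrix(model, trials)
  beta <- point$beta
  if (is.null(names(beta))) names(beta) <- model$fixed_terms
  if (!all(model$fixed_terms %in% names(beta)))
    stop("parameter point lacks coefficients for: ",
         paste(setdiff(model$fixed_terms, names(beta)), collapse = ", "))
  eta <- drop(X %*% beta[model$fixed_terms])
  if (!is.null(point$participant_effects)) {
    pid <- as.integer(factor(trials$participant_id))
    U <- as.matrix(point$participant_effects)
    eta <- eta + rowSums(X * U[pid, , drop = FALSE])
  }
  if (!is.null(point$stimulus_effects)) {
    sid <- as.integer(factor(trials$stimulus_id))
    eta <- eta + point$stimulus_effects[sid]
  }
  bernoulli_probit_loglik(eta, trials$response)
}
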