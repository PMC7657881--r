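# PSIS-LOO expected log predictive density, and model comparison.

#' Draws x trials log-likelihood matrix for a fitted model
#'
#' Entry (s, n) is the Bernoulli-probit log-likelihood of trial n at
#' posterior draw s (fixed effects plus that draw's participant and stimulus
#' effects when the fit has them).
#'
#' @param fit an [fit_probit()] result.
#' @param trials trial table; must refer to the fit's participants and
#'   stimuli (defaults to the fitted data).
#' @return S x N matrix.
#' @export
pointwise_loglik <- function(fit, trials = fit$data) {
  E <- linear_predictor_draws(fit, trials)
  y <- trials$response
  if (any(!y %in% c(0, 1))) stop("responses must be 0 or 1")
  LL <- matrix(NA_real_, nrow(E), ncol(E))
  pos <- y == 1
  if (any(pos)) LL[, pos] <- pnorm(E[, pos, drop = FALSE], log.p = TRUE)
  if (any(!pos)) LL[, !pos] <- pnorm(-E[, !pos, drop = FALSE], log.p = TRUE)
  LL
}

# S x N matrix of linear predictors eta for every posterior draw
linear_predictor_draws <- function(fit, trials) {
  stopifnot(inherits(fit, "sdt_fit"))
  X <- model_matrix(fit$model, trials)
  n <- nrow(X)
  S <- nrow(fit$draws)
  B <- fit$draws[, paste0("b_", sanitize_label(fit$model$fixed_terms)),
                 drop = FALSE]
  E <- B %*% t(X)
  if (fit$include_ranef) {
    pidx <- match(as.character(trials$participant_id), fit$levels$participant)
    sidx <- match(as.character(trials$stimulus_id), fit$levels$stimulus)
    if (anyNA(pidx) || anyNA(sidx))
      stop("trials refer to participants or stimuli absent from the fit")
    for (k in seq_len(ncol(X))) {
      xk <- X[, k]
      active <- xk != 0
      if (!any(active)) next
      E[, active] <- E[, active, drop = FALSE] +
        fit$ranef$participant[, pidx[active], k, drop = FALSE][, , 1] *
        rep(xk[active], each = S)
    }
    E <- E + fit$ranef$stimulus[, sidx, drop = FALSE]
  }
  E
}

#' PSIS-LOO estimate of out-of-sample predictive accuracy
#'
#' Leave-one-out expected log predictive density estimated by
#' Pareto-smoothed self-normalized importance sampling, with the standard
#' error from the pointwise variance and LOOIC = -2 elpd.
#'
#' @param loglik S x N log-likelihood matrix (see [pointwise_loglik()]).
#' @return object of class `sdt_loo`: `elpd_loo`, `se_elpd`, `looic`,
#'   `pointwise_elpd`, `pareto_k`, and `flagged` (trials with k > 0.7).
#' @export
loo <- function(loglik) {
  if (!is.matrix(loglik) || any(!is.finite(loglik)))
    stop("loglik must be a finite S x N matrix")
  N <- ncol(loglik); S <- nrow(loglik)
  pointwise <- numeric(N)
  k <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-loglik[, i], log = TRUE)
    lw <- sm$log_weights - logsumexp(sm$log_weights)
    pointwise[i] <- logsumexp(lw + loglik[, i])
    k[i] <- sm$pareto_k
  }
  elpd <- sum(pointwise)
  se <- if (N > 1L) sqrt(N * var(pointwise)) else 0
  flagged <- which(is.finite(k) & k > 0.7)
  structure(list(elpd_loo = elpd, se_elpd = se, looic = -2 * elpd,
                 pointwise_elpd = pointwise, pareto_k = k, flagged = flagged,
                 n_draws = S),
            class = "sdt_loo")
}

#' @export
print.sdt_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd =", round(x$elpd_loo, 1), "(se", round(x$se_elpd, 1),
      "), LOOIC =", round(x$looic, 1), "\n")
  if (length(x$flagged))
    cat("  ", length(x$flagged), "trial(s) with Pareto k > 0.7\n")
  invisible(x)
}

#' Rank models by estimated out-of-sample error
#'
#' @param results named list of [loo()] results computed on the same trials.
#' @return data.frame of class `sdt_loo_comparison`, sorted by LOOIC
#'   ascending, with the elpd difference to the best model and the standard
#'   error of each difference (from the pointwise elpd differences).
#' @export
loo_compare <- function(results) {
  if (length(results) < 2L) stop("need at least 2 loo results to compare")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("model", seq_along(results))
  N <- vapply(results, function(r) length(r$pointwise_elpd), 0L)
  if (length(unique(N)) != 1L)
    stop("loo results cover different numbers of trials: ",
         paste(N, collapse = ", "))
  elpd <- vapply(results, `[[`, 0, "elpd_loo")
  best <- which.max(elpd)
  out <- data.frame(
    model = names(results),
    looic = vapply(results, `[[`, 0, "looic"),
    elpd_loo = elpd,
    elpd_diff = elpd - elpd[best],
    se_diff = vapply(seq_along(results), function(m) {
      d <- results[[best]]$pointwise_elpd - results[[m]]$pointwise_elpd
      if (m == best) 0 else sqrt(length(d) * var(d))
    }, 0),
    n_high_k = vapply(results, function(r) length(r$flagged), 0L),
    row.names = NULL)
  out <- out[order(out$looic), ]
  rownames(out) <- NULL
  class(out) <- c("sdt_loo_comparison", "data.frame")
  out
}
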