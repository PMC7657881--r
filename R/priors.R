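#' Weakly regularizing prior specification
#'
#' Fixed effects get independent normal(0, sd) priors; the default sd of 0.3
#' is the value selected by prior-predictive checking (see
#' [prior_predictive()]): it still allows a broad range of "friends"-rate
#' outcomes while making extreme rates improbable. Random-effect standard
#' deviations get half-normal(0, `re_sd_scale`) priors and the participant
#' correlation matrix an LKJ prior with the given concentration.
#'
#' @param fixed_effect_sd prior sd of the non-intercept fixed effects.
#' @param intercept_sd prior sd of the intercept (criterion); wider by
#'   default since the overall bias is less constrained a priori.
#' @param re_sd_scale scale of the half-normal priors on random-effect sds.
#' @param corr_concentration LKJ concentration (> 1 favours near-identity).
#' @return object of class `sdt_prior_spec`.
#' @export
prior_spec <- function(fixed_effect_sd = 0.3, intercept_sd = 1,
                       re_sd_scale = 0.3, corr_concentration = 2) {
  vals <- c(fixed_effect_sd, intercept_sd, re_sd_scale, corr_concentration)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior scales must be positive and finite")
  structure(list(fixed_effect_sd = fixed_effect_sd, intercept_sd = intercept_sd,
                 re_sd_scale = re_sd_scale,
                 corr_concentration = corr_concentration),
            class = "sdt_prior_spec")
}

#' Prior-predictive check over a grid of fixed-effect prior scales
#'
#' For each candidate prior sd, draws fixed effects (all of the model's
#' terms, intercept included) from normal(0, sd), random-effect sds from
#' half-normal(0, `re_sd_scale`), simulates the full experiment, and
#' records the overall rate of answering "friends". A good weakly
#' regularizing prior generates a broad rate distribution while giving low
#' probability to extreme rates.
#'
#' @param model an [make_model()] spec.
#' @param priors an [prior_spec()] (supplies `re_sd_scale`).
#' @param design trial design from [build_design()].
#' @param n_draws prior-predictive draws per grid point (>= 100).
#' @param sd_grid candidate prior sds.
#' @param extreme rate interval outside which a simulated overall rate
#'   counts as extreme.
#' @param seed RNG seed.
#' @return data.frame per grid point: `prior_sd`, mean/sd of the simulated
#'   overall rate, and `p_extreme`; the simulated rates are attached as
#'   attribute `"rates"` (a matrix, one column per grid point).
#' @export
prior_predictive <- function(model, priors, design, n_draws = 2000,
                             sd_grid = c(1, 0.5, 0.3, 0.1),
                             extreme = c(0.05, 0.95), seed = 1L) {
  stopifnot(inherits(model, "sdt_model_spec"))
  if (length(sd_grid) == 0L) stop("empty prior-sd grid")
  if (n_draws < 100L) stop("n_draws must be at least 100")
  X <- model_matrix(model, design)
  K <- ncol(X)
  pid <- as.integer(factor(design$participant_id))
  sid <- as.integer(factor(design$stimulus_id))
  J <- max(pid); I <- max(sid); n <- nrow(X)

  rates <- matrix(NA_real_, n_draws, length(sd_grid))
  colnames(rates) <- paste0("sd_", sd_grid)
  with_seed(seed, {
    for (g in seq_along(sd_grid)) {
      for (d in seq_len(n_draws)) {
        beta <- rnorm(K, 0, sd_grid[g])
        sd_p <- abs(rnorm(K, 0, priors$re_sd_scale))
        sd_s <- abs(rnorm(1, 0, priors$re_sd_scale))
        u <- matrix(rnorm(J * K), J, K) * rep(sd_p, each = J)
        s <- rnorm(I, 0, sd_s)
        eta <- drop(X %*% beta) + rowSums(X * u[pid, , drop = FALSE]) + s[sid]
        rates[d, g] <- mean(rbinom(n, 1L, pnorm(eta)))
      }
    }
  })
  out <- data.frame(prior_sd = sd_grid,
                    rate_mean = colMeans(rates),
                    rate_sd = apply(rates, 2, sd),
                    p_extreme = colMeans(rates < extreme[1] | rates > extreme[2]))
  attr(out, "rates") <- rates
  out
}
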