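#' Sampler configuration
#'
#' Defaults mirror the published analysis: two chains of 3000 iterations,
#' half used as warmup. `target_accept` and `max_trajectory_depth` record
#' the corresponding settings of gradient-based backends (adapt delta 0.99,
#' tree depth 20) for provenance and pluggability; the built-in
#' latent-variable Gibbs sampler does not use them (its conditional draws
#' are exact and it has no divergent-transition failure mode).
#'
#' @param n_chains number of independent chains.
#' @param n_iterations iterations per chain (warmup included).
#' @param warmup_fraction fraction of iterations discarded as warmup.
#' @param target_accept recorded target acceptance for gradient backends.
#' @param max_trajectory_depth recorded trajectory-depth cap.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return object of class `sdt_fit_config`.
#' @export
fit_config <- function(n_chains = 2, n_iterations = 3000,
                       warmup_fraction = 0.5, target_accept = 0.99,
                       max_trajectory_depth = 20, seed = 1L) {
  stopifnot(n_chains >= 1, n_iterations >= 20,
            warmup_fraction > 0, warmup_fraction < 1,
            target_accept > 0, target_accept < 1, max_trajectory_depth >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 warmup_fraction = warmup_fraction,
                 target_accept = target_accept,
                 max_trajectory_depth = as.integer(max_trajectory_depth),
                 seed = as.integer(seed)),
            class = "sdt_fit_config")
}

# draw from N(A^{-1} b, A^{-1}) given the upper-triangular cholesky R of A
draw_gaussian_chol <- function(R, b) {
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  drop(mu + backsolve(R, rnorm(ncol(R))))
}

# multivariate-normal log-likelihood of the participant effect rows U under
# covariance D C D, dropping constants; returns NULL if C is not PD
mvn_ranef_ll <- function(U, sd_p, Cmat) {
  K <- length(sd_p)
  Rc <- tryCatch(chol(Cmat), error = function(e) NULL)
  if (is.null(Rc)) return(NULL)
  Rs <- Rc %*% diag(pmax(sd_p, 1e-12), nrow = K)
  V <- backsolve(Rs, t(U), transpose = TRUE)
  list(ll = -nrow(U) * sum(log(diag(Rs))) - 0.5 * sum(V * V),
       logdet_C = 2 * sum(log(diag(Rc))))
}

#' Fit a multilevel Bayesian probit signal-detection model
#'
#' Posterior sampling uses latent-utility (data-augmentation) Gibbs updates:
#' the truncated-normal latent utilities, fixed effects, participant effect
#' vectors and stimulus intercepts all have exact conjugate conditional
#' draws; the participant-effect standard deviations, their correlations and
#' the stimulus-intercept sd are updated by adaptive random-walk Metropolis
#' on unconstrained scales (log sds, atanh correlations) under half-normal
#' and LKJ priors. Random effects are handled on the centered scale, which
#' is natural for conjugate augmentation.
#'
#' @param model an [make_model()] spec.
#' @param trials trial table with 0/1 responses (both values present).
#' @param priors an [prior_spec()].
#' @param config an [fit_config()].
#' @param include_ranef set `FALSE` to fit a plain (complete-pooling)
#'   Bayesian probit regression without participant or stimulus effects,
#'   e.g. for the closed-form signal-detection limit on pooled data.
#' @return object of class `sdt_fit`: `draws` (matrix of posterior draws,
#'   columns `b_<term>`, `sd_participant__<term>`,
#'   `cor_participant__<t1>__<t2>`, `sd_stimulus__intercept`), `chain`
#'   (chain index per draw), `ranef` (participant-effect array S x J x K and
#'   stimulus-intercept matrix S x I), `levels`, the data, and a
#'   `diagnostics` report.
#' @export
fit_probit <- function(model, trials, priors = prior_spec(),
                       config = fit_config(), include_ranef = TRUE) {
  stopifnot(inherits(model, "sdt_model_spec"),
            inherits(priors, "sdt_prior_spec"),
            inherits(config, "sdt_fit_config"))
  trials <- validate_trials(trials, require_response = TRUE)
  y <- as.integer(trials$response)
  if (length(unique(y)) < 2L)
    stop("degenerate data: both response values (0 and 1) must be present")

  X <- model_matrix(model, trials)
  K <- ncol(X)
  n <- nrow(X)
  pid <- factor(trials$participant_id)
  sid <- factor(trials$stimulus_id)
  J <- nlevels(pid); I <- nlevels(sid)
  pidx <- as.integer(pid); sidx <- as.integer(sid)
  prior_sd <- ifelse(colnames(X) == "intercept",
                     priors$intercept_sd, priors$fixed_effect_sd)

  n_iter <- config$n_iterations
  n_warm <- max(10L, as.integer(floor(config$warmup_fraction * n_iter)))
  n_keep <- n_iter - n_warm
  XtX <- crossprod(X)
  prior_prec <- diag(1 / prior_sd^2, nrow = K)

  # per-participant design crossproducts; identical in balanced designs,
  # which allows one shared cholesky per sweep
  xtx_p <- NULL; balanced <- FALSE
  if (include_ranef) {
    xtx_p <- lapply(seq_len(J), function(j) crossprod(X[pidx == j, , drop = FALSE]))
    balanced <- all(vapply(xtx_p, function(m) max(abs(m - xtx_p[[1]])) < 1e-9, TRUE))
    stim_count <- tabulate(sidx, I)
  }
  pairs <- if (K > 1L) t(combn(K, 2)) else matrix(integer(0), 0, 2)
  npair <- nrow(pairs)
  labels <- sanitize_label(colnames(X))
  par_names <- c(paste0("b_", labels),
                 if (include_ranef) c(paste0("sd_participant__", labels),
                                      if (npair) paste0("cor_participant__",
                                                        labels[pairs[, 1]], "__",
                                                        labels[pairs[, 2]]),
                                      "sd_stimulus__intercept"))

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    beta <- rep(0, K)
    u <- matrix(0, J, K)
    s <- rep(0, I)
    sd_p <- rep(0.1, K)
    Cmat <- diag(K)
    sd_s <- 0.1
    # adaptive RW-Metropolis state
    st_sd_p <- rep(0.4, K); st_cor <- rep(0.4, npair); st_sd_s <- 0.4
    ac_sd_p <- rep(0L, K); ac_cor <- rep(0L, npair); ac_sd_s <- 0L
    batch <- 50L

    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    u_draws <- if (include_ranef) array(NA_real_, c(n_keep, J, K))
    s_draws <- if (include_ranef) matrix(NA_real_, n_keep, I)

    for (it in seq_len(n_iter)) {
      ran <- if (include_ranef)
        rowSums(X * u[pidx, , drop = FALSE]) + s[sidx] else 0
      eta <- drop(X %*% beta) + ran

      # latent utilities: z ~ N(eta, 1) truncated by the observed response
      lo <- pnorm(-eta)
      uu <- runif(n)
      pr <- ifelse(y == 1L, lo + uu * (1 - lo), uu * lo)
      z <- eta + qnorm(pmin(pmax(pr, 1e-16), 1 - 1e-16))

      # fixed effects (conjugate)
      A <- XtX + prior_prec
      beta <- draw_gaussian_chol(chol(A), crossprod(X, z - ran))

      if (include_ranef) {
        # participant effect vectors (conjugate, shared cholesky if balanced)
        Sig <- diag(sd_p, nrow = K) %*% Cmat %*% diag(sd_p, nrow = K)
        Sinv <- chol2inv(chol(Sig + diag(1e-10, K)))
        resid_u <- z - drop(X %*% beta) - s[sidx]
        B <- rowsum(X * resid_u, pidx, reorder = TRUE)
        if (balanced) {
          Rj <- chol(xtx_p[[1]] + Sinv)
          Mu <- backsolve(Rj, backsolve(Rj, t(B), transpose = TRUE))
          u <- t(Mu + backsolve(Rj, matrix(rnorm(K * J), K, J)))
        } else {
          for (j in seq_len(J))
            u[j, ] <- draw_gaussian_chol(chol(xtx_p[[j]] + Sinv), B[j, ])
        }

        # stimulus intercepts (conjugate scalars); residual keeps the old s
        # out: z minus fixed effects minus participant effects only
        resid_s <- resid_u + s[sidx] - rowSums(X * u[pidx, , drop = FALSE])
        prec <- stim_count + 1 / sd_s^2
        s <- drop(rowsum(resid_s, sidx, reorder = TRUE)) / prec +
          rnorm(I) / sqrt(prec)

        # interweaved non-centered rescaling: conditionally on the scaled
        # effects, each scale enters the latent-Gaussian likelihood
        # linearly, so it has a conjugate truncated-normal draw. This
        # breaks the slow random walk between effects and their scales.
        resid_fix <- z - drop(X %*% beta)
        if (sd_s > 1e-8) {
          h <- s / sd_s
          r2 <- resid_fix - rowSums(X * u[pidx, , drop = FALSE])
          w <- h[sidx]
          prec <- sum(w * w) + 1 / priors$re_sd_scale^2
          mn <- sum(w * r2) / prec
          a <- pnorm(-mn * sqrt(prec))
          sd_s <- mn + qnorm(pmin(pmax(a + runif(1) * (1 - a), 1e-16),
                                  1 - 1e-16)) / sqrt(prec)
          s <- sd_s * h
        }
        if (all(sd_p > 1e-8)) {
          v <- u %*% diag(1 / sd_p, nrow = K)
          W <- X * v[pidx, , drop = FALSE]
          rbase <- resid_fix - s[sidx]
          for (k in seq_len(K)) {
            rk <- rbase - drop(W[, -k, drop = FALSE] %*% sd_p[-k])
            prec <- sum(W[, k]^2) + 1 / priors$re_sd_scale^2
            mn <- sum(W[, k] * rk) / prec
            a <- pnorm(-mn * sqrt(prec))
            sd_p[k] <- mn + qnorm(pmin(pmax(a + runif(1) * (1 - a), 1e-16),
                                       1 - 1e-16)) / sqrt(prec)
          }
          u <- v %*% diag(sd_p, nrow = K)
        }

        # stimulus sd: RW Metropolis on the log scale, half-normal prior
        lp_sd_s <- function(sig)
          sum(dnorm(s, 0, sig, log = TRUE)) +
            dnorm(sig, 0, priors$re_sd_scale, log = TRUE) + log(sig)
        prop <- sd_s * exp(st_sd_s * rnorm(1))
        if (log(runif(1)) < lp_sd_s(prop) - lp_sd_s(sd_s)) {
          sd_s <- prop; ac_sd_s <- ac_sd_s + 1L
        }

        # participant sds and correlations: RW Metropolis within Gibbs
        cur <- mvn_ranef_ll(u, sd_p, Cmat)
        for (k in seq_len(K)) {
          prop_sd <- sd_p
          prop_sd[k] <- sd_p[k] * exp(st_sd_p[k] * rnorm(1))
          cand <- mvn_ranef_ll(u, prop_sd, Cmat)
          lr <- cand$ll - cur$ll +
            dnorm(prop_sd[k], 0, priors$re_sd_scale, log = TRUE) -
            dnorm(sd_p[k], 0, priors$re_sd_scale, log = TRUE) +
            log(prop_sd[k]) - log(sd_p[k])
          if (log(runif(1)) < lr) {
            sd_p <- prop_sd; cur <- cand; ac_sd_p[k] <- ac_sd_p[k] + 1L
          }
        }
        if (npair) {
          eta_lkj <- priors$corr_concentration
          for (q in seq_len(npair)) {
            k <- pairs[q, 1]; l <- pairs[q, 2]
            th <- atanh(Cmat[k, l]) + st_cor[q] * rnorm(1)
            rho <- tanh(th)
            Cp <- Cmat; Cp[k, l] <- Cp[l, k] <- rho
            cand <- mvn_ranef_ll(u, sd_p, Cp)
            if (!is.null(cand)) {
              lr <- cand$ll - cur$ll +
                (eta_lkj - 1) * (cand$logdet_C - cur$logdet_C) +
                log1p(-rho^2) - log1p(-Cmat[k, l]^2)
              if (log(runif(1)) < lr) {
                Cmat <- Cp; cur <- cand; ac_cor[q] <- ac_cor[q] + 1L
              }
            }
          }
        }
      }

      # warmup adaptation of proposal scales (batches of 50)
      if (it <= n_warm && it %% batch == 0L) {
        tune <- function(step, acc) {
          rate <- acc / batch
          step * ifelse(rate > 0.5, 1.4, ifelse(rate < 0.25, 1 / 1.4, 1))
        }
        st_sd_s <- tune(st_sd_s, ac_sd_s); ac_sd_s <- 0L
        st_sd_p <- tune(st_sd_p, ac_sd_p); ac_sd_p <- rep(0L, K)
        if (npair) { st_cor <- tune(st_cor, ac_cor); ac_cor <- rep(0L, npair) }
      }

      if (it > n_warm) {
        idx <- it - n_warm
        row <- beta
        if (include_ranef)
          row <- c(row, sd_p, if (npair) Cmat[pairs], sd_s)
        draws[idx, ] <- row
        if (include_ranef) {
          u_draws[idx, , ] <- u
          s_draws[idx, ] <- s
        }
      }
    }
    list(draws = draws, u = u_draws, s = s_draws)
  }

  chains <- lapply(seq_len(config$n_chains),
                   function(cc) run_chain(config$seed + cc - 1L))
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(config$n_chains), each = n_keep)
  ranef <- NULL
  if (include_ranef) {
    u_all <- array(NA_real_, c(n_keep * config$n_chains, J, K))
    s_all <- do.call(rbind, lapply(chains, `[[`, "s"))
    for (cc in seq_len(config$n_chains))
      u_all[(cc - 1L) * n_keep + seq_len(n_keep), , ] <- chains[[cc]]$u
    ranef <- list(participant = u_all, stimulus = s_all)
  }

  fit <- structure(list(model = model, draws = draws, chain = chain_id,
                        ranef = ranef,
                        levels = list(participant = levels(pid),
                                      stimulus = levels(sid)),
                        data = trials, priors = priors, config = config,
                        include_ranef = include_ranef),
                   class = "sdt_fit")
  fit$diagnostics <- compute_diagnostics(fit)
  if (fit$diagnostics$n_divergences > 0)
    warning(fit$diagnostics$n_divergences, " divergent transitions recorded")
  fit
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("Bayesian multilevel probit SDT fit (model", x$model$level, "):",
      nrow(x$draws), "draws x", ncol(x$draws), "parameters,",
      max(x$chain), "chains\n")
  b <- x$draws[, grep("^b_", colnames(x$draws)), drop = FALSE]
  print(round(t(apply(b, 2, function(v)
    c(mean = mean(v), `2.5%` = quantile(v, 0.025, names = FALSE),
      `97.5%` = quantile(v, 0.975, names = FALSE)))), 3))
  invisible(x)
}
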