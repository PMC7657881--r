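#' Simulate binary affiliation judgements from the generative probit model
#'
#' For each trial the linear predictor is
#' \deqn{\eta = x'(\beta + u_j) + s_i}
#' with design codes \eqn{x} (reference coding, see [beta_labels()]),
#' participant effect vectors \eqn{u_j} drawn from a zero-mean multivariate
#' normal with covariance \eqn{D\,C\,D} (D = diag of `participant_sd`,
#' C = `participant_corr`), and stimulus intercepts \eqn{s_i} drawn
#' \eqn{N(0, \sigma_s^2)}. The two speed versions of a clip share one
#' stimulus intercept. Responses are Bernoulli with success probability
#' \eqn{\Phi(\eta)} (probability of answering "friends").
#'
#' @param design trial table from [build_design()].
#' @param params an [generative_params()] object.
#' @param liking if `TRUE`, also generate a 1-7 liking rating as a monotone
#'   transform of \eqn{\Phi(\eta)} plus noise (for I/O testing only; the
#'   package never models it).
#' @return the design with the response column filled in (and optionally a
#'   liking column); byte-identical for identical design/params/seed.
#' @export
simulate_responses <- function(design, params, liking = FALSE) {
  stopifnot(inherits(params, "sdt_generative_params"))
  X <- design_codes(design)
  pid <- factor(design$participant_id)
  sid <- factor(design$stimulus_id)
  J <- nlevels(pid)
  I <- nlevels(sid)

  with_seed(params$seed, {
    D <- diag(params$participant_sd, nrow = 8)
    Sigma <- D %*% params$participant_corr %*% D
    u <- if (all(params$participant_sd == 0)) {
      matrix(0, J, 8)
    } else {
      MASS::mvrnorm(J, mu = rep(0, 8), Sigma = Sigma, tol = 1e-6)
    }
    if (J == 1L) u <- matrix(u, 1, 8)
    s <- rnorm(I, 0, params$stimulus_sd)
    eta <- drop(X %*% params$beta) +
      rowSums(X * u[as.integer(pid), , drop = FALSE]) +
      s[as.integer(sid)]
    p <- pnorm(eta)
    out <- design
    out$response <- rbinom(nrow(design), 1L, p)
    if (liking) {
      out$liking <- pmin(7L, pmax(1L, as.integer(round(1 + 6 * p + rnorm(nrow(design), 0, 0.75)))))
    }
    attr(out, "stimuli") <- attr(design, "stimuli")
    out
  })
}
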