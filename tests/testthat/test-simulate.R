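test_that("null parameters give a coin-flip response rate", {
  d <- build_design(design_spec(n_participants = 60,
                                n_conversations_per_familiarity = 6, seed = 2))
  tr <- simulate_responses(d, generative_params(beta = rep(0, 8), seed = 2))
  se <- sqrt(0.25 / nrow(tr))
  expect_lt(abs(mean(tr$response) - 0.5), 4 * se)
})

test_that("a saturating familiarity effect separates the classes", {
  d <- build_design(design_spec(n_participants = 40,
                                n_conversations_per_familiarity = 6, seed = 3))
  tr <- simulate_responses(d, generative_params(beta = c(0, 5, rep(0, 6)),
                                                seed = 3))
  r <- condition_rates(tr)
  expect_true(all(r$rate[r$familiarity == "friends"] > 0.995))
  expect_true(all(abs(r$rate[r$familiarity == "strangers"] - 0.5) < 0.06))
})

test_that("cell rates are calibrated to the closed-form probit oracle", {
  # no random effects: each cell's rate must converge to Phi(cell z)
  beta <- table1_beta()
  d <- build_design(design_spec(n_participants = 1000,
                                n_conversations_per_familiarity = 6, seed = 5))
  tr <- simulate_responses(d, generative_params(beta = beta, seed = 5))
  r <- condition_rates(tr)
  est <- reference_condition_estimates()
  for (i in seq_len(nrow(est))) {
    z_str <- est$criterion_z[i]
    z_fri <- est$criterion_z[i] + est$sensitivity_z[i]
    for (fam in c("strangers", "friends")) {
      target <- pnorm(if (fam == "strangers") z_str else z_fri)
      cell <- r[r$mode == est$mode[i] & r$speed == est$speed[i] &
                  r$familiarity == fam, ]
      mc_se <- sqrt(target * (1 - target) / cell$n)
      expect_lt(abs(cell$rate - target), 3 * mc_se)
    }
  }
})

test_that("random effects shift marginal rates per the integral oracle", {
  # single-cell comparison: marginal P(friends) = E_a[Phi(beta + a)],
  # a ~ N(0, sd_p^2 + sd_s^2); numeric integration is the oracle
  beta0 <- 0.8
  sd_p <- 0.6; sd_s <- 0.5
  C <- diag(8)
  p <- generative_params(beta = c(beta0, rep(0, 7)),
                         participant_sd = c(sd_p, rep(0, 7)),
                         participant_corr = C, stimulus_sd = sd_s, seed = 9)
  d <- build_design(design_spec(n_participants = 500,
                                n_conversations_per_familiarity = 12, seed = 9))
  tr <- simulate_responses(d, p)
  oracle <- integrate(function(a) pnorm(beta0 + a) *
                        dnorm(a, 0, sqrt(sd_p^2 + sd_s^2)),
                      -Inf, Inf)$value
  closed <- pnorm(beta0 / sqrt(1 + sd_p^2 + sd_s^2))
  expect_equal(oracle, closed, tolerance = 1e-6)
  # clustered data: the Monte-Carlo error of the observed mean is dominated
  # by the 500 participant and 96 stimulus draws (delta method), not the
  # Bernoulli noise
  mc_se <- sqrt((dnorm(beta0) * sd_p)^2 / 500 +
                (dnorm(beta0) * sd_s)^2 / 96 + 0.25 / nrow(tr))
  expect_lt(abs(mean(tr$response) - oracle), 4 * mc_se)
})

test_that("simulation is byte-identical under a repeated seed", {
  d <- tiny_design(seed = 4)
  p <- default_generative_params(seed = 21)
  expect_identical(simulate_responses(d, p), simulate_responses(d, p))
  p2 <- default_generative_params(seed = 22)
  expect_false(identical(simulate_responses(d, p)$response,
                         simulate_responses(d, p2)$response))
})

test_that("optional liking ratings stay on the 1-7 scale", {
  d <- tiny_design(seed = 6)
  tr <- simulate_responses(d, default_generative_params(seed = 6), liking = TRUE)
  expect_true(all(tr$liking %in% 1:7))
  expect_silent(validate_trials(tr, require_response = TRUE))
})

test_that("an invalid correlation matrix is rejected", {
  C <- diag(8); C[1, 2] <- C[2, 1] <- 1.2
  expect_error(generative_params(beta = rep(0, 8), participant_corr = C),
               "positive semi-definite")
  expect_error(generative_params(beta = rep(0, 8),
                                 participant_sd = c(-1, rep(0, 7))),
               "non-negative")
})
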