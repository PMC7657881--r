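test_that("rank AUC equals exhaustive pairwise enumeration on small instances", {
  set.seed(2)
  for (rep_ in 1:8) {
    n <- sample(6:12, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    expect_identical(auc_rank(scores, pos), brute_auc(scores, pos))
  }
})

test_that("AUC endpoints and invariances hold", {
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(auc_rank(as.numeric(pos), pos), 1)
  set.seed(3)
  sc <- runif(20000)
  lab <- rbinom(20000, 1, 0.5) == 1
  expect_lt(abs(auc_rank(sc, lab) - 0.5), 0.02)
  # invariant to strictly increasing transforms
  sc2 <- runif(50); lab2 <- rep(c(TRUE, FALSE), 25)
  expect_equal(auc_rank(sc2, lab2), auc_rank(qnorm(sc2), lab2))
  expect_equal(auc_rank(sc2, lab2), auc_rank(sc2^3 + 2 * sc2, lab2))
  expect_error(auc_rank(runif(5), rep(TRUE, 5)), "one class")
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- runif(300)
  lab <- rbinom(300, 1, pnorm(2 * sc - 1)) == 1
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(auc_rank(sc, lab), ref, tolerance = 1e-12)
})

test_that("threshold-sweep curves bracket the rank AUC at grid resolution", {
  set.seed(5)
  scored <- data.frame(score = runif(400),
                       label = sample(c("friends", "strangers"), 400, TRUE))
  rc <- roc_points(scored)
  expect_equal(rc$points$fpr, sort(rc$points$fpr))
  expect_lt(abs(rc$auc - auc_rank(scored$score, scored$label)), 1 / 1000)
  # exhaustive thresholds make the trapezoid area exact
  rc_ex <- roc_points(scored, thresholds = "exhaustive")
  expect_equal(rc_ex$auc, auc_rank(scored$score, scored$label),
               tolerance = 1e-12)
})

test_that("degenerate score patterns trace the expected curves", {
  sep <- data.frame(score = c(rep(0.9, 6), rep(0.1, 6)),
                    label = rep(c("friends", "strangers"), each = 6))
  rc <- roc_points(sep)
  expect_true(any(rc$points$fpr == 0 & rc$points$tpr == 1))
  expect_equal(rc$auc, 1)

  flat <- data.frame(score = rep(0.5, 10),
                     label = rep(c("friends", "strangers"), 5))
  rc2 <- roc_points(flat)
  expect_equal(unique(paste(rc2$points$fpr, rc2$points$tpr)), c("0 0", "1 1"))
  expect_equal(rc2$auc, 0.5)

  expect_error(roc_points(data.frame(score = 0.5, label = "friends")),
               "strangers")
})

test_that("the equal-variance SDT population AUC is Phi(d/sqrt(2))", {
  set.seed(6)
  d_prime <- 0.7
  n <- 100000
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  dv <- rnorm(n, mean = ifelse(lab, d_prime, 0))
  expect_lt(abs(auc_rank(dv, lab) - pnorm(d_prime / sqrt(2))), 0.005)
})

test_that("posterior predictions are internally consistent", {
  p <- generative_params(beta = c(-0.1, 0.6, rep(0, 6)),
                         participant_sd = c(0.3, rep(0, 7)),
                         stimulus_sd = 0.3, seed = 23)
  tr <- simulate_responses(tiny_design(n_participants = 6, seed = 23), p)
  fit <- fit_probit(make_model(1), tr, prior_spec(),
                    quick_config(seed = 23, n_iterations = 300, n_chains = 1))
  pm <- predict_probabilities(fit)
  pd <- predict_probabilities(fit, mode = "per_draw")
  expect_true(all(pm$score >= 0 & pm$score <= 1))
  expect_equal(pm$score, colMeans(pd), tolerance = 1e-12)

  a <- auc_posterior(fit)
  expect_true(all(a$draws >= 0 & a$draws <= 1))
  expect_true(a$lower <= a$mean && a$mean <= a$upper)

  # constant draws give a zero-width AUC interval
  fit0 <- fit
  fit0$draws[] <- rep(colMeans(fit$draws), each = nrow(fit$draws))
  fit0$ranef$participant[] <- 0
  fit0$ranef$stimulus[] <- 0
  a0 <- auc_posterior(fit0)
  expect_equal(a0$upper - a0$lower, 0)
})

test_that("a fit with null parameters scores every trial at one half", {
  p <- generative_params(beta = c(0, 0.4, rep(0, 6)), seed = 27)
  tr <- simulate_responses(tiny_design(n_participants = 4, seed = 27), p)
  fit <- fit_probit(make_model(1), tr, prior_spec(),
                    quick_config(seed = 27, n_iterations = 200, n_chains = 1))
  fit$draws[] <- 0
  fit$ranef$participant[] <- 0
  fit$ranef$stimulus[] <- 0
  expect_equal(unique(predict_probabilities(fit)$score), 0.5)
})
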