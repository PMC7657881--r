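test_that("cell combinations expand the reference coding correctly", {
  w <- cell_combination("cospeech", "original", "criterion")
  expect_equal(unname(w["intercept"]), 1)
  expect_equal(sum(w), 1)

  w <- cell_combination("cospeech", "original", "sensitivity")
  expect_equal(unname(w["familiarity"]), 1)
  expect_equal(sum(w), 1)

  # symbolic derivation oracle: difference the Model 4 linear predictor
  # between friends and strangers for each cell and compare weights
  for (mo in c("colaughter", "cospeech")) for (sp in c("original", "sped-up")) {
    mk <- function(fam) {
      tr <- data.frame(familiarity = fam, mode = mo, speed = sp)
      drop(design_codes(tr))
    }
    expect_equal(cell_combination(mo, sp, "sensitivity"),
                 mk("friends") - mk("strangers"))
    expect_equal(cell_combination(mo, sp, "criterion"), mk("strangers"))
  }

  w <- cell_combination("colaughter", "sped-up", "sensitivity")
  expect_equal(names(w[w == 1]),
               c("familiarity", "familiarity:speed", "familiarity:talk",
                 "familiarity:talk:speed"))
  expect_error(cell_combination("humming", "original"), "unknown mode")
})

test_that("the generative betas invert the published condition table", {
  est <- reference_condition_estimates()
  beta <- params_from_cells(est)
  for (i in seq_len(nrow(est))) {
    expect_equal(sum(cell_combination(est$mode[i], est$speed[i], "criterion") * beta),
                 est$criterion_z[i], tolerance = 1e-12)
    expect_equal(sum(cell_combination(est$mode[i], est$speed[i], "sensitivity") * beta),
                 est$sensitivity_z[i], tolerance = 1e-12)
  }
})

test_that("z transforms reproduce every published z/percent pair", {
  est <- reference_condition_estimates()
  printed_crit <- c(41, 50, 49, 56)
  printed_sens <- c(13, 9, 26, 24)
  ord <- match(c("cospeech.original", "cospeech.sped-up",
                 "colaughter.original", "colaughter.sped-up"),
               paste(est$mode, est$speed, sep = "."))
  est <- est[ord, ]
  expect_equal(round(z_to_percent(est$criterion_z)), printed_crit)
  expect_equal(round(sensitivity_to_percent(est$criterion_z, est$sensitivity_z)),
               printed_sens)
})

test_that("transform monotonicity and zero properties hold", {
  z <- seq(-3, 3, 0.1)
  expect_true(all(diff(z_to_percent(z)) > 0))
  expect_equal(z_to_percent(0), 50)
  expect_equal(sensitivity_to_percent(0.7, 0), 0)
  expect_true(all(sensitivity_to_percent(z, 0.5) > 0))
  expect_true(all(sensitivity_to_percent(z, -0.5) < 0))
})

test_that("summarize_draws reports interval and sign-credibility", {
  set.seed(20)
  sym <- rnorm(20000)
  s <- summarize_draws(sym)
  expect_lt(abs(s["credibility"] - 50), 2)
  expect_lt(abs(s["lower"] - qnorm(0.025)), 0.05)
  expect_lt(abs(s["upper"] - qnorm(0.975)), 0.05)

  expect_equal(unname(summarize_draws(abs(rnorm(500)) + 0.01)["credibility"]), 100)
  expect_error(summarize_draws(rnorm(10)), "at least 100")
})

test_that("contrasts at the published posterior means give the printed values", {
  beta <- table1_beta()
  draws <- constant_draws(beta)
  sens_diff <- contrast(draws, list(
    list(mode = "colaughter", speed = "original", quantity = "sensitivity", weight = 1),
    list(mode = "cospeech", speed = "original", quantity = "sensitivity", weight = -1)))
  expect_equal(unname(sens_diff["mean"]), 0.37, tolerance = 1e-10)
  expect_equal(unname(sens_diff["upper"] - sens_diff["lower"]), 0)

  crit_speed <- contrast(draws, list(
    list(mode = "colaughter", speed = "sped-up", quantity = "criterion", weight = 1),
    list(mode = "colaughter", speed = "original", quantity = "criterion", weight = -1)))
  expect_equal(unname(crit_speed["mean"]), 0.19, tolerance = 1e-10)

  expect_error(contrast(draws, list(
    list(mode = "colaughter", speed = "original", quantity = "criterion", weight = 1),
    list(mode = "colaughter", speed = "original", quantity = "criterion", weight = -1))),
    "zero weight")
})

test_that("sdt_summary reproduces the published table from matched draws", {
  draws <- constant_draws(table1_beta())
  summ <- sdt_summary(draws)
  est <- reference_condition_estimates()
  m <- match(paste(summ$mode, summ$speed), paste(est$mode, est$speed))
  expect_equal(summ$criterion_z, est$criterion_z[m], tolerance = 1e-10)
  expect_equal(summ$sensitivity_z, est$sensitivity_z[m], tolerance = 1e-10)
  expect_equal(round(summ$criterion_pct),
               round(z_to_percent(est$criterion_z[m])))
  # transform-of-mean and mean-of-transform agree for constant draws
  expect_equal(summ$criterion_pct, summ$criterion_pct_draws, tolerance = 1e-10)
})

test_that("the two percentage conventions stay close for moderate z", {
  # nonlinearity discipline: on dispersed draws with |z| <= 1 the transform
  # of the mean and the mean of the transform differ by under a point
  set.seed(9)
  beta <- table1_beta()
  draws <- constant_draws(beta, S = 4000) +
    matrix(rnorm(4000 * 8, 0, 0.05), 4000, 8)
  summ <- sdt_summary(draws)
  expect_true(all(abs(summ$criterion_pct - summ$criterion_pct_draws) < 1))
  expect_true(all(abs(summ$sensitivity_pct - summ$sensitivity_pct_draws) < 1))
})
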