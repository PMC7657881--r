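# Signal-detection summaries: condition-wise criterion and sensitivity on
# z and percentage scales, contrasts and sign-credibility.

#' The four mode x speed condition cells
#'
#' @return data.frame with columns mode and speed.
#' @export
sdt_cells <- function() {
  data.frame(mode = rep(c("cospeech", "colaughter"), each = 2),
             speed = rep(c("original", "sped-up"), 2),
             stringsAsFactors = FALSE)
}

#' Coefficient weights of a cell's criterion or sensitivity
#'
#' Under the reference coding (strangers / cospeech / original speed), a
#' condition's criterion is the linear combination of coefficients active
#' for stranger stimuli in that cell, and its sensitivity is the
#' friends-minus-strangers difference: the familiarity terms active in the
#' cell.
#'
#' @param mode `"colaughter"` or `"cospeech"`.
#' @param speed `"original"` or `"sped-up"`.
#' @param quantity `"criterion"` or `"sensitivity"`.
#' @return named numeric weight vector over [beta_labels()].
#' @export
#' @examples
#' cell_combination("colaughter", "sped-up", "sensitivity")
cell_combination <- function(mode, speed,
                             quantity = c("criterion", "sensitivity")) {
  quantity <- match.arg(quantity)
  if (!mode %in% c("colaughter", "cospeech")) stop("unknown mode: ", mode)
  if (!speed %in% c("original", "sped-up")) stop("unknown speed: ", speed)
  w <- setNames(numeric(8), beta_labels())
  laugh <- mode == "colaughter"
  sped <- speed == "sped-up"
  if (quantity == "criterion") {
    w["intercept"] <- 1
    if (laugh) w["talk"] <- 1
    if (sped) w["speed"] <- 1
    if (laugh && sped) w["talk:speed"] <- 1
  } else {
    w["familiarity"] <- 1
    if (laugh) w["familiarity:talk"] <- 1
    if (sped) w["familiarity:speed"] <- 1
    if (laugh && sped) w["familiarity:talk:speed"] <- 1
  }
  w
}

#' Criterion z value to the percentage scale
#'
#' 100 * Phi(z): the percentage of "friends" answers expected for stimuli
#' actually produced by strangers.
#'
#' @param z criterion on the z scale.
#' @return percentage (0-100), unrounded; round for display.
#' @export
z_to_percent <- function(z) 100 * pnorm(z)

#' Sensitivity as a percentage-point difference
#'
#' 100 * (Phi(c + d) - Phi(c)): the increase in the probability of
#' answering "friends" when the stimulus really is produced by friends.
#'
#' @param criterion_z criterion c on the z scale.
#' @param sensitivity_z sensitivity d on the z scale.
#' @return percentage points, unrounded.
#' @export
sensitivity_to_percent <- function(criterion_z, sensitivity_z) {
  100 * (pnorm(criterion_z + sensitivity_z) - pnorm(criterion_z))
}

#' Posterior summary of a draw vector
#'
#' Mean, central 95% interval, and the sign-credibility: the percentage of
#' draws on the same side of zero as the mean (50 for a zero mean).
#'
#' @param x numeric vector of posterior draws (>= 100).
#' @return named numeric vector: mean, lower, upper, credibility.
#' @export
summarize_draws <- function(x) {
  if (length(x) < 100L) stop("need at least 100 draws to summarize")
  m <- mean(x)
  cred <- if (m > 0) 100 * mean(x > 0) else if (m < 0) 100 * mean(x < 0) else 50
  c(mean = m,
    lower = quantile(x, 0.025, names = FALSE),
    upper = quantile(x, 0.975, names = FALSE),
    credibility = cred)
}

# posterior draws of a weighted combination of the 8 coefficients; accepts a
# fitted model or a draws matrix with b_<term> columns (missing terms = 0)
beta_draw_matrix <- function(fit) {
  draws <- if (inherits(fit, "sdt_fit")) fit$draws else as.matrix(fit)
  out <- matrix(0, nrow(draws), 8,
                dimnames = list(NULL, beta_labels()))
  for (lab in beta_labels()) {
    col <- paste0("b_", sanitize_label(lab))
    if (col %in% colnames(draws)) out[, lab] <- draws[, col]
  }
  out
}

#' Posterior summary of a contrast over cell quantities
#'
#' Evaluates a weighted combination of condition-level criteria and/or
#' sensitivities draw by draw, then summarizes. Weights are given as a list
#' of terms, each `list(mode=, speed=, quantity=, weight=)`.
#'
#' @param fit an [fit_probit()] result (or a draws matrix with `b_` columns).
#' @param terms list of weighted cell quantities.
#' @return [summarize_draws()] vector of the contrast.
#' @export
#' @examples
#' # sensitivity difference colaughter - cospeech at original speed:
#' # contrast(fit, list(list(mode="colaughter", speed="original",
#' #                         quantity="sensitivity", weight=1),
#' #                    list(mode="cospeech", speed="original",
#' #                         quantity="sensitivity", weight=-1)))
contrast <- function(fit, terms) {
  w <- setNames(numeric(8), beta_labels())
  for (tm in terms)
    w <- w + tm$weight * cell_combination(tm$mode, tm$speed, tm$quantity)
  if (all(w == 0)) stop("contrast has zero weight on every coefficient")
  draws <- beta_draw_matrix(fit) %*% w
  summarize_draws(drop(draws))
}

#' Condition-wise criterion and sensitivity table
#'
#' One row per mode x speed condition with the posterior mean and 95%
#' interval of criterion and sensitivity on the z scale, sign-credibility,
#' and both on the percentage scale. Percentages are reported as the
#' transform of the posterior-mean z (`*_pct`), which reproduces the
#' published table; the posterior mean of the transformed draws is also
#' provided (`*_pct_draws`) since the transform is nonlinear.
#'
#' @param fit an [fit_probit()] result or draws matrix.
#' @return data.frame with 4 rows.
#' @export
sdt_summary <- function(fit) {
  B <- beta_draw_matrix(fit)
  cells <- sdt_cells()
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cz <- drop(B %*% cell_combination(cells$mode[i], cells$speed[i], "criterion"))
    dz <- drop(B %*% cell_combination(cells$mode[i], cells$speed[i], "sensitivity"))
    sc <- summarize_draws(cz); sd_ <- summarize_draws(dz)
    data.frame(mode = cells$mode[i], speed = cells$speed[i],
               criterion_z = sc["mean"], criterion_lo = sc["lower"],
               criterion_hi = sc["upper"], criterion_cred = sc["credibility"],
               sensitivity_z = sd_["mean"], sensitivity_lo = sd_["lower"],
               sensitivity_hi = sd_["upper"], sensitivity_cred = sd_["credibility"],
               criterion_pct = z_to_percent(sc["mean"]),
               sensitivity_pct = sensitivity_to_percent(sc["mean"], sd_["mean"]),
               criterion_pct_draws = mean(z_to_percent(cz)),
               sensitivity_pct_draws = mean(sensitivity_to_percent(cz, dz)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
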