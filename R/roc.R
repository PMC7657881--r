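# Posterior-predictive ROC curves and AUC.

#' Predicted "friends" probabilities per trial
#'
#' @param fit an [fit_probit()] result.
#' @param trials trial table (defaults to the fitted data).
#' @param mode `"posterior_mean"` (one score per trial: the mean over draws
#'   of \eqn{\Phi(\eta_s)}) or `"per_draw"` (an S x N matrix of scores).
#' @return for `posterior_mean`, a data.frame of scored trials (score,
#'   label, mode, speed); for `per_draw`, the score matrix with the scored
#'   trial frame attached as attribute `"trials"`.
#' @export
predict_probabilities <- function(fit, trials = fit$data,
                                  mode = c("posterior_mean", "per_draw")) {
  mode <- match.arg(mode)
  P <- pnorm(linear_predictor_draws(fit, trials))
  meta <- data.frame(score = colMeans(P),
                     label = trials$familiarity,
                     mode = trials$mode, speed = trials$speed,
                     stringsAsFactors = FALSE)
  if (mode == "posterior_mean") return(meta)
  attr(P, "trials") <- meta
  P
}

check_both_classes <- function(labels) {
  for (cls in c("friends", "strangers"))
    if (!any(labels == cls))
      stop("cannot build an ROC curve: no '", cls, "' trials present")
}

#' ROC curve by threshold sweep
#'
#' For each threshold t, a trial with score >= t is classified "friends";
#' sensitivity is the share of friend stimuli correctly identified and
#' specificity the share of stranger stimuli correctly identified. The
#' curve is stored in the conventional (FPR, TPR) orientation with
#' endpoints (0,0) and (1,1).
#'
#' @param scored data.frame with `score` and `label` columns (see
#'   [predict_probabilities()]).
#' @param thresholds threshold grid; `"exhaustive"` uses every observed
#'   score (plus sentinels), which makes the trapezoid area exact.
#' @return object of class `sdt_roc`: `points` (threshold, sensitivity,
#'   specificity, fpr, tpr) and trapezoid `auc`.
#' @export
roc_points <- function(scored, thresholds = seq(0, 1, length.out = 1001)) {
  check_both_classes(scored$label)
  if (identical(thresholds, "exhaustive"))
    thresholds <- c(-Inf, sort(unique(scored$score)), Inf)
  pos <- scored$label == "friends"
  sens <- vapply(thresholds, function(t) mean(scored$score[pos] >= t), 0)
  spec <- vapply(thresholds, function(t) mean(scored$score[!pos] < t), 0)
  pts <- data.frame(threshold = thresholds, sensitivity = sens,
                    specificity = spec, fpr = 1 - spec, tpr = sens)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  fpr <- c(0, pts$fpr, 1); tpr <- c(0, pts$tpr, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "sdt_roc")
}

#' @export
print.sdt_roc <- function(x, ...) {
  cat("ROC curve over", nrow(x$points), "thresholds; trapezoid AUC =",
      round(x$auc, 3), "\n")
  invisible(x)
}

#' Rank-statistic AUC
#'
#' The probability that a randomly chosen friend-stimulus trial outscores a
#' randomly chosen stranger-stimulus trial, ties counted half (the
#' Mann-Whitney identity).
#'
#' @param scores numeric prediction scores.
#' @param labels trial labels (`"friends"` / `"strangers"`) or logical with
#'   `TRUE` = friends.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "friends"
  if (is.character(labels) || is.factor(labels)) check_both_classes(labels)
  n1 <- as.numeric(sum(pos)); n0 <- as.numeric(sum(!pos))
  if (n1 == 0 || n0 == 0)
    stop("cannot compute AUC: only one class present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior distribution of AUC
#'
#' Computes the rank AUC for every posterior draw's predicted scores,
#' optionally within one mode x speed cell, and summarizes.
#'
#' @param fit an [fit_probit()] result.
#' @param trials trial table (defaults to the fitted data).
#' @param mode,speed optional cell filter.
#' @return list: `mean`, `lower`, `upper` (95% interval) and `draws`.
#' @export
auc_posterior <- function(fit, trials = fit$data, mode = NULL, speed = NULL) {
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(mode)) keep <- keep & trials$mode == mode
  if (!is.null(speed)) keep <- keep & trials$speed == speed
  sub <- trials[keep, , drop = FALSE]
  check_both_classes(sub$familiarity)
  P <- predict_probabilities(fit, sub, mode = "per_draw")
  pos <- sub$familiarity == "friends"
  draws <- apply(P, 1, function(sc) auc_rank(sc, pos))
  list(mean = mean(draws),
       lower = quantile(draws, 0.025, names = FALSE),
       upper = quantile(draws, 0.975, names = FALSE),
       draws = draws)
}
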