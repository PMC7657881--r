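# Independent oracles and small fixtures used across the suite.

# naive per-row Bernoulli-probit log-likelihood (direct log(pnorm), no
# stability tricks) -- the brute-force oracle for log_likelihood()
naive_probit_ll <- function(eta, y) {
  sapply(seq_along(eta), function(i) {
    p <- pnorm(eta[i])
    if (y[i] == 1) log(p) else log(1 - p)
  })
}

# exhaustive pairwise AUC: probability a friend trial outscores a stranger
# trial, ties half credit
brute_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# small factorial design: 2 conversations per familiarity -> 16 stimuli
tiny_design <- function(n_participants = 4, seed = 1) {
  build_design(design_spec(n_participants = n_participants,
                           n_conversations_per_familiarity = 2,
                           seed = seed))
}

# reduced-scale design used for fitting tests: 24 x 48
reduced_design <- function(seed = 1, n_participants = 24) {
  build_design(design_spec(n_participants = n_participants,
                           n_conversations_per_familiarity = 6,
                           seed = seed))
}

quick_config <- function(seed = 1, n_iterations = 600, n_chains = 2) {
  fit_config(n_chains = n_chains, n_iterations = n_iterations, seed = seed)
}

# a degenerate fit-like object with fixed coefficient draws and no random
# effects, for testing draw-based summaries independently of the sampler
constant_draws <- function(beta, S = 200) {
  m <- matrix(rep(beta, each = S), S, length(beta))
  colnames(m) <- paste0("b_", gsub(":", "_x_", names(beta), fixed = TRUE))
  m
}

table1_beta <- function() {
  params_from_cells(reference_condition_estimates())
}
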