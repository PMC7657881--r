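#' Define one of the five nested probit signal-detection models
#'
#' The model ladder separates response bias from discriminability:
#' Model 0 is intercept-only (pure criterion); Model 1 adds the familiarity
#' effect (sensitivity); Model 2 lets vocalization mode (talk) move both
#' criterion (main effect) and sensitivity (familiarity:talk interaction);
#' Model 3 does the same for playback speed; Model 4 carries all eight
#' design codes including the three-way interaction. Every fixed term also
#' varies by participant (correlated random slopes) and the intercept varies
#' by stimulus.
#'
#' @param level integer 0-4.
#' @return object of class `sdt_model_spec` with elements `level`,
#'   `fixed_terms`, `participant_varying`, `stimulus_varying`.
#' @export
#' @examples
#' make_model(2)$fixed_terms
make_model <- function(level) {
  if (length(level) != 1L || !level %in% 0:4)
    stop("level must be a single integer in 0..4")
  level <- as.integer(level)
  terms <- switch(as.character(level),
    "0" = "intercept",
    "1" = c("intercept", "familiarity"),
    "2" = c("intercept", "familiarity", "talk", "familiarity:talk"),
    "3" = c("intercept", "familiarity", "speed", "familiarity:speed"),
    "4" = beta_labels())
  structure(list(level = level,
                 fixed_terms = terms,
                 participant_varying = terms,
                 stimulus_varying = "intercept"),
            class = "sdt_model_spec")
}

#' @export
print.sdt_model_spec <- function(x, ...) {
  cat("Probit SDT model", x$level, "\n  fixed (participant-varying):",
      paste(x$fixed_terms, collapse = ", "),
      "\n  stimulus-varying: intercept\n")
  invisible(x)
}

#' Model design matrix for a trial table
#'
#' @param model an [make_model()] spec.
#' @param trials trial table.
#' @return numeric matrix with one column per fixed term.
#' @export
model_matrix <- function(model, trials) {
  stopifnot(inherits(model, "sdt_model_spec"))
  design_codes(trials, terms = model$fixed_terms)
}
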