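#' Specify the factorial listening-experiment design
#'
#' Describes a within-participant judgement experiment in which every
#' listener hears short clips of two vocalization modes (colaughter and
#' cospeech) recorded from conversations between friend or stranger dyads,
#' each clip in one of two speed versions (original or time-compressed).
#' Defaults reproduce the published design: 108 participants, 24
#' conversations (12 per familiarity), the first and last qualifying clip of
#' each mode per conversation (96 stimuli), and two counterbalanced lists
#' that split each mode's sped-up clips in half.
#'
#' @param n_participants number of listeners.
#' @param n_conversations_per_familiarity conversations per dyad type.
#' @param clips_per_conversation_per_mode clips excised per conversation and
#'   mode (2 = first and last occurrence).
#' @param modes vocalization modes (factor levels, reference first... the
#'   reference level for design coding is `"cospeech"` regardless of order).
#' @param speeds speed versions; reference level `"original"`.
#' @param n_lists number of counterbalancing lists.
#' @param seed integer seed controlling list assignment and trial order.
#' @return an object of class `sdt_design_spec`.
#' @export
#' @examples
#' spec <- design_spec(n_participants = 4, n_conversations_per_familiarity = 2)
#' nrow(build_design(spec))
design_spec <- function(n_participants = 108,
                        n_conversations_per_familiarity = 12,
                        clips_per_conversation_per_mode = 2,
                        modes = c("colaughter", "cospeech"),
                        speeds = c("original", "sped-up"),
                        n_lists = 2,
                        seed = 1L) {
  stopifnot(n_participants >= 1, n_conversations_per_familiarity >= 1,
            clips_per_conversation_per_mode >= 1, n_lists >= 1)
  if (!setequal(modes, c("colaughter", "cospeech")))
    stop("modes must be the two levels 'colaughter' and 'cospeech'")
  if (!setequal(speeds, c("original", "sped-up")))
    stop("speeds must be the two levels 'original' and 'sped-up'")
  out <- list(n_participants = as.integer(n_participants),
              n_conversations_per_familiarity = as.integer(n_conversations_per_familiarity),
              clips_per_conversation_per_mode = as.integer(clips_per_conversation_per_mode),
              modes = c("colaughter", "cospeech"),
              speeds = c("original", "sped-up"),
              n_lists = as.integer(n_lists),
              seed = as.integer(seed))
  class(out) <- "sdt_design_spec"
  out
}

#' @export
print.sdt_design_spec <- function(x, ...) {
  n_stim <- 2L * x$n_conversations_per_familiarity *
    x$clips_per_conversation_per_mode * length(x$modes)
  cat("Affiliation-judgement design:", x$n_participants, "participants x",
      n_stim, "stimuli,", x$n_lists, "lists (seed", x$seed, ")\n")
  invisible(x)
}

occurrence_levels <- function(k) {
  if (k == 1L) "first" else if (k == 2L) c("first", "last") else paste0("occ", seq_len(k))
}

#' Enumerate the stimulus set implied by a design specification
#'
#' One row per clip: conversation, dyad familiarity, vocalization mode and
#' occurrence within the conversation. The stimulus is the clip; its two
#' speed versions share the identifier (and, downstream, the stimulus-level
#' random intercept).
#'
#' @param spec an [design_spec()] object.
#' @return data.frame with columns stimulus_id, conversation_id, familiarity,
#'   mode, occurrence.
#' @export
build_stimuli <- function(spec) {
  stopifnot(inherits(spec, "sdt_design_spec"))
  fams <- c("friends", "strangers")
  occ <- occurrence_levels(spec$clips_per_conversation_per_mode)
  conv <- expand.grid(conv_idx = seq_len(spec$n_conversations_per_familiarity),
                      familiarity = fams, stringsAsFactors = FALSE)
  conv$conversation_id <- sprintf("conv%02d_%s", conv$conv_idx,
                                  substr(conv$familiarity, 1, 3))
  grid <- merge(conv,
                expand.grid(mode = spec$modes, occurrence = occ,
                            stringsAsFactors = FALSE),
                by = NULL)
  grid$stimulus_id <- sprintf("%s_%s_%s", grid$conversation_id, grid$mode,
                              grid$occurrence)
  grid <- grid[order(grid$familiarity, grid$conv_idx, grid$mode, grid$occurrence), ]
  rownames(grid) <- NULL
  grid[, c("stimulus_id", "conversation_id", "familiarity", "mode", "occurrence")]
}

#' Build the trial-level design (without responses)
#'
#' Enumerates every participant x stimulus presentation. The speed version a
#' participant hears is fixed by their list: within each familiarity x mode
#' cell the clips are split evenly across lists (a seeded split, balanced
#' over occurrence when possible), and list `l` hears its own share sped-up
#' and the remainder at original speed, so each list carries half of each
#' mode's sped-up clips at the default two lists. Participants alternate
#' lists by index; each participant's presentation order is an independent
#' seeded permutation.
#'
#' @param spec an [design_spec()] object.
#' @return data.frame of trials with columns participant_id, list_id,
#'   trial_index (0-based presentation position), stimulus_id, familiarity,
#'   mode, speed and an all-`NA` response column; the stimulus table is
#'   attached as attribute `"stimuli"`.
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "sdt_design_spec"))
  stimuli <- build_stimuli(spec)
  n_stim <- nrow(stimuli)

  with_seed(spec$seed, {
    # list assignment of sped-up clips: split every familiarity x mode cell
    sped_list <- integer(n_stim)
    for (fam in unique(stimuli$familiarity)) {
      for (mo in spec$modes) {
        cell <- which(stimuli$familiarity == fam & stimuli$mode == mo)
        if (length(cell) %% spec$n_lists != 0L)
          stop(sprintf("cannot split the %d clips of cell (%s, %s) evenly across %d lists",
                       length(cell), fam, mo, spec$n_lists))
        # balance the split over occurrence where occurrence cells allow it
        occs <- split(cell, stimuli$occurrence[cell])
        if (all(lengths(occs) %% spec$n_lists == 0L)) {
          for (oc in occs) {
            grp <- rep(seq_len(spec$n_lists), length.out = length(oc))
            sped_list[sample(oc)] <- grp
          }
        } else {
          grp <- rep(seq_len(spec$n_lists), each = length(cell) / spec$n_lists)
          sped_list[sample(cell)] <- grp
        }
      }
    }

    trials <- vector("list", spec$n_participants)
    for (j in seq_len(spec$n_participants)) {
      list_id <- (j - 1L) %% spec$n_lists + 1L
      speed <- ifelse(sped_list == list_id, "sped-up", "original")
      ord <- sample.int(n_stim)
      trials[[j]] <- data.frame(
        participant_id = sprintf("p%03d", j),
        list_id = sprintf("list%d", list_id),
        trial_index = order(ord) - 1L,
        stimulus_id = stimuli$stimulus_id,
        familiarity = stimuli$familiarity,
        mode = stimuli$mode,
        speed = speed,
        response = NA_integer_,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, trials)
    out <- out[order(out$participant_id, out$trial_index), ]
    rownames(out) <- NULL
    attr(out, "stimuli") <- stimuli
    out
  })
}

#' Labels of the eight probit design codes
#'
#' Reference coding with 0/1 indicators: familiarity = 1 for friends,
#' talk = 1 for colaughter, speed = 1 for sped-up; reference levels are
#' strangers, cospeech and original speed. Order matches the generative
#' coefficient vector: intercept, familiarity, talk, speed, then the
#' two-way interactions familiarity:speed, familiarity:talk, talk:speed,
#' and the three-way interaction.
#'
#' @return character vector of length 8.
#' @export
beta_labels <- function() {
  c("intercept", "familiarity", "talk", "speed",
    "familiarity:speed", "familiarity:talk", "talk:speed",
    "familiarity:talk:speed")
}

#' Design-code matrix for a trial table
#'
#' @param trials a trial data.frame with familiarity, mode and speed columns.
#' @param terms which design codes to include (default all eight).
#' @return numeric matrix, one column per requested label.
#' @export
design_codes <- function(trials, terms = beta_labels()) {
  f <- as.numeric(trials$familiarity == "friends")
  t_ <- as.numeric(trials$mode == "colaughter")
  s <- as.numeric(trials$speed == "sped-up")
  all_codes <- cbind(intercept = rep(1, nrow(trials)), familiarity = f,
                     talk = t_, speed = s, "familiarity:speed" = f * s,
                     "familiarity:talk" = f * t_, "talk:speed" = t_ * s,
                     "familiarity:talk:speed" = f * t_ * s)
  bad <- setdiff(terms, colnames(all_codes))
  if (length(bad)) stop("unknown design-code label(s): ", paste(bad, collapse = ", "))
  all_codes[, terms, drop = FALSE]
}

#' Mean "friends"-response rate per familiarity x mode x speed cell
#'
#' @param trials a trial table with responses.
#' @return data.frame with 8 rows (full factorial), columns familiarity,
#'   mode, speed, n and rate. Cells with no trials are kept with `n = 0`
#'   and `NA` rate, and reported in a warning rather than dropped.
#' @export
condition_rates <- function(trials) {
  if (!nrow(trials)) stop("empty trial table")
  validate_trials(trials, require_response = TRUE)
  grid <- expand.grid(familiarity = c("friends", "strangers"),
                      mode = c("colaughter", "cospeech"),
                      speed = c("original", "sped-up"),
                      stringsAsFactors = FALSE)
  agg <- aggregate(response ~ familiarity + mode + speed, data = trials,
                   FUN = mean)
  cnt <- aggregate(cbind(n = response) ~ familiarity + mode + speed,
                   data = trials, FUN = length)
  out <- merge(merge(grid, cnt, all.x = TRUE), agg, all.x = TRUE)
  names(out)[names(out) == "response"] <- "rate"
  out$n[is.na(out$n)] <- 0L
  out <- out[order(out$mode, out$speed, out$familiarity), ]
  rownames(out) <- NULL
  if (any(out$n == 0L)) {
    empty <- out[out$n == 0L, c("familiarity", "mode", "speed")]
    warning("empty design cell(s): ",
            paste(apply(empty, 1, paste, collapse = "/"), collapse = "; "))
  }
  out
}
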