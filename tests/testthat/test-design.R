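test_that("default design enumerates the full factorial experiment", {
  d <- build_design(design_spec(seed = 3))
  expect_equal(nrow(d), 108 * 96)
  stim <- attr(d, "stimuli")
  expect_equal(nrow(stim), 96)
  expect_equal(anyDuplicated(stim[, c("conversation_id", "mode", "occurrence")]), 0L)
  fam_by_conv <- tapply(stim$familiarity, stim$conversation_id,
                        function(x) length(unique(x)))
  expect_true(all(fam_by_conv == 1))
  # every participant hears every stimulus exactly once
  expect_true(all(table(d$participant_id, d$stimulus_id) == 1))
  # 12 trials per familiarity x mode x speed cell per participant
  cells <- table(d$participant_id, d$familiarity, d$mode, d$speed)
  expect_true(all(cells == 12))
})

test_that("a minimal one-participant design has one row per condition", {
  d <- build_design(design_spec(n_participants = 1,
                                n_conversations_per_familiarity = 1,
                                clips_per_conversation_per_mode = 1,
                                n_lists = 1))
  expect_equal(nrow(d), 4)
  expect_equal(sort(paste(d$familiarity, d$mode)),
               sort(c(outer(c("friends", "strangers"),
                            c("colaughter", "cospeech"), paste))))
})

test_that("design balance invariants hold across random seeds and sizes", {
  for (seed in c(2, 9, 41)) {
    spec <- design_spec(n_participants = 5,
                        n_conversations_per_familiarity = 3, seed = seed)
    d <- build_design(spec)
    n_stim <- 2 * 3 * 2 * 2
    expect_equal(nrow(d), 5 * n_stim)
    # trial_index is a 0-based permutation per participant
    idx <- tapply(d$trial_index, d$participant_id,
                  function(x) identical(sort(x), 0:(n_stim - 1)))
    expect_true(all(idx))
    # each list hears half of each mode's clips sped-up
    one <- d[d$participant_id == d$participant_id[1], ]
    sped_share <- tapply(one$speed == "sped-up", one$mode, mean)
    expect_true(all(sped_share == 0.5))
    # a stimulus' speed is fixed within a list and complementary across lists
    by_stim <- tapply(paste(d$list_id, d$speed), d$stimulus_id,
                      function(x) length(unique(x)))
    expect_true(all(by_stim == 2))
  }
})

test_that("list counts that cannot split a condition cell fail loudly", {
  expect_error(build_design(design_spec(n_participants = 2,
                                        n_conversations_per_familiarity = 3,
                                        clips_per_conversation_per_mode = 1,
                                        n_lists = 2)),
               "cell \\(friends, colaughter\\)|cell \\(friends, cospeech\\)")
})

test_that("the design is byte-identical under a repeated seed", {
  a <- build_design(design_spec(n_participants = 6,
                                n_conversations_per_familiarity = 2, seed = 7))
  b <- build_design(design_spec(n_participants = 6,
                                n_conversations_per_familiarity = 2, seed = 7))
  expect_identical(a, b)
  c_ <- build_design(design_spec(n_participants = 6,
                                 n_conversations_per_familiarity = 2, seed = 8))
  # presentation order (stimulus sequence within participant) depends on seed
  expect_false(identical(a$stimulus_id, c_$stimulus_id))
})

test_that("condition_rates reports all eight cells and flags empty ones", {
  d <- tiny_design()
  d$response <- 1L
  r <- condition_rates(d)
  expect_equal(nrow(r), 8)
  expect_true(all(r$rate == 1))
  expect_equal(sum(r$n), nrow(d))
  # dropping one mode leaves explicit empty cells, not silent omission
  sub <- d[d$mode == "colaughter", ]
  expect_warning(r2 <- condition_rates(sub), "empty design cell")
  expect_equal(nrow(r2), 8)
  expect_equal(sum(r2$n == 0), 4)
})

test_that("default-scale cells hold 1296 trials each", {
  d <- build_design(design_spec(seed = 1))
  d$response <- 0L
  d$response[seq(1, nrow(d), 2)] <- 1L
  r <- condition_rates(d)
  expect_true(all(r$n == 108 * 12))
})
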