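stream_with <- function(run_lengths, label = "weaving", ears = rep("neutral", 10),
                        depressed = 0) {
  ev <- if (length(run_lengths)) {
    data.frame(label = label, run_length = run_lengths)
  }
  observation_stream("h1", ev, ears, depressed_seen = depressed)
}

test_that("the 3-successive/5-events rule scores stereotypies correctly", {
  expect_equal(score_sb_arb(stream_with(c(3, 4, 3, 5, 3))), 1L)
  expect_equal(score_sb_arb(stream_with(c(3, 3, 3, 3))), 0L)    # only 4 events
  expect_equal(score_sb_arb(stream_with(c(2, 2, 2, 2, 2))), 0L) # runs too short
  expect_equal(score_sb_arb(stream_with(integer(0))), 0L)
  # runs below 3 never count toward the 5 events
  expect_equal(score_sb_arb(stream_with(c(3, 3, 3, 3, 2, 2))), 0L)
  # events split across behaviours do not combine
  ev <- data.frame(label = rep(c("weaving", "cribbing"), c(3, 3)),
                   run_length = rep(4, 6))
  expect_equal(score_sb_arb(observation_stream("h", ev, rep("neutral", 10))), 0L)
})

test_that("score_sb_arb is monotone in added events", {
  set.seed(171)
  for (rep in 1:20) {
    runs <- sample(1:6, sample(0:7, 1), replace = TRUE)
    before <- score_sb_arb(stream_with(runs))
    after <- score_sb_arb(stream_with(c(runs, sample(1:6, 2, replace = TRUE))))
    expect_gte(after, before)
  }
})

test_that("depressed-like posture is scored on at-least-once basis", {
  expect_equal(score_depressed(stream_with(3, depressed = 0)), 0L)
  expect_equal(score_depressed(stream_with(3, depressed = 1)), 1L)
  expect_equal(score_depressed(stream_with(3, depressed = 7)), 1L)
})

test_that("favourite ear position needs 60% of the 10 scans", {
  expect_equal(categorize_ear_position(rep(c("backward", "forward"), c(6, 4))),
               "backward")
  expect_equal(categorize_ear_position(rep(c("forward", "backward"), c(5, 5))),
               "neutral")
  expect_equal(categorize_ear_position(rep("forward", 10)), "forward")
  expect_equal(categorize_ear_position(rep(c("forward", "neutral"), c(5, 5))),
               "neutral")
  expect_error(categorize_ear_position(rep("forward", 9)), "10")
})

test_that("prevalence reproduces printed percentage arithmetic", {
  expect_equal(prevalence(c(rep(1, 15), rep(0, 70)))$rounded, 18)
  expect_equal(prevalence(c(rep(1, 9), rep(0, 76)))$rounded, 11)
  expect_equal(prevalence(rep(0, 40))$rounded, 0)
  expect_equal(prevalence(rep(1, 12))$raw, 100)
  p <- prevalence(c(1, 0, 0, 0))
  expect_equal(p$raw, 25)
  expect_equal(p$n, 1)
  expect_error(prevalence(numeric(0)), "empty")
  set.seed(181)
  for (i in 1:10) {
    flags <- rbinom(sample(3:50, 1), 1, runif(1))
    pr <- prevalence(flags)$raw
    expect_true(pr >= 0 && pr <= 100)
  }
})

test_that("welfare and stream CSV round-trips preserve scores", {
  recs <- data.frame(horse_id = c("a", "b", "c"), sb_arb = c(1, 0, 1),
                     depressed = c(0, 1, 0),
                     ear_category = c("forward", "backward", "neutral"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_welfare_csv(recs, path)
  expect_equal(read_welfare_csv(path), recs)
  streams <- generate_observation_streams(recs, seed = 5)
  spath <- withr::local_tempfile(fileext = ".csv")
  write_streams_csv(streams, spath)
  back <- read_streams_csv(spath)
  expect_equal(vapply(back, score_sb_arb, integer(1), USE.NAMES = FALSE),
               vapply(streams, score_sb_arb, integer(1)))
  expect_equal(vapply(back, function(s) s$ear_scans[1], character(1),
                      USE.NAMES = FALSE),
               vapply(streams, function(s) s$ear_scans[1], character(1)))
})

test_that("generated observation streams reproduce their records' scores", {
  set.seed(191)
  recs <- data.frame(
    horse_id = sprintf("h%02d", 1:30),
    sb_arb = rbinom(30, 1, 0.4),
    depressed = rbinom(30, 1, 0.2),
    ear_category = sample(c("forward", "backward", "neutral"), 30, replace = TRUE)
  )
  streams <- generate_observation_streams(recs, seed = 77)
  expect_equal(vapply(streams, score_sb_arb, integer(1)), recs$sb_arb)
  expect_equal(vapply(streams, score_depressed, integer(1)), recs$depressed)
  expect_equal(vapply(streams, categorize_ear_position, character(1)),
               recs$ear_category)
  # reproducible under the seed
  streams2 <- generate_observation_streams(recs, seed = 77)
  expect_identical(streams, streams2)
})
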