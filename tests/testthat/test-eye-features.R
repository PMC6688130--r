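test_that("fixation classes follow the first-pass definitions", {
  expect_identical(label_fixations(make_trial(c(1, 2, 1, 3, 3))),
                   c("first_pass_first", "first_pass_first", "re_fixation",
                     "first_pass_first", "multi_fixation"))
  expect_identical(label_fixations(make_trial(c(2, 1))),
                   c("first_pass_first", "later_pass_first"))
  expect_identical(label_fixations(make_trial(integer(0), n_words = 3)),
                   character(0))
  # a run started by a later-pass first fixation yields re-fixations
  expect_identical(label_fixations(make_trial(c(2, 1, 1))),
                   c("first_pass_first", "later_pass_first", "re_fixation"))
})

test_that("reading/re-reading partition splits at first entry to the last AOI", {
  expect_identical(phase_partition(make_trial(c(1, 2, 3, 2, 3), n_words = 3)),
                   c(reading = 3L, re_reading = 2L))
  expect_identical(phase_partition(make_trial(c(1, 2, 1, 2), n_words = 5)),
                   c(reading = 4L, re_reading = 0L))
  expect_identical(phase_partition(make_trial(3, n_words = 3)),
                   c(reading = 1L, re_reading = 0L))
})

test_that("saccade and regression statistics match hand computation", {
  tr <- make_trial(c(1, 2, 3), n_words = 5,
                   saccades = data.frame(start_aoi = c(1, 5, 4),
                                         end_aoi = c(2, 2, 3),
                                         amplitude_deg = c(1.0, 2.0, 3.0)))
  fv <- extract_eye_features(tr)
  expect_equal(fv[["saccade_amplitude_mean"]], 2.0)
  expect_equal(fv[["saccade_amplitude_sd"]], sd(c(1, 2, 3)))
  # regressions 5->2 and 4->3: distances 3 and 1
  expect_equal(fv[["regression_distance_mean"]], 2.0)
  expect_equal(fv[["max_regression_distance"]], 3)
  expect_equal(fv[["max_regression_amplitude"]], 3.0)

  no_sac <- make_trial(c(1, 2), saccades = data.frame(
    start_aoi = integer(), end_aoi = integer(), amplitude_deg = numeric()))
  fv0 <- extract_eye_features(no_sac)
  expect_true(is.na(fv0[["saccade_amplitude_mean"]]))
  expect_true(is.na(fv0[["regression_distance_mean"]]))
})

test_that("wrap-up gaze uses first-pass gaze on sentence-final words", {
  # two sentences of two words; first-pass gaze per word:
  # word1 = 150, word2 (final) = 100 + 200 = 300, word3 = 250,
  # word4 (final) = 400; internal mean (150 + 250)/2 = 200
  tr <- make_trial(c(1, 2, 2, 3, 4),
                   durations = c(150, 100, 200, 250, 400),
                   n_words = 4,
                   sentence_spans = data.frame(first_aoi = c(1, 3),
                                               last_aoi = c(2, 4)))
  fv <- extract_eye_features(tr)
  expect_equal(fv[["wrapup_gaze_mean_ms"]], mean(c(300, 400)))  # 350
  expect_equal(fv[["wrapup_gaze_sd_ms"]], sd(c(300, 400)))
  expect_equal(fv[["wrapup_ratio"]], 350 / 200)                 # 1.75
})

test_that("class counts satisfy the partition identities on random scanpaths", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      nw <- sample(3:12, 1)
      aois <- sample.int(nw, sample(1:30, 1), replace = TRUE)
      tr <- make_trial(aois, n_words = nw)
      labels <- label_fixations(tr)
      fv <- extract_eye_features(tr)
      expect_identical(sum(fv[c("first_pass_first_fixation_count",
                                "later_pass_first_fixation_count",
                                "multi_fixation_count",
                                "re_fixation_count")]),
                       fv[["fixation_count"]])
      expect_identical(fv[["reading_fixation_count"]] +
                         fv[["re_reading_fixation_count"]],
                       fv[["fixation_count"]])
      expect_identical(
        sum(labels %in% c("first_pass_first", "later_pass_first")),
        length(unique(aois)))
    }
  })
})

test_that("permuting fixation durations leaves all count features unchanged", {
  withr::with_seed(7, {
    aois <- sample.int(8, 25, replace = TRUE)
    durs <- runif(25, 80, 400)
    count_features <- c("fixation_count", "first_pass_first_fixation_count",
                        "later_pass_first_fixation_count",
                        "multi_fixation_count", "re_fixation_count",
                        "reading_fixation_count", "re_reading_fixation_count")
    f1 <- extract_eye_features(make_trial(aois, durations = durs))
    f2 <- extract_eye_features(make_trial(aois, durations = sample(durs)))
    expect_identical(f1[count_features], f2[count_features])
  })
})

test_that("labeling agrees with the prefix-scanning oracle", {
  withr::with_seed(99, {
    for (rep in 1:300) {
      nw <- sample(2:15, 1)
      aois <- sample.int(nw, sample(1:40, 1), replace = TRUE)
      expect_identical(label_fixations(make_trial(aois, n_words = nw)),
                       oracle_labels(aois))
    }
  })
})
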