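## Eye-movement features from word-AOI scanpaths.
##
## Fixations are classified into four exclusive classes:
##   first_pass_first -- first fixation on its word while no word later in
##     the text has yet been fixated;
##   later_pass_first -- first fixation on its word after some later word
##     has already been fixated;
##   multi_fixation   -- a non-first fixation inside the consecutive run of
##     fixations that starts with a first-pass first fixation on that word;
##   re_fixation      -- any other non-first fixation on a word.
## The gaze duration of a word is the summed duration of its first-pass run
## (the first-pass first fixation plus its multi-fixations).

#' Classify each fixation of a reading trial
#'
#' @param trial A [trial_gaze()] record.
#' @return Character vector, one of `first_pass_first`, `later_pass_first`,
#'   `multi_fixation`, `re_fixation` per fixation, in fixation order.
#' @examples
#' tg <- trial_gaze(3, data.frame(first_aoi = 1, last_aoi = 3),
#'                  data.frame(aoi_index = c(1, 2, 1, 3, 3),
#'                             onset_ms = c(0, 200, 400, 600, 800),
#'                             duration_ms = rep(150, 5)),
#'                  data.frame(start_aoi = integer(), end_aoi = integer(),
#'                             amplitude_deg = numeric()))
#' label_fixations(tg)
#' @export
label_fixations <- function(trial) {
  stopifnot(inherits(trial, "trial_gaze"))
  aoi <- trial$fixations$aoi_index
  n <- length(aoi)
  labels <- character(n)
  if (n == 0) return(labels)
  seen <- logical(trial$n_words)
  run_word <- 0L       # word of the current consecutive run
  run_is_fp <- FALSE   # run started with a first-pass first fixation
  for (i in seq_len(n)) {
    w <- aoi[i]
    if (!seen[w]) {
      later_seen <- w < trial$n_words && any(seen[(w + 1L):trial$n_words])
      labels[i] <- if (later_seen) "later_pass_first" else "first_pass_first"
      run_word <- w
      run_is_fp <- labels[i] == "first_pass_first"
      seen[w] <- TRUE
    } else if (i > 1L && aoi[i - 1L] == w && run_word == w && run_is_fp) {
      labels[i] <- "multi_fixation"
    } else {
      labels[i] <- "re_fixation"
      run_word <- w
      run_is_fp <- FALSE
    }
  }
  labels
}

#' Split fixations into reading and re-reading phases
#'
#' The reading phase runs up to and including the fixation that first enters
#' the last AOI of the text; re-reading is everything strictly after it, so
#' the two counts always partition the total. If the last AOI is never
#' fixated, all fixations count as reading.
#'
#' @param trial A [trial_gaze()] record.
#' @return Named integer vector `c(reading = ..., re_reading = ...)`.
#' @export
phase_partition <- function(trial) {
  stopifnot(inherits(trial, "trial_gaze"))
  aoi <- trial$fixations$aoi_index
  n <- length(aoi)
  hit <- which(aoi == trial$n_words)
  reading <- if (length(hit)) hit[1] else n
  c(reading = as.integer(reading), re_reading = as.integer(n - reading))
}

# first-pass gaze duration per word; NA where no first-pass run exists
first_pass_gaze <- function(trial, labels = label_fixations(trial)) {
  gaze <- rep(NA_real_, trial$n_words)
  aoi <- trial$fixations$aoi_index
  dur <- trial$fixations$duration_ms
  run_word <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == "first_pass_first") {
      run_word <- aoi[i]
      gaze[run_word] <- dur[i]
    } else if (labels[i] == "multi_fixation") {
      gaze[run_word] <- gaze[run_word] + dur[i]
    }
  }
  gaze
}

#' Extract the 22 eye-movement features of one trial
#'
#' Saccade and regression amplitude/distance statistics, fixation-class
#' counts, reading/re-reading phase counts, first-pass first fixation
#' duration statistics, and the sentence wrap-up measures (gaze time on
#' sentence-final words and its ratio to the mean sentence-internal gaze
#' time). Statistics over empty sets -- e.g. regression measures in a trial
#' without regressions -- are masked missing (`NA`).
#'
#' Within-word saccades (equal start and end AOI) have word distance 0 and
#' are not regressions; a regression requires a strictly preceding end AOI.
#'
#' @param trial A [trial_gaze()] record.
#' @param task Task the trial belongs to (default silent reading).
#' @return A [feature_vector()] of mode `eyes` (22 features).
#' @export
extract_eye_features <- function(trial, task = "reading_silent") {
  stopifnot(inherits(trial, "trial_gaze"))
  sac <- trial$saccades
  dist <- abs(sac$end_aoi - sac$start_aoi)
  reg <- sac[sac$end_aoi < sac$start_aoi, , drop = FALSE]
  reg_dist <- sac$start_aoi[sac$end_aoi < sac$start_aoi] -
    sac$end_aoi[sac$end_aoi < sac$start_aoi]

  labels <- label_fixations(trial)
  phases <- phase_partition(trial)
  fpf_dur <- trial$fixations$duration_ms[labels == "first_pass_first"]

  gaze <- first_pass_gaze(trial, labels)
  final_words <- trial$sentence_spans$last_aoi
  wrap <- gaze[final_words]
  wrap <- wrap[!is.na(wrap)]
  internal <- gaze[setdiff(seq_len(trial$n_words), final_words)]
  internal <- internal[!is.na(internal)]
  internal_mean <- masked_mean(internal)

  vals <- c(
    saccade_amplitude_mean = masked_mean(sac$amplitude_deg),
    saccade_amplitude_sd = masked_sd(sac$amplitude_deg),
    saccade_distance_mean = masked_mean(dist),
    saccade_distance_sd = masked_sd(dist),
    regression_amplitude_mean = masked_mean(reg$amplitude_deg),
    regression_amplitude_sd = masked_sd(reg$amplitude_deg),
    regression_distance_mean = masked_mean(reg_dist),
    regression_distance_sd = masked_sd(reg_dist),
    max_regression_amplitude = masked_max(reg$amplitude_deg),
    max_regression_distance = masked_max(reg_dist),
    fixation_count = length(labels),
    first_pass_first_fixation_count = sum(labels == "first_pass_first"),
    later_pass_first_fixation_count = sum(labels == "later_pass_first"),
    multi_fixation_count = sum(labels == "multi_fixation"),
    re_fixation_count = sum(labels == "re_fixation"),
    reading_fixation_count = phases[["reading"]],
    re_reading_fixation_count = phases[["re_reading"]],
    fpf_duration_mean_ms = masked_mean(fpf_dur),
    fpf_duration_sd_ms = masked_sd(fpf_dur),
    wrapup_gaze_mean_ms = masked_mean(wrap),
    wrapup_gaze_sd_ms = masked_sd(wrap),
    wrapup_ratio = if (length(wrap) == 0 || is.na(internal_mean) ||
                       internal_mean == 0) NA_real_
                   else mean(wrap) / internal_mean
  )
  feature_vector(vals, mode = "eyes", task = task)
}
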