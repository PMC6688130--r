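## Temporal speech-fluency features from voiced-interval timing records.

#' Derive silent pauses from a speech timing record
#'
#' A pause is a silent gap between two consecutive voiced intervals whose
#' duration strictly exceeds the threshold (default 150 ms). Leading and
#' trailing silence is not between speech and is therefore never a pause,
#' although it still contributes to total duration.
#'
#' @param timing A [speech_timing()] record.
#' @param threshold_ms Pause threshold in milliseconds; a gap must be longer
#'   than this (strict) to count.
#' @return Numeric vector of pause durations in ms, in temporal order.
#' @examples
#' st <- speech_timing(4, 10, data.frame(start_s = c(0, 1.1, 2.5),
#'                                       end_s = c(1.0, 2.0, 4.0)))
#' derive_pauses(st)  # one 500 ms pause; the 100 ms gap is below threshold
#' @export
derive_pauses <- function(timing, threshold_ms = 150) {
  stopifnot(inherits(timing, "speech_timing"), threshold_ms > 0)
  v <- timing$voiced_intervals
  if (nrow(v) < 2) return(numeric(0))
  gaps_ms <- (v$start_s[-1] - v$end_s[-nrow(v)]) * 1000
  gaps_ms[gaps_ms > threshold_ms]
}

#' Extract the 12 temporal speech features of one sample
#'
#' Syllable count, pause count, total duration, phonation time (summed
#' voiced time, excluding silent pauses), proportion of time spent speaking,
#' speech rate (syllables per second of total duration), average syllable
#' duration (phonation time per syllable), pauses per syllable, pause rate,
#' and mean / s.d. / maximum pause duration. Pause statistics over an empty
#' pause set are masked missing, as are the per-syllable ratios when the
#' sample contains no syllables.
#'
#' @param timing A [speech_timing()] record.
#' @param task Task the sample belongs to (default picture description).
#' @param threshold_ms Pause threshold passed to [derive_pauses()].
#' @return A [feature_vector()] of mode `speech` (12 features).
#' @export
extract_speech_features <- function(timing, task = "picture_description",
                                    threshold_ms = 150) {
  stopifnot(inherits(timing, "speech_timing"))
  pauses <- derive_pauses(timing, threshold_ms)
  dur <- timing$total_duration_s
  v <- timing$voiced_intervals
  phonation <- sum(v$end_s - v$start_s)
  syl <- timing$syllable_count

  vals <- c(
    syllable_count = syl,
    pause_count = length(pauses),
    duration_s = dur,
    phonation_time_s = phonation,
    proportion_speaking = phonation / dur,
    speech_rate = syl / dur,
    avg_syllable_duration = masked_ratio(phonation, syl),
    pauses_per_syllable = masked_ratio(length(pauses), syl),
    pause_rate = length(pauses) / dur,
    pause_duration_mean_ms = masked_mean(pauses),
    pause_duration_sd_ms = masked_sd(pauses),
    max_pause_duration_ms = masked_max(pauses)
  )
  feature_vector(vals, mode = "speech", task = task)
}
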