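## Canonical vocabulary of the session/task/mode/feature hierarchy.
##
## A data-collection session comprises three tasks -- picture description
## (pd), silent reading (rs) and reading aloud (ra) -- each observed through
## a subset of four modes: speech timing, transcript language, eye movements
## and comprehension responses.  Seven (task, mode) combinations exist.

#' Task and mode vocabulary
#'
#' `task_kinds()` and `mode_kinds()` return the canonical task and mode
#' identifiers. `valid_slots()` returns the seven valid (task, mode)
#' combinations in canonical session order: picture-description language and
#' speech, silent-reading eyes and comprehension, reading-aloud eyes,
#' comprehension and speech.
#'
#' @return Character vector of identifiers, or for `valid_slots()` a
#'   data.frame with columns `task` and `mode`.
#' @examples
#' task_kinds()
#' valid_slots()
#' @export
task_kinds <- function() c("picture_description", "reading_silent", "reading_aloud")

#' @rdname task_kinds
#' @export
mode_kinds <- function() c("speech", "language", "eyes", "comprehension")

#' @rdname task_kinds
#' @export
valid_slots <- function() {
  data.frame(
    task = c("picture_description", "picture_description",
             "reading_silent", "reading_silent",
             "reading_aloud", "reading_aloud", "reading_aloud"),
    mode = c("language", "speech",
             "eyes", "comprehension",
             "eyes", "comprehension", "speech"),
    stringsAsFactors = FALSE
  )
}

slot_id <- function(task, mode) paste(task, mode, sep = ".")

is_valid_slot <- function(task, mode) {
  vs <- valid_slots()
  any(vs$task == task & vs$mode == mode)
}

assert_valid_slot <- function(task, mode) {
  task <- match.arg(task, task_kinds())
  mode <- match.arg(mode, mode_kinds())
  if (!is_valid_slot(task, mode)) {
    stop(sprintf("(%s, %s) is not a valid task/mode combination", task, mode),
         call. = FALSE)
  }
  invisible(c(task = task, mode = mode))
}

#' Mode dimensionality and canonical feature names
#'
#' Each mode has a fixed feature-vector length: 26 language features, 12
#' speech features, 22 eye-movement features, and `2q + 1` comprehension
#' features for `q` questions (11 at the default five questions). Feature
#' order is canonical and stable; `feature_names()` documents it.
#'
#' @param mode One of `"language"`, `"speech"`, `"eyes"`, `"comprehension"`.
#' @param n_questions Number of comprehension questions (default 5).
#' @return `mode_dimension()`: integer length; `feature_names()`: character
#'   vector of canonical names in canonical order.
#' @examples
#' mode_dimension("eyes")
#' feature_names("speech")
#' @export
mode_dimension <- function(mode, n_questions = 5L) {
  length(feature_names(mode, n_questions = n_questions))
}

#' @rdname mode_dimension
#' @export
feature_names <- function(mode, n_questions = 5L) {
  mode <- match.arg(mode, mode_kinds())
  switch(mode,
    language = c(
      "total_words", "mean_length_sentence",
      "prop_pp_words", "prop_np_words", "prop_vg_words",
      "prop_main_finite_clause_words", "prop_main_infinitive_clause_words",
      "prop_subordinate_clause_words",
      "ratio_noun_verb", "ratio_pronoun_noun", "ratio_determiner_noun",
      "ratio_open_closed",
      "prop_present_tense_verbs",
      "median_word_frequency",
      "type_token_ratio",
      "iu_subjects_norm", "iu_objects_norm", "iu_places_norm",
      "iu_actions_norm",
      "content_density", "content_efficiency",
      "propositional_density",
      "filled_pauses_per_word", "false_starts_per_word",
      "incomplete_sentences_per_word", "dysfluency_index"
    ),
    speech = c(
      "syllable_count", "pause_count", "duration_s", "phonation_time_s",
      "proportion_speaking", "speech_rate", "avg_syllable_duration",
      "pauses_per_syllable", "pause_rate",
      "pause_duration_mean_ms", "pause_duration_sd_ms",
      "max_pause_duration_ms"
    ),
    eyes = c(
      "saccade_amplitude_mean", "saccade_amplitude_sd",
      "saccade_distance_mean", "saccade_distance_sd",
      "regression_amplitude_mean", "regression_amplitude_sd",
      "regression_distance_mean", "regression_distance_sd",
      "max_regression_amplitude", "max_regression_distance",
      "fixation_count",
      "first_pass_first_fixation_count", "later_pass_first_fixation_count",
      "multi_fixation_count", "re_fixation_count",
      "reading_fixation_count", "re_reading_fixation_count",
      "fpf_duration_mean_ms", "fpf_duration_sd_ms",
      "wrapup_gaze_mean_ms", "wrapup_gaze_sd_ms",
      "wrapup_ratio"
    ),
    comprehension = {
      q <- seq_len(n_questions)
      c("average_accuracy",
        paste0("q", q, "_correct"),
        paste0("q", q, "_response_time_ms"))
    }
  )
}

#' Construct a mode-level feature vector
#'
#' Wraps a named numeric vector as a feature vector for one (task, mode)
#' slot, checking length and canonical naming. Missing (undefined) feature
#' values are represented as `NA` and carried explicitly; they are imputed
#' at classification time, never silently zero-filled.
#'
#' @param values Named numeric vector in canonical order.
#' @param mode,task Mode and task identifiers; the pair must be valid.
#' @param n_questions Number of comprehension questions (default 5).
#' @return An object of class `feature_vector`.
#' @export
feature_vector <- function(values, mode, task, n_questions = 5L) {
  assert_valid_slot(task, mode)
  expected <- feature_names(mode, n_questions = n_questions)
  if (length(values) != length(expected)) {
    stop(sprintf("%s feature vector must have length %d, got %d",
                 mode, length(expected), length(values)), call. = FALSE)
  }
  if (is.null(names(values))) {
    names(values) <- expected
  } else if (!identical(names(values), expected)) {
    stop("feature names do not match the canonical order for mode ", mode,
         call. = FALSE)
  }
  structure(as.numeric(setNames(values, expected)),
            names = expected,
            mode = mode, task = task,
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s / %s (%d features, %d missing)\n",
              attr(x, "task"), attr(x, "mode"), length(x), sum(is.na(x))))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
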