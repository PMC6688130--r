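## Raw per-mode records, session records and cohort containers.

#' Word-level gaze record for one reading trial
#'
#' Fixations are attributed to word areas of interest (AOIs), indexed 1-based
#' from the first word of the text; fixations outside any AOI are not
#' represented. Saccades carry the start/end AOI and an amplitude in degrees
#' of visual angle.
#'
#' @param n_words Number of words (AOIs) in the text.
#' @param sentence_spans Data frame with columns `first_aoi`, `last_aoi`, one
#'   row per sentence; the spans must partition `1..n_words`.
#' @param fixations Data frame with columns `aoi_index`, `onset_ms`,
#'   `duration_ms`, ordered by onset.
#' @param saccades Data frame with columns `start_aoi`, `end_aoi`,
#'   `amplitude_deg`.
#' @return An object of class `trial_gaze`.
#' @export
trial_gaze <- function(n_words, sentence_spans, fixations, saccades) {
  n_words <- as.integer(n_words)
  stopifnot(n_words >= 1)
  sentence_spans <- as.data.frame(sentence_spans)
  fixations <- as.data.frame(fixations)
  saccades <- as.data.frame(saccades)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(sentence_spans, c("first_aoi", "last_aoi"), "sentence_spans")
  need(fixations, c("aoi_index", "onset_ms", "duration_ms"), "fixations")
  need(saccades, c("start_aoi", "end_aoi", "amplitude_deg"), "saccades")
  covered <- unlist(Map(seq, sentence_spans$first_aoi, sentence_spans$last_aoi))
  if (!identical(sort(as.integer(covered)), seq_len(n_words)))
    stop("sentence_spans must partition 1..n_words", call. = FALSE)
  if (nrow(fixations)) {
    if (any(fixations$aoi_index < 1 | fixations$aoi_index > n_words))
      stop("fixation aoi_index out of range [1, n_words]", call. = FALSE)
    if (any(fixations$duration_ms <= 0))
      stop("fixation durations must be positive", call. = FALSE)
    if (is.unsorted(fixations$onset_ms))
      stop("fixations must be ordered by onset", call. = FALSE)
  }
  if (nrow(saccades)) {
    if (any(saccades$amplitude_deg < 0))
      stop("saccade amplitudes must be non-negative", call. = FALSE)
    if (any(saccades$start_aoi < 1 | saccades$start_aoi > n_words |
            saccades$end_aoi < 1 | saccades$end_aoi > n_words))
      stop("saccade AOI indices out of range", call. = FALSE)
  }
  structure(list(n_words = n_words,
                 sentence_spans = sentence_spans,
                 fixations = fixations,
                 saccades = saccades),
            class = "trial_gaze")
}

#' Syllable-and-pause timing record of one speech sample
#'
#' @param total_duration_s Total duration of the speech sample in seconds.
#' @param syllable_count Number of syllables produced (estimated upstream
#'   from the audio; consumed here as given).
#' @param voiced_intervals Data frame with columns `start_s`, `end_s` of
#'   ordered, non-overlapping voiced intervals within the sample.
#' @return An object of class `speech_timing`.
#' @export
speech_timing <- function(total_duration_s, syllable_count, voiced_intervals) {
  voiced_intervals <- as.data.frame(voiced_intervals)
  stopifnot(all(c("start_s", "end_s") %in% names(voiced_intervals)))
  if (total_duration_s <= 0)
    stop("total_duration_s must be positive", call. = FALSE)
  if (syllable_count < 0)
    stop("syllable_count must be non-negative", call. = FALSE)
  v <- voiced_intervals
  if (nrow(v)) {
    if (any(v$end_s <= v$start_s))
      stop("voiced intervals must have end > start", call. = FALSE)
    if (any(v$start_s < 0 | v$end_s > total_duration_s + 1e-9))
      stop("voiced intervals must lie within [0, total_duration_s]",
           call. = FALSE)
    if (nrow(v) > 1 && any(diff(v$start_s) <= 0))
      stop("voiced interval starts must be strictly increasing", call. = FALSE)
    if (nrow(v) > 1 && any(v$start_s[-1] < v$end_s[-nrow(v)] - 1e-12))
      stop("voiced intervals must not overlap", call. = FALSE)
  }
  structure(list(total_duration_s = as.numeric(total_duration_s),
                 syllable_count = as.integer(round(syllable_count)),
                 voiced_intervals = v),
            class = "speech_timing")
}

#' Token-annotated picture-description transcript
#'
#' One row per token with the linguistic annotations consumed by the
#' language-feature extractor (part-of-speech class, open-class flag,
#' phrase and clause tags, propositional flag, dysfluency class, corpus
#' frequency). Annotations are produced upstream; this container only
#' validates their vocabulary.
#'
#' @param tokens Data frame with columns `surface`, `is_word`, `pos_class`
#'   (`noun`/`verb`/`pronoun`/`determiner`/`other`), `open_class`,
#'   `present_tense`, `phrase_tag` (`PP`/`NP`/`VG`/`none`), `clause_tag`
#'   (`main_finite`/`main_infinitive`/`subordinate`/`none`),
#'   `proposition_flag`, `dysfluency_class` (`filled_pause`/`false_start`/
#'   `none`), `frequency_per_million` (`NA` allowed).
#' @param sentence_count Number of sentences in the narrative.
#' @param incomplete_sentence_count Annotated count of incomplete sentences.
#' @param sample_duration_s Duration of the speech sample in seconds (used by
#'   content efficiency).
#' @return An object of class `annotated_transcript`.
#' @export
annotated_transcript <- function(tokens, sentence_count,
                                 incomplete_sentence_count = 0L,
                                 sample_duration_s) {
  tokens <- as.data.frame(tokens)
  cols <- c("surface", "is_word", "pos_class", "open_class", "present_tense",
            "phrase_tag", "clause_tag", "proposition_flag",
            "dysfluency_class", "frequency_per_million")
  miss <- setdiff(cols, names(tokens))
  if (length(miss))
    stop("tokens table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  chk <- function(col, levels)
    if (!all(tokens[[col]] %in% levels))
      stop(sprintf("invalid %s value(s)", col), call. = FALSE)
  chk("pos_class", c("noun", "verb", "pronoun", "determiner", "other"))
  chk("phrase_tag", c("PP", "NP", "VG", "none"))
  chk("clause_tag", c("main_finite", "main_infinitive", "subordinate", "none"))
  chk("dysfluency_class", c("filled_pause", "false_start", "none"))
  if (nrow(tokens) > 0 && sentence_count < 1)
    stop("sentence_count must be >= 1 for a non-empty transcript",
         call. = FALSE)
  if (sample_duration_s <= 0)
    stop("sample_duration_s must be positive", call. = FALSE)
  structure(list(tokens = tokens,
                 sentence_count = as.integer(sentence_count),
                 incomplete_sentence_count = as.integer(incomplete_sentence_count),
                 sample_duration_s = as.numeric(sample_duration_s)),
            class = "annotated_transcript")
}

#' Comprehension question responses for one reading task
#'
#' @param correct Binary (0/1) correctness per question, in question order.
#' @param response_time_ms Positive response time per question, in ms.
#' @return An object of class `comprehension_responses`.
#' @export
comprehension_responses <- function(correct, response_time_ms) {
  if (length(correct) != length(response_time_ms))
    stop("correct and response_time_ms must have equal length", call. = FALSE)
  if (!all(correct %in% c(0, 1)))
    stop("correct must be binary 0/1", call. = FALSE)
  if (any(response_time_ms <= 0))
    stop("response times must be positive", call. = FALSE)
  structure(list(items = data.frame(correct = as.integer(correct),
                                    response_time_ms = as.numeric(response_time_ms))),
            class = "comprehension_responses")
}

slot_record_class <- function(mode) {
  switch(mode,
         eyes = "trial_gaze",
         speech = "speech_timing",
         language = "annotated_transcript",
         comprehension = "comprehension_responses")
}

#' One participant's data-collection session
#'
#' A complete session holds raw records for all seven (task, mode) slots:
#' picture-description language and speech, silent-reading eyes and
#' comprehension, reading-aloud eyes, comprehension and speech. The
#' diagnosis label codes healthy controls as 0 and MCI (the positive class)
#' as 1; it may be `NA` at prediction time.
#'
#' @param participant_id Opaque participant identifier.
#' @param diagnosis 0 (HC), 1 (MCI) or `NA`.
#' @param records Named list keyed `"<task>.<mode>"` of raw records
#'   (`trial_gaze`, `speech_timing`, `annotated_transcript`,
#'   `comprehension_responses`).
#' @return An object of class `session_record`.
#' @seealso [validate_session()]
#' @export
session_record <- function(participant_id, diagnosis = NA, records = list()) {
  if (!is.character(participant_id) || length(participant_id) != 1 ||
      !nzchar(participant_id))
    stop("participant_id must be a non-empty string", call. = FALSE)
  if (!is.na(diagnosis) && !diagnosis %in% c(0, 1))
    stop("diagnosis must be 0 (HC), 1 (MCI) or NA", call. = FALSE)
  structure(list(participant_id = participant_id,
                 diagnosis = if (is.na(diagnosis)) NA_integer_ else as.integer(diagnosis),
                 records = records,
                 features = list()),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s  diagnosis=%s  slots=%d/7  extracted=%s\n",
              x$participant_id,
              if (is.na(x$diagnosis)) "?" else if (x$diagnosis == 1) "MCI" else "HC",
              length(x$records),
              if (length(x$features)) "yes" else "no"))
  invisible(x)
}

#' Structural validation of a session record
#'
#' Checks that all seven (task, mode) slots are present, uniquely keyed, and
#' carry the record type their mode requires. This is a reporting operation:
#' it never throws for structural problems.
#'
#' @param session A [session_record()].
#' @return Character vector of violations; empty for a complete session.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_record"))
  violations <- character()
  keys <- names(session$records)
  dup <- unique(keys[duplicated(keys)])
  for (d in dup)
    violations <- c(violations, sprintf("duplicated slot: %s", d))
  vs <- valid_slots()
  expected <- slot_id(vs$task, vs$mode)
  for (i in seq_len(nrow(vs))) {
    key <- expected[i]
    if (!key %in% keys) {
      violations <- c(violations,
                      sprintf("missing (%s, %s) record", vs$task[i], vs$mode[i]))
    } else {
      rec <- session$records[[key]]
      want <- slot_record_class(vs$mode[i])
      if (!inherits(rec, want))
        violations <- c(violations,
                        sprintf("slot %s holds a %s, expected %s",
                                key, class(rec)[1], want))
    }
  }
  extra <- setdiff(unique(keys), expected)
  for (e in extra)
    violations <- c(violations, sprintf("invalid slot: %s", e))
  violations
}

#' Labeled cohort of sessions with optional neuropsychological profiles
#'
#' @param sessions List of [session_record()] with unique participant ids.
#' @param neuropsych Optional data frame of neuropsychological profiles, one
#'   row per participant (see [neuropsych_battery()]), with a
#'   `participant_id` column.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(sessions, neuropsych = NULL) {
  ids <- vapply(sessions, function(s) s$participant_id, character(1))
  if (anyDuplicated(ids))
    stop("participant ids must be unique", call. = FALSE)
  if (!is.null(neuropsych)) {
    neuropsych <- as.data.frame(neuropsych)
    if (!"participant_id" %in% names(neuropsych))
      stop("neuropsych table needs a participant_id column", call. = FALSE)
  }
  structure(list(sessions = sessions, neuropsych = neuropsych),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<cohort_dataset> %d participants (%d MCI, %d HC)%s\n",
              length(x$sessions), sum(lab == 1, na.rm = TRUE),
              sum(lab == 0, na.rm = TRUE),
              if (is.null(x$neuropsych)) "" else ", neuropsych profiles attached"))
  invisible(x)
}

cohort_ids <- function(cohort)
  vapply(cohort$sessions, function(s) s$participant_id, character(1))

cohort_labels <- function(cohort)
  vapply(cohort$sessions, function(s) as.integer(s$diagnosis), integer(1))

#' Extract all mode-level feature vectors of a session or cohort
#'
#' Runs the mode-appropriate extractor on every raw record and stores the
#' resulting feature vectors on the object. Extraction is a pure function of
#' the raw records; it must precede [assemble_design_matrix()].
#'
#' @param x A [session_record()] or [cohort_dataset()].
#' @param lexicon Information-unit lexicon for the language extractor
#'   (default [default_iu_lexicon()]).
#' @return The input object with feature vectors attached.
#' @export
extract_features <- function(x, lexicon = default_iu_lexicon()) {
  UseMethod("extract_features")
}

#' @export
extract_features.session_record <- function(x, lexicon = default_iu_lexicon()) {
  for (key in names(x$records)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    task <- parts[1]; mode <- parts[2]
    rec <- x$records[[key]]
    x$features[[key]] <- switch(mode,
      eyes = extract_eye_features(rec, task = task),
      speech = extract_speech_features(rec, task = task),
      language = extract_language_features(rec, lexicon = lexicon, task = task),
      comprehension = extract_comprehension_features(rec, task = task))
  }
  x
}

#' @export
extract_features.cohort_dataset <- function(x, lexicon = default_iu_lexicon()) {
  x$sessions <- lapply(x$sessions, extract_features, lexicon = lexicon)
  x
}

#' Assemble the design matrix for one (task, mode) slot
#'
#' Rows follow cohort order; columns follow the canonical feature order of
#' the mode. Feature extraction ([extract_features()]) must have been run.
#'
#' @param cohort A [cohort_dataset()].
#' @param task,mode A valid (task, mode) combination.
#' @return List with `x` (numeric matrix, participants x features, `NA` for
#'   masked-missing entries), `y` (diagnosis labels) and `participant_id`.
#' @examples
#' coh <- generate_cohort(generator_config(n_hc = 2, n_mci = 2, seed = 1))
#' coh <- extract_features(coh)
#' dm <- assemble_design_matrix(coh, "reading_silent", "eyes")
#' dim(dm$x)  # 4 x 22
#' @export
assemble_design_matrix <- function(cohort, task, mode) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  assert_valid_slot(task, mode)
  key <- slot_id(task, mode)
  n <- length(cohort$sessions)
  nq <- NULL
  if (mode == "comprehension" && n > 0) {
    fv0 <- cohort$sessions[[1]]$features[[key]]
    nq <- if (is.null(fv0)) 5L else (length(fv0) - 1L) / 2L
  }
  cols <- feature_names(mode, n_questions = nq %||% 5L)
  x <- matrix(NA_real_, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    fv <- cohort$sessions[[i]]$features[[key]]
    if (is.null(fv))
      stop(sprintf("features for slot %s not extracted for participant %s; run extract_features() first",
                   key, cohort$sessions[[i]]$participant_id), call. = FALSE)
    x[i, ] <- as.numeric(fv)
  }
  list(x = x,
       y = if (n > 0) cohort_labels(cohort) else integer(0),
       participant_id = cohort_ids(cohort))
}

# all seven design matrices keyed by slot id, in canonical session order
assemble_all_matrices <- function(cohort) {
  vs <- valid_slots()
  out <- vector("list", nrow(vs))
  names(out) <- slot_id(vs$task, vs$mode)
  for (i in seq_len(nrow(vs)))
    out[[i]] <- assemble_design_matrix(cohort, vs$task[i], vs$mode[i])
  out
}
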