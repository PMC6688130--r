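# Fixture builders shared across the test files. Everything is generated in
# code; nothing is read from disk.

# trial_gaze from an AOI sequence; durations default to 100, 200, 300, ...
make_trial <- function(aois, durations = NULL, n_words = max(aois, 1),
                       sentence_spans = NULL, saccades = NULL) {
  n <- length(aois)
  if (is.null(durations)) durations <- 100 * seq_len(n)
  if (is.null(sentence_spans))
    sentence_spans <- data.frame(first_aoi = 1L, last_aoi = n_words)
  if (is.null(saccades))
    saccades <- if (n >= 2)
      data.frame(start_aoi = aois[-n], end_aoi = aois[-1],
                 amplitude_deg = abs(diff(aois)) * 0.5 + 0.1)
    else
      data.frame(start_aoi = integer(), end_aoi = integer(),
                 amplitude_deg = numeric())
  onsets <- if (n == 0) numeric(0) else cumsum(c(0, durations[-n] + 20))
  trial_gaze(n_words, sentence_spans,
             data.frame(aoi_index = aois, onset_ms = onsets,
                        duration_ms = durations),
             saccades)
}

# independent prefix-scanning oracle for the four fixation classes
oracle_labels <- function(aois) {
  n <- length(aois)
  labels <- character(n)
  for (i in seq_len(n)) {
    w <- aois[i]
    prior <- if (i > 1) aois[seq_len(i - 1)] else integer(0)
    first <- !w %in% prior
    later_seen <- any(prior > w)
    if (first) {
      labels[i] <- if (later_seen) "later_pass_first" else "first_pass_first"
    } else {
      # walk back through the consecutive same-word run containing i
      j <- i
      while (j > 1 && aois[j - 1] == w) j <- j - 1
      run_first_is_fpf <- j < i &&
        !w %in% (if (j > 1) aois[seq_len(j - 1)] else integer(0)) &&
        !any((if (j > 1) aois[seq_len(j - 1)] else integer(0)) > w)
      labels[i] <- if (run_first_is_fpf) "multi_fixation" else "re_fixation"
    }
  }
  labels
}

# a small annotated-token row
tok <- function(surface, pos = "noun", open = TRUE, present = FALSE,
                phrase = "NP", clause = "main_finite", prop = FALSE,
                dys = "none", freq = 100, word = TRUE) {
  data.frame(surface = surface, is_word = word, pos_class = pos,
             open_class = open, present_tense = present, phrase_tag = phrase,
             clause_tag = clause, proposition_flag = prop,
             dysfluency_class = dys, frequency_per_million = freq,
             stringsAsFactors = FALSE)
}

# quick small synthetic cohort with features extracted; short text keeps
# the unit tests fast
small_cohort <- function(n_hc = 4, n_mci = 4, d = 2, seed = 1,
                         n_words = 40L, n_sentences = 5L) {
  extract_features(generate_cohort(generator_config(
    n_hc = n_hc, n_mci = n_mci, effect_size = d, seed = seed,
    n_words = n_words, n_sentences = n_sentences)))
}
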