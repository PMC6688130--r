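## Synthetic cohort generator.
##
## Each participant carries a latent impairment value z (healthy controls
## z ~ N(0, 1), MCI z ~ N(d, 1) with d the configured effect size). All
## mode-level generation parameters are monotone in z, following the
## directions expected for early cognitive decline: more fixations,
## regressions and re-reading with longer first-pass fixations; slower
## speech with more and longer pauses; reduced information-unit coverage,
## lexical diversity and more dysfluencies; slower and slightly less
## accurate comprehension; lower (direction-aware: worse) neuropsychological
## scores. Generation happens at the raw-record level -- scanpaths, voiced
## intervals, annotated tokens, question responses -- so every extractor
## lies on the test path.

#' Generator configuration
#'
#' Defaults mirror a memory-clinic case-control cohort: 29 healthy controls
#' and 26 MCI participants, two 146-word reading texts of 10 sentences each,
#' five comprehension questions per text.
#'
#' @param n_hc,n_mci Group sizes.
#' @param effect_size Separation `d` of the latent impairment distributions
#'   (z is N(0,1) for HC, N(d,1) for MCI); 0 yields exchangeable groups.
#' @param seed Integer seed; generation is fully reproducible given the
#'   configuration.
#' @param n_words,n_sentences Reading text length (words are the AOIs).
#' @param n_questions Comprehension questions per reading task.
#' @param np_missing_rate Fraction of neuropsychological scores missing
#'   completely at random.
#' @param noise Named multipliers on the within-mode noise scales
#'   (`eyes`, `speech`, `language`, `comprehension`, `neuropsych`).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_hc = 29L, n_mci = 26L, effect_size = 2,
                             seed = 1L, n_words = 146L, n_sentences = 10L,
                             n_questions = 5L, np_missing_rate = 0.05,
                             noise = list()) {
  stopifnot(n_hc >= 1, n_mci >= 1, effect_size >= 0,
            n_words >= n_sentences, n_sentences >= 1, n_questions >= 1,
            np_missing_rate >= 0, np_missing_rate < 1)
  noise_full <- list(eyes = 1, speech = 1, language = 1, comprehension = 1,
                     neuropsych = 1)
  noise_full[names(noise)] <- noise
  structure(list(n_hc = as.integer(n_hc), n_mci = as.integer(n_mci),
                 effect_size = effect_size, seed = as.integer(seed),
                 n_words = as.integer(n_words),
                 n_sentences = as.integer(n_sentences),
                 n_questions = as.integer(n_questions),
                 np_missing_rate = np_missing_rate, noise = noise_full),
            class = "generator_config")
}

# ---- word bank -------------------------------------------------------------

# minimal Swedish-like vocabulary with static annotations (ASCII-folded);
# kind feeds the proposition flag (verb/adjective/adverb/preposition/
# conjunction are propositions)
word_bank <- function() {
  wb <- function(surface, pos, kind, open, phrase, freq)
    data.frame(surface = surface, pos_class = pos, kind = kind,
               open_class = open, phrase_tag = phrase,
               frequency_per_million = freq, stringsAsFactors = FALSE)
  rbind(
    wb(c("han", "hon", "den", "det", "de"), "pronoun", "pronoun", FALSE,
       "NP", c(9000, 7000, 8000, 21000, 8500)),
    wb(c("en", "ett", "denna", "nagra"), "determiner", "determiner", FALSE,
       "NP", c(28000, 15000, 900, 1200)),
    wb(c("ar", "har", "ser", "gor", "vill", "ska", "verkar", "sitter"),
       "verb", "verb", TRUE, "VG",
       c(30000, 12000, 1500, 2100, 1800, 5200, 400, 700)),
    wb(c("hus", "dag", "sak", "sida", "hand", "vagg", "stol", "bord",
         "kopp", "sko"), "noun", "noun", TRUE, "NP",
       c(800, 2500, 1100, 950, 1300, 150, 210, 340, 90, 120)),
    wb(c("stor", "liten", "glad", "hog"), "other", "adjective", TRUE, "NP",
       c(1400, 900, 300, 600)),
    wb(c("dar", "haer", "sen", "ocksa", "inte", "kanske"), "other", "adverb",
       TRUE, "none", c(3200, 5200, 1900, 2600, 16000, 800)),
    wb(c("pa", "i", "under", "vid", "bakom"), "other", "preposition", FALSE,
       "PP", c(17000, 32000, 1500, 1900, 300)),
    wb(c("och", "men", "att", "som"), "other", "conjunction", FALSE, "none",
       c(26000, 6800, 24000, 12000))
  )
}

# information-unit surfaces with their annotation rows
iu_bank <- function(lexicon) {
  nouns <- c(lexicon$subjects, lexicon$objects, lexicon$places)
  data.frame(
    surface = c(nouns, lexicon$actions),
    pos_class = c(rep("noun", length(nouns)),
                  rep("verb", length(lexicon$actions))),
    kind = c(rep("noun", length(nouns)), rep("verb", length(lexicon$actions))),
    open_class = TRUE,
    phrase_tag = c(rep("NP", length(nouns)),
                   rep("VG", length(lexicon$actions))),
    frequency_per_million = c(seq(30, 280, length.out = length(nouns)),
                              seq(40, 220, length.out = length(lexicon$actions))),
    stringsAsFactors = FALSE
  )
}

# ---- per-mode raw record generators ---------------------------------------

sentence_spans_for <- function(n_words, n_sentences) {
  bounds <- round(seq(0, n_words, length.out = n_sentences + 1))
  data.frame(first_aoi = bounds[-length(bounds)] + 1L,
             last_aoi = bounds[-1])
}

sample_trial_gaze <- function(z, config, task) {
  nw <- config$n_words
  noise <- config$noise$eyes
  p_skip <- plogis(qlogis(0.25) - 0.20 * z)
  p_refix <- plogis(qlogis(0.10) + 0.30 * z)
  p_regress <- plogis(qlogis(0.08) + 0.35 * z)
  p_reread <- if (task == "reading_silent") plogis(qlogis(0.30) + 0.50 * z)
              else plogis(qlogis(0.10) + 0.25 * z)
  dur_fpf <- function(n) rlnorm(n, log(220) + 0.08 * z, 0.25 * noise)
  dur_other <- function(n) rlnorm(n, log(180) + 0.08 * z, 0.30 * noise)

  aoi <- integer(0); dur <- numeric(0)
  add <- function(w, d) { aoi <<- c(aoi, w); dur <<- c(dur, d) }
  for (w in seq_len(nw)) {
    if (w < nw && runif(1) < p_skip) next
    add(w, dur_fpf(1))
    while (runif(1) < p_refix) add(w, dur_other(1))
    if (w > 1 && runif(1) < p_regress) {
      back <- max(1L, w - 1L - rgeom(1, 0.45))
      add(back, dur_other(1))
      add(w, dur_other(1))
    }
  }
  if (runif(1) < p_reread) {
    n_re <- 3L + rpois(1, 2 + pmax(z, 0) * 2)
    start <- sample.int(max(1L, nw %/% 2L), 1)
    w <- start
    for (i in seq_len(n_re)) {
      add(w, dur_other(1))
      w <- min(nw, w + 1L + rgeom(1, 0.6))
    }
  }
  onset <- cumsum(c(0, dur[-length(dur)] + 30))
  fixations <- data.frame(aoi_index = aoi, onset_ms = onset, duration_ms = dur)
  if (length(aoi) >= 2) {
    d_words <- abs(diff(aoi))
    amp <- ifelse(d_words == 0, runif(length(d_words), 0.05, 0.30),
                  d_words * 0.55 * runif(length(d_words), 0.85, 1.15))
    saccades <- data.frame(start_aoi = aoi[-length(aoi)], end_aoi = aoi[-1],
                           amplitude_deg = amp)
  } else {
    saccades <- data.frame(start_aoi = integer(), end_aoi = integer(),
                           amplitude_deg = numeric())
  }
  trial_gaze(nw, sentence_spans_for(nw, config$n_sentences), fixations,
             saccades)
}

sample_speech_timing <- function(z, config, task) {
  noise <- config$noise$speech
  n_chunks <- 1L + (if (task == "picture_description") 7L else 9L) +
    rpois(1, 6)
  chunk_mean <- if (task == "picture_description") log(3.0) else log(3.5)
  chunks <- rlnorm(n_chunks, chunk_mean - 0.15 * z, 0.35 * noise)
  short_gap <- runif(n_chunks - 1) < 0.25
  gaps <- ifelse(short_gap, runif(n_chunks - 1, 0.05, 0.14),
                 rlnorm(n_chunks - 1, log(0.50) + 0.28 * z, 0.50 * noise))
  lead <- runif(1, 0.2, 1.0); trail <- runif(1, 0.2, 1.0)
  starts <- lead + cumsum(c(0, chunks[-n_chunks] + gaps))
  ends <- starts + chunks
  total <- ends[n_chunks] + trail
  rate <- max(1.2, (if (task == "picture_description") 4.3 else 4.6) -
                0.35 * z + rnorm(1, 0, 0.25 * noise))
  syllables <- max(1L, round(sum(chunks) * rate))
  speech_timing(total, syllables,
                data.frame(start_s = starts, end_s = ends))
}

sample_transcript <- function(z, config, lexicon, duration_s) {
  noise <- config$noise$language
  bank <- word_bank()
  ius <- iu_bank(lexicon)
  pick <- function(df, kinds, n = 1, eff = NULL) {
    rows <- df[df$kind %in% kinds, , drop = FALSE]
    if (!is.null(eff)) rows <- rows[seq_len(min(eff, nrow(rows))), , drop = FALSE]
    rows[sample.int(nrow(rows), n, replace = TRUE), , drop = FALSE]
  }
  # impairment narrows the effective filler vocabulary (lower diversity)
  eff_nouns <- max(3L, round(10 * exp(-0.15 * z)))
  eff_verbs <- max(3L, round(8 * exp(-0.12 * z)))

  # plan information-unit mentions: coverage decreases with z
  p_mention <- plogis(1.0 - 0.50 * z)
  mentioned <- ius[runif(nrow(ius)) < p_mention, , drop = FALSE]
  reps <- 1L + rpois(nrow(mentioned), 0.3)
  iu_queue <- mentioned[rep(seq_len(nrow(mentioned)), reps), , drop = FALSE]
  if (nrow(iu_queue) > 1)
    iu_queue <- iu_queue[sample.int(nrow(iu_queue)), , drop = FALSE]
  iu_nouns <- iu_queue[iu_queue$pos_class == "noun", , drop = FALSE]
  iu_verbs <- iu_queue[iu_queue$pos_class == "verb", , drop = FALSE]
  # consuming queues of planned information-unit mentions
  ni <- 0L; vi <- 0L
  take_noun <- function() {
    if (ni >= nrow(iu_nouns)) return(NULL)
    ni <<- ni + 1L
    iu_nouns[ni, , drop = FALSE]
  }
  take_verb <- function() {
    if (vi >= nrow(iu_verbs)) return(NULL)
    vi <<- vi + 1L
    iu_verbs[vi, , drop = FALSE]
  }

  p_pronoun <- plogis(qlogis(0.25) + 0.30 * z)
  p_filled <- 0.015 * exp(0.35 * z)
  p_false <- 0.008 * exp(0.35 * z)
  n_sent <- max(3L, rpois(1, 9))
  sent_tokens <- vector("list", n_sent)
  for (s in seq_len(n_sent)) {
    clause <- sample(c("main_finite", "subordinate", "main_infinitive"), 1,
                     prob = c(0.72, 0.20, 0.08))
    toks <- list()
    push <- function(row, tag = NULL) {
      row$clause_tag <- clause
      if (!is.null(tag)) row$phrase_tag <- tag
      toks[[length(toks) + 1L]] <<- row
    }
    # subject: pronoun or noun phrase (IU noun when available)
    if (runif(1) < p_pronoun) {
      push(pick(bank, "pronoun"))
    } else {
      if (runif(1) < 0.6) push(pick(bank, "determiner"))
      got <- take_noun()
      if (!is.null(got)) push(got) else push(pick(bank, "noun", eff = eff_nouns))
    }
    # verb: IU action when available
    got <- take_verb()
    if (!is.null(got)) push(got) else push(pick(bank, "verb", eff = eff_verbs))
    # optional object
    if (runif(1) < 0.7) {
      if (runif(1) < 0.5) push(pick(bank, "determiner"))
      got <- take_noun()
      if (!is.null(got)) push(got) else push(pick(bank, "noun", eff = eff_nouns))
      if (runif(1) < 0.3) push(pick(bank, "adjective"))
    }
    # optional prepositional phrase
    if (runif(1) < 0.5) {
      push(pick(bank, "preposition"))
      got <- take_noun()
      if (!is.null(got)) push(got, tag = "PP")
      else push(pick(bank, "noun", eff = eff_nouns), tag = "PP")
    }
    if (runif(1) < 0.4) push(pick(bank, c("adverb", "conjunction")))
    sent_tokens[[s]] <- do.call(rbind, toks)
  }
  # drain remaining planned IU mentions into the last sentence
  leftover <- rbind(
    if (ni < nrow(iu_nouns)) iu_nouns[(ni + 1L):nrow(iu_nouns), , drop = FALSE],
    if (vi < nrow(iu_verbs)) iu_verbs[(vi + 1L):nrow(iu_verbs), , drop = FALSE])
  if (is.null(leftover)) leftover <- iu_nouns[0, , drop = FALSE]
  if (nrow(leftover) > 0) {
    leftover$clause_tag <- "main_finite"
    sent_tokens[[n_sent]] <- rbind(sent_tokens[[n_sent]], leftover)
  }
  tokens <- do.call(rbind, sent_tokens)
  tokens$present_tense <- tokens$pos_class == "verb" & runif(nrow(tokens)) < 0.85
  tokens$is_word <- TRUE
  tokens$dysfluency_class <- "none"
  tokens$proposition_flag <- tokens$kind %in%
    c("verb", "adjective", "adverb", "preposition", "conjunction")

  # interleave dysfluencies
  dys <- function(surface, cls, n) {
    if (n == 0) return(NULL)
    data.frame(surface = surface, pos_class = "other", kind = "dysfluency",
               open_class = FALSE, phrase_tag = "none", clause_tag = "none",
               frequency_per_million = NA_real_, present_tense = FALSE,
               is_word = FALSE, dysfluency_class = cls,
               proposition_flag = FALSE, stringsAsFactors = FALSE)[rep(1, n), ]
  }
  n_tok <- nrow(tokens)
  extra <- rbind(dys("eh", "filled_pause", rbinom(1, n_tok, min(p_filled, 1))),
                 dys("sa-", "false_start", rbinom(1, n_tok, min(p_false, 1))))
  if (!is.null(extra) && nrow(extra) > 0) {
    pos <- sample.int(n_tok, nrow(extra), replace = TRUE)
    tokens <- rbind(tokens, extra)
    ord <- order(c(seq_len(n_tok), pos + 0.5))
    tokens <- tokens[ord, , drop = FALSE]
  }
  tokens$kind <- NULL
  rownames(tokens) <- NULL
  incomplete <- rbinom(1, n_sent, plogis(-3 + 0.50 * z))
  annotated_transcript(tokens, sentence_count = n_sent,
                       incomplete_sentence_count = incomplete,
                       sample_duration_s = duration_s)
}

sample_comprehension <- function(z, config) {
  noise <- config$noise$comprehension
  q <- config$n_questions
  comprehension_responses(
    correct = rbinom(q, 1, plogis(2.2 - 0.45 * z)),
    response_time_ms = rlnorm(q, log(3500) + 0.18 * z, 0.30 * noise)
  )
}

# reference population for the neuropsychological battery: healthy-aging
# means/sds with per-test loadings on the latent impairment scale
np_population <- function() {
  data.frame(
    test = neuropsych_battery()$test,
    mean = c(29.6, 45.5, 9.2, 9.5, 18.8, 18.6, 21.9, 25.8,
             53.3, 47.2, 24.6, 20.9, 13.1, 62.9, 34.1, 79.8,
             40.6, 33.6, 22.4, 9.5, 68.2, 13.2, 17.6, 24.1, 1.8),
    sd = c(0.6, 11.1, 3.6, 3.5, 5.1, 4.4, 8.1, 6.3,
           4.6, 11.5, 4.7, 1.4, 3.5, 12.3, 11.9, 32.9,
           9.5, 2.4, 4.2, 2.3, 21.5, 2.4, 3.4, 6.6, 0.4),
    loading = c(0.50, 0.55, 0.60, 0.60, 0.45, 0.50, 0.50, 0.50,
                0.30, 0.25, 0.15, 0.30, 0.15, 0.35, 0.25, 0.30,
                0.25, 0.20, 0.40, 0.20, 0.40, 0.20, 0.20, 0.30, 0.10),
    stringsAsFactors = FALSE
  )
}

sample_neuropsych <- function(z, config, id, age) {
  pop <- np_population()
  battery <- neuropsych_battery()
  noise <- config$noise$neuropsych
  dir <- ifelse(battery$higher_is_better[match(pop$test, battery$test)], -1, 1)
  eps <- rnorm(nrow(pop), 0, noise)
  score <- pop$mean + pop$sd *
    (dir * pop$loading * z + sqrt(pmax(1 - pop$loading^2, 0)) * eps)
  miss <- runif(nrow(pop)) < config$np_missing_rate
  score[miss] <- NA_real_
  out <- as.data.frame(as.list(setNames(score, pop$test)))
  cbind(data.frame(participant_id = id, age = age, stringsAsFactors = FALSE),
        out)
}

# ---- session / cohort ------------------------------------------------------

#' Sample one synthetic session
#'
#' Generates the seven raw (task, mode) records plus a neuropsychological
#' profile for a participant with latent impairment `z`.
#'
#' @param z Latent impairment value.
#' @param config A [generator_config()].
#' @param participant_id,diagnosis Identity and 0/1 label of the session.
#' @param lexicon Information-unit lexicon used for transcript generation.
#' @return List with `session` (a complete [session_record()]) and
#'   `neuropsych` (one-row profile data frame).
#' @export
sample_session <- function(z, config, participant_id, diagnosis = NA,
                           lexicon = default_iu_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  pd_speech <- sample_speech_timing(z, config, "picture_description")
  records <- list()
  records[[slot_id("picture_description", "language")]] <-
    sample_transcript(z, config, lexicon, pd_speech$total_duration_s)
  records[[slot_id("picture_description", "speech")]] <- pd_speech
  records[[slot_id("reading_silent", "eyes")]] <-
    sample_trial_gaze(z, config, "reading_silent")
  records[[slot_id("reading_silent", "comprehension")]] <-
    sample_comprehension(z, config)
  records[[slot_id("reading_aloud", "eyes")]] <-
    sample_trial_gaze(z, config, "reading_aloud")
  records[[slot_id("reading_aloud", "comprehension")]] <-
    sample_comprehension(z, config)
  records[[slot_id("reading_aloud", "speech")]] <-
    sample_speech_timing(z, config, "reading_aloud")
  age <- round(runif(1, 50, 79))
  list(session = session_record(participant_id, diagnosis, records),
       neuropsych = sample_neuropsych(z, config, participant_id, age))
}

#' Generate a labeled synthetic cohort
#'
#' @param config A [generator_config()].
#' @param lexicon Information-unit lexicon for transcript generation.
#' @return A [cohort_dataset()] with `n_hc + n_mci` complete sessions and
#'   attached neuropsychological profiles; deterministic given the
#'   configuration (including its seed).
#' @examples
#' coh <- generate_cohort(generator_config(n_hc = 3, n_mci = 2, seed = 7))
#' coh
#' @export
generate_cohort <- function(config = generator_config(),
                            lexicon = default_iu_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_hc + config$n_mci
  labels <- c(rep(0L, config$n_hc), rep(1L, config$n_mci))
  ids <- sprintf("S%03d", seq_len(n))
  with_seed(config$seed, {
    zs <- rnorm(n, mean = labels * config$effect_size, sd = 1)
    out <- lapply(seq_len(n), function(i)
      sample_session(zs[i], config, ids[i], labels[i], lexicon))
  })
  cohort <- cohort_dataset(sessions = lapply(out, `[[`, "session"),
                           neuropsych = do.call(rbind,
                                                lapply(out, `[[`, "neuropsych")))
  # the drawn latent values, exposed for calibration checks
  attr(cohort, "latent_z") <- setNames(zs, ids)
  cohort
}
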