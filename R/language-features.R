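## Linguistic features from token-annotated picture-description transcripts.
##
## Tokens arrive annotated (part-of-speech class, phrase/clause tags,
## dysfluency class, corpus frequency); no tagging or parsing happens here.
## "Counted words" excludes punctuation/non-word tokens and all dysfluent
## tokens (filled pauses, false starts).

#' Information-unit lexicon
#'
#' Keyword lemmas for the four content-unit categories of the Cookie Theft
#' scene: subjects, objects, places and actions. The bundled default is a
#' Swedish-like inventory with the standard category sizes 3/11/2/7.
#'
#' @param subjects,objects,places,actions Character vectors of keyword
#'   lemmas per category.
#' @return An object of class `iu_lexicon` (named list of lowercased
#'   keyword vectors).
#' @export
iu_lexicon <- function(subjects, objects, places, actions) {
  lex <- list(subjects = tolower(subjects), objects = tolower(objects),
              places = tolower(places), actions = tolower(actions))
  if (any(vapply(lex, length, integer(1)) == 0))
    stop("every lexicon category must be non-empty", call. = FALSE)
  structure(lex, class = "iu_lexicon")
}

#' @rdname iu_lexicon
#' @export
default_iu_lexicon <- function() {
  iu_lexicon(
    subjects = c("pojke", "flicka", "mamma"),
    objects  = c("kaka", "burk", "pall", "fonster", "disk",
                 "vatten", "tallrik", "gardin", "golv", "vask", "hylla"),
    places   = c("kok", "tradgard"),
    actions  = c("ramlar", "torkar", "svammar", "racker", "tar", "star",
                 "diskar")
  )
}

#' @param path JSON file mapping category names to keyword lists.
#' @rdname iu_lexicon
#' @export
read_iu_lexicon <- function(path) {
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("subjects", "objects", "places", "actions")
  miss <- setdiff(need, names(lex))
  if (length(miss))
    stop("lexicon JSON lacks category(ies): ", paste(miss, collapse = ", "),
         call. = FALSE)
  iu_lexicon(lex$subjects, lex$objects, lex$places, lex$actions)
}

#' Keyword-spot information units in a transcript
#'
#' Matches counted-word surfaces (case-insensitive) against the lexicon.
#' The distinct count per category is the number of lexicon units matched at
#' least once; total mentions count every match occurrence, including
#' repetitions.
#'
#' @param transcript An [annotated_transcript()].
#' @param lexicon An [iu_lexicon()].
#' @return List with `distinct` (named integer per category) and
#'   `total_mentions` (integer, across all categories).
#' @export
spot_information_units <- function(transcript, lexicon = default_iu_lexicon()) {
  stopifnot(inherits(transcript, "annotated_transcript"),
            inherits(lexicon, "iu_lexicon"))
  words <- counted_words(transcript)
  surfaces <- tolower(words$surface)
  distinct <- vapply(lexicon, function(keys) sum(keys %in% surfaces), integer(1))
  mentions <- sum(surfaces %in% unlist(lexicon))
  list(distinct = distinct, total_mentions = as.integer(mentions))
}

counted_words <- function(transcript) {
  tok <- transcript$tokens
  tok[tok$is_word & tok$dysfluency_class == "none", , drop = FALSE]
}

#' Extract the 26 linguistic features of a picture description
#'
#' Total words; mean length of sentence; word proportions per phrase type
#' (PP, NP, verb group) and clause type (main finite, main infinitive,
#' subordinate); part-of-speech ratios (noun/verb, pronoun/noun,
#' determiner/noun, open/closed class); proportion of present-tense verbs;
#' median corpus word frequency; type-token ratio over lowercased counted
#' words; normalized distinct information-unit counts per category; content
#' density and efficiency (total unit mentions per word and per second);
#' propositional density; and the dysfluency measures (filled pauses, false
#' starts and incomplete sentences per word, plus their summed index).
#' Ratios with a zero denominator (e.g. noun/verb with no verbs) are masked
#' missing.
#'
#' @param transcript An [annotated_transcript()].
#' @param lexicon An [iu_lexicon()].
#' @param task Task the transcript belongs to.
#' @return A [feature_vector()] of mode `language` (26 features).
#' @export
extract_language_features <- function(transcript,
                                      lexicon = default_iu_lexicon(),
                                      task = "picture_description") {
  stopifnot(inherits(transcript, "annotated_transcript"))
  tok <- transcript$tokens
  words <- counted_words(transcript)
  n_words <- nrow(words)
  if (n_words == 0)
    stop("transcript contains no countable words", call. = FALSE)

  n_nouns <- sum(words$pos_class == "noun")
  n_verbs <- sum(words$pos_class == "verb")
  n_pron <- sum(words$pos_class == "pronoun")
  n_det <- sum(words$pos_class == "determiner")
  n_open <- sum(words$open_class)
  n_closed <- n_words - n_open

  prop_tag <- function(col, tag) sum(words[[col]] == tag) / n_words

  freqs <- words$frequency_per_million
  freqs <- freqs[!is.na(freqs)]

  iu <- spot_information_units(transcript, lexicon)

  n_filled <- sum(tok$dysfluency_class == "filled_pause")
  n_false <- sum(tok$dysfluency_class == "false_start")
  n_incomplete <- transcript$incomplete_sentence_count

  vals <- c(
    total_words = n_words,
    mean_length_sentence = n_words / transcript$sentence_count,
    prop_pp_words = prop_tag("phrase_tag", "PP"),
    prop_np_words = prop_tag("phrase_tag", "NP"),
    prop_vg_words = prop_tag("phrase_tag", "VG"),
    prop_main_finite_clause_words = prop_tag("clause_tag", "main_finite"),
    prop_main_infinitive_clause_words = prop_tag("clause_tag", "main_infinitive"),
    prop_subordinate_clause_words = prop_tag("clause_tag", "subordinate"),
    ratio_noun_verb = masked_ratio(n_nouns, n_verbs),
    ratio_pronoun_noun = masked_ratio(n_pron, n_nouns),
    ratio_determiner_noun = masked_ratio(n_det, n_nouns),
    ratio_open_closed = masked_ratio(n_open, n_closed),
    prop_present_tense_verbs = masked_ratio(sum(words$pos_class == "verb" &
                                                  words$present_tense), n_verbs),
    median_word_frequency = if (length(freqs)) median(freqs) else NA_real_,
    type_token_ratio = length(unique(tolower(words$surface))) / n_words,
    iu_subjects_norm = iu$distinct[["subjects"]] / n_words,
    iu_objects_norm = iu$distinct[["objects"]] / n_words,
    iu_places_norm = iu$distinct[["places"]] / n_words,
    iu_actions_norm = iu$distinct[["actions"]] / n_words,
    content_density = iu$total_mentions / n_words,
    content_efficiency = iu$total_mentions / transcript$sample_duration_s,
    propositional_density = sum(words$proposition_flag) / n_words,
    filled_pauses_per_word = n_filled / n_words,
    false_starts_per_word = n_false / n_words,
    incomplete_sentences_per_word = n_incomplete / n_words,
    dysfluency_index = (n_filled + n_false + n_incomplete) / n_words
  )
  feature_vector(vals, mode = "language", task = task)
}
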