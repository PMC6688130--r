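lex <- default_iu_lexicon()

test_that("information-unit spotting counts distinct units and mentions", {
  tokens <- rbind(tok("Pojke"), tok("springer", pos = "verb", phrase = "VG"),
                  tok("pojke"), tok("mamma"), tok("hus"))
  tr <- annotated_transcript(tokens, sentence_count = 2,
                             sample_duration_s = 30)
  iu <- spot_information_units(tr, lex)
  expect_identical(iu$distinct[["subjects"]], 2L)   # pojke, mamma
  expect_identical(iu$total_mentions, 3L)           # pojke x2 + mamma

  none <- annotated_transcript(rbind(tok("hus"), tok("dag")), 1, 0, 30)
  iu0 <- spot_information_units(none, lex)
  expect_true(all(iu0$distinct == 0))
  expect_identical(iu0$total_mentions, 0L)

  all_places <- annotated_transcript(rbind(tok("kok"), tok("tradgard")),
                                     1, 0, 30)
  expect_identical(spot_information_units(all_places, lex)$distinct[["places"]],
                   2L)
})

test_that("sentence, lexical-diversity and dysfluency features match hand counts", {
  words <- c("the", "boy", "takes", "a", "cookie", "the", "boy", "falls")
  tokens <- do.call(rbind, lapply(words, tok))
  tr <- annotated_transcript(tokens, sentence_count = 2,
                             sample_duration_s = 20)
  fv <- extract_language_features(tr, lex)
  expect_equal(fv[["total_words"]], 8)
  expect_equal(fv[["mean_length_sentence"]], 4.0)
  expect_equal(fv[["type_token_ratio"]], 6 / 8)

  # 2 filled pauses + 1 false start + 1 incomplete sentence over 40 words
  forty <- do.call(rbind, lapply(sprintf("w%02d", 1:40), tok))
  dys <- rbind(tok("eh", dys = "filled_pause", word = FALSE),
               tok("eh", dys = "filled_pause", word = FALSE),
               tok("fa-", dys = "false_start", word = FALSE))
  tr2 <- annotated_transcript(rbind(forty, dys), sentence_count = 5,
                              incomplete_sentence_count = 1,
                              sample_duration_s = 60)
  fv2 <- extract_language_features(tr2, lex)
  expect_equal(fv2[["total_words"]], 40)
  expect_equal(fv2[["filled_pauses_per_word"]], 2 / 40)
  expect_equal(fv2[["false_starts_per_word"]], 1 / 40)
  expect_equal(fv2[["incomplete_sentences_per_word"]], 1 / 40)
  expect_equal(fv2[["dysfluency_index"]], 0.1)
})

test_that("ratios mask on zero denominators and the even median averages", {
  nouns_only <- annotated_transcript(
    rbind(tok("hus", freq = 10), tok("dag", freq = 30),
          tok("sak", freq = 20), tok("sida", freq = 40)),
    sentence_count = 1, sample_duration_s = 10)
  fv <- extract_language_features(nouns_only, lex)
  expect_true(is.na(fv[["ratio_noun_verb"]]))
  expect_true(is.na(fv[["prop_present_tense_verbs"]]))
  expect_equal(fv[["median_word_frequency"]], 25)  # mean of 20 and 30

  verbs_only <- annotated_transcript(
    rbind(tok("ser", pos = "verb", phrase = "VG", prop = TRUE),
          tok("gor", pos = "verb", phrase = "VG", prop = TRUE)),
    sentence_count = 1, sample_duration_s = 10)
  fv2 <- extract_language_features(verbs_only, lex)
  expect_true(is.na(fv2[["ratio_pronoun_noun"]]))
  expect_true(is.na(fv2[["ratio_determiner_noun"]]))
  expect_equal(fv2[["propositional_density"]], 1)
})

test_that("proportion features are proportions and exclude dysfluent tokens", {
  coh <- small_cohort(n_hc = 2, n_mci = 2, d = 3, seed = 21)
  props <- c("prop_pp_words", "prop_np_words", "prop_vg_words",
             "prop_main_finite_clause_words",
             "prop_main_infinitive_clause_words",
             "prop_subordinate_clause_words", "prop_present_tense_verbs",
             "type_token_ratio", "content_density", "propositional_density")
  for (s in coh$sessions) {
    fv <- s$features[["picture_description.language"]]
    vals <- fv[props]
    expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
    tr <- s$records[["picture_description.language"]]
    n_countable <- sum(tr$tokens$is_word & tr$tokens$dysfluency_class == "none")
    expect_equal(fv[["total_words"]], n_countable)
  }
})

test_that("verbatim doubling preserves proportions and lowers diversity", {
  tokens <- rbind(tok("pojke"), tok("tar", pos = "verb", phrase = "VG",
                                    prop = TRUE, present = TRUE),
                  tok("en", pos = "determiner", open = FALSE),
                  tok("kaka"), tok("och", pos = "other", open = FALSE,
                                   phrase = "none", prop = TRUE),
                  tok("ramlar", pos = "verb", phrase = "VG", prop = TRUE))
  t1 <- annotated_transcript(tokens, 1, 0, 30)
  t2 <- annotated_transcript(rbind(tokens, tokens), 2, 0, 30)
  f1 <- extract_language_features(t1, lex)
  f2 <- extract_language_features(t2, lex)
  unchanged <- c("mean_length_sentence", "prop_np_words", "prop_vg_words",
                 "prop_main_finite_clause_words", "ratio_noun_verb",
                 "ratio_determiner_noun", "ratio_open_closed",
                 "prop_present_tense_verbs", "propositional_density",
                 "median_word_frequency")
  for (f in unchanged) expect_equal(f2[[f]], f1[[f]], info = f)
  expect_lt(f2[["type_token_ratio"]], f1[["type_token_ratio"]])
})
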