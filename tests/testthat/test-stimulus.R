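# Word classification, speech rate, word position, and impulse matrices.

make_ann <- function(onsets, pos, sent_id, sent_bounds, interrog,
                     phon = NULL, duration = max(sent_bounds)) {
  words <- data.frame(onset_s = onsets, form = sprintf("w%d",
                                                       seq_along(onsets)),
                      pos_tag = pos, sentence_id = sent_id,
                      stringsAsFactors = FALSE)
  n_s <- length(sent_bounds) - 1
  sent <- data.frame(sentence_id = seq_len(n_s),
                     onset_s = sent_bounds[-length(sent_bounds)],
                     offset_s = sent_bounds[-1],
                     interrogative = interrog)
  if (is.null(phon))
    phon <- data.frame(onset_s = numeric(0), class = character(0),
                       stringsAsFactors = FALSE)
  speech_annotation(1, duration, words, phon, sent)
}

test_that("POS tags map deterministically onto the 15-class inventory", {
  got <- classify_word(c("general_noun", "preposition", "zzz_not_a_tag",
                         "NN", "IN", "MD"))
  expect_equal(got$pos_class,
               c("general_noun", "preposition", "others", "general_noun",
                 "preposition", "auxiliary_verb"))
  expect_equal(got$word_class,
               c("open", "closed", "other", "open", "closed", "closed"))
  expect_error(classify_word(""), "non-empty")
  # inventory contract: 6 open, 8 closed, 1 other
  pc <- pos_classes()
  expect_equal(sum(pc$word_class == "open"), 6)
  expect_equal(sum(pc$word_class == "closed"), 8)
  expect_equal(nrow(pc), 15)
})

test_that("speech rate uses syllables per minute with an inclusive fast boundary", {
  mk <- function(n_syl, dur) {
    phon <- data.frame(onset_s = seq(0.01, dur - 0.01, length.out = n_syl),
                       class = rep("short_vowel", n_syl),
                       stringsAsFactors = FALSE)
    make_ann(0.1, "verb", 1L, c(0, dur), FALSE, phon)
  }
  expect_equal(compute_speech_rate(mk(10, 2.4), 1),
               list(spm = 250, rate_class = "fast"))
  expect_equal(compute_speech_rate(mk(9, 2.4), 1),
               list(spm = 225, rate_class = "slow"))
  expect_equal(compute_speech_rate(mk(23, 6), 1)$spm, 230)
  expect_equal(compute_speech_rate(mk(23, 6), 1)$rate_class, "fast")
  bad <- make_ann(0.1, "verb", 1L, c(0, 1), FALSE)
  bad$sentences$offset_s <- 0
  expect_error(compute_speech_rate(bad, 1), "positive")
})

test_that("word positions split into ordinal tertiles with interrogative exclusion", {
  ann <- make_ann(seq(0.1, 29.9, length.out = 30), rep("verb", 30),
                  rep(1L, 30), c(0, 30), FALSE)
  pos <- assign_position(ann)
  expect_equal(pos[1], "beginning")
  expect_equal(pos[15], "middle")
  expect_equal(pos[30], "end")
  expect_equal(as.integer(table(pos)[c("beginning", "middle", "end")]),
               c(10L, 10L, 10L))
  # words of a trial-final interrogative sentence are excluded
  ann2 <- make_ann(c(seq(0.5, 8, length.out = 9), 9.0, 9.5),
                   rep("verb", 11), c(rep(1L, 9), 2L, 2L),
                   c(0, 8.5, 10), c(FALSE, TRUE))
  pos2 <- assign_position(ann2)
  expect_equal(pos2[10:11], c("excluded", "excluded"))
  expect_equal(sum(pos2 == "beginning"), 3)
})

test_that("impulse matrices place single 1s at rounded onset samples", {
  ann <- make_ann(1.000, "general_noun", 1L, c(0, 2), FALSE)
  sm <- build_stimulus_matrix(ann, "word_class", fs = 200)
  expect_equal(ncol(sm$values), 400)
  expect_equal(unname(sm$values["open", 201]), 1)   # 0-based sample 200
  expect_equal(sum(sm$values["open", ]), 1)
  expect_true(all(sm$values %in% c(0, 1)))

  # zero events -> all-zero matrix of the right shape
  empty <- speech_annotation(1, 2, data.frame(onset_s = numeric(0),
                                              form = character(0),
                                              pos_tag = character(0),
                                              sentence_id = integer(0)),
                             data.frame(onset_s = numeric(0),
                                        class = character(0)),
                             data.frame(sentence_id = integer(0),
                                        onset_s = numeric(0),
                                        offset_s = numeric(0),
                                        interrogative = logical(0)))
  sm0 <- build_stimulus_matrix(empty, "word_class", fs = 200)
  expect_equal(dim(sm0$values), c(13L, 400L))
  expect_equal(sum(sm0$values), 0)

  # colliding impulses clip at 1
  ann2 <- make_ann(c(1.000, 1.001), c("general_noun", "verb"), c(1L, 1L),
                   c(0, 2), FALSE)
  sm2 <- build_stimulus_matrix(ann2, "word_class", fs = 200)
  expect_equal(unname(sm2$values["open", 201]), 1)
})

test_that("no word impulse is lost or duplicated across schemes", {
  ann <- simulate_annotations(1, 20, 2.5, seed = 11)[[1]]
  cls <- classify_word(ann$words$pos_tag)
  for (scheme in c("word_class", "word_position", "speech_rate",
                   "parts_of_speech")) {
    sm <- build_stimulus_matrix(ann, scheme, fs = 1000,
                                include_phonemes = FALSE,
                                include_sentence = FALSE)
    n_expected <- switch(scheme,
      word_class = sum(cls$word_class != "other"),
      parts_of_speech = sum(cls$pos_class != "others"),
      word_position = sum(assign_position(ann) != "excluded"),
      speech_rate = sum(cls$word_class %in% c("open", "closed")))
    expect_equal(sum(sm$values), n_expected, info = scheme)
  }
  # open+closed impulse count >= POS scheme count (POS drops "others")
  wc <- build_stimulus_matrix(ann, "word_class", fs = 1000,
                              include_phonemes = FALSE,
                              include_sentence = FALSE)
  ps <- build_stimulus_matrix(ann, "parts_of_speech", fs = 1000,
                              include_phonemes = FALSE,
                              include_sentence = FALSE)
  expect_gte(sum(wc$values), sum(ps$values))
  # idempotence
  expect_identical(build_stimulus_matrix(ann, "word_class", fs = 200),
                   build_stimulus_matrix(ann, "word_class", fs = 200))
})

test_that("onsets beyond the trial duration are rejected", {
  ann <- make_ann(1.0, "verb", 1L, c(0, 2), FALSE)
  ann$phonemes <- data.frame(onset_s = 5, class = "short_vowel",
                             stringsAsFactors = FALSE)
  expect_error(build_stimulus_matrix(ann, "word_class", fs = 100),
               "outside trial duration")
})
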