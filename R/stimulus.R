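## Speech annotations and impulse stimulus matrices.
##
## Four schemes of binary (0/1) feature-by-time matrices are built from timed
## word/phoneme/sentence annotations: word class (open/closed), word position
## (beginning/middle/end tertiles), speech rate (fast/slow by
## syllables-per-minute), and 14 parts of speech.  Phoneme-class and
## sentence-boundary rows are appended to every scheme so that acoustic and
## prosodic responses are absorbed by their own kernels.

#' The 9 articulatory phoneme classes
#' @return Character vector.
#' @export
phoneme_classes <- function() {
  c("short_vowel", "long_vowel", "diphthong", "plosive", "affricate",
    "fricative", "nasal", "liquid", "semivowel")
}

# vowel nuclei used for syllable counting
vowel_nuclei <- function() c("short_vowel", "long_vowel", "diphthong")

#' The 15 part-of-speech classes and their open/closed membership
#'
#' The first six classes are open (content) classes, the next eight closed
#' (function) classes, and `others` is outside both.
#' @return Data frame with `pos_class` and `word_class`.
#' @export
pos_classes <- function() {
  open <- c("general_noun", "proper_noun", "verb", "adjective", "adverb",
            "number")
  closed <- c("article_determiner", "pronoun", "interrogative_word",
              "relative_pronoun", "be_verb", "auxiliary_verb", "preposition",
              "conjunction")
  data.frame(pos_class = c(open, closed, "others"),
             word_class = c(rep("open", length(open)),
                            rep("closed", length(closed)), "other"),
             stringsAsFactors = FALSE)
}

# tag -> pos_class table: canonical class names plus common Penn-style tags
pos_tag_table <- function() {
  c(general_noun = "general_noun", proper_noun = "proper_noun",
    verb = "verb", adjective = "adjective", adverb = "adverb",
    number = "number", article_determiner = "article_determiner",
    pronoun = "pronoun", interrogative_word = "interrogative_word",
    relative_pronoun = "relative_pronoun", be_verb = "be_verb",
    auxiliary_verb = "auxiliary_verb", preposition = "preposition",
    conjunction = "conjunction", others = "others",
    NN = "general_noun", NNS = "general_noun", NNP = "proper_noun",
    NNPS = "proper_noun", VB = "verb", VBD = "verb", VBG = "verb",
    VBN = "verb", VBP = "verb", VBZ = "verb", JJ = "adjective",
    JJR = "adjective", JJS = "adjective", RB = "adverb", RBR = "adverb",
    RBS = "adverb", CD = "number", DT = "article_determiner",
    PDT = "article_determiner", PRP = "pronoun", "PRP$" = "pronoun",
    WP = "interrogative_word", WRB = "interrogative_word",
    WDT = "relative_pronoun", MD = "auxiliary_verb", IN = "preposition",
    TO = "preposition", CC = "conjunction", UH = "others", FW = "others")
}

#' Classify a part-of-speech tag into the 15-class inventory
#'
#' Deterministic lookup through a documented tag table (canonical class names
#' and common Penn-treebank tags); unmapped tags fall back to
#' `others`/`other`.
#'
#' @param pos_tag Character vector of tags (non-empty strings).
#' @return Data frame with `pos_class` and `word_class` (open/closed/other).
#' @export
classify_word <- function(pos_tag) {
  if (length(pos_tag) == 0 || any(is.na(pos_tag)) || any(!nzchar(pos_tag)))
    stop("pos_tag must be non-empty", call. = FALSE)
  tab <- pos_tag_table()
  cls <- unname(tab[pos_tag])
  cls[is.na(cls)] <- "others"
  pc <- pos_classes()
  data.frame(pos_class = cls,
             word_class = pc$word_class[match(cls, pc$pos_class)],
             stringsAsFactors = FALSE)
}

#' Container for one trial's speech annotation
#'
#' @param trial_id Trial identifier.
#' @param duration_s Trial duration in seconds.
#' @param words Data frame: `onset_s`, `form`, `pos_tag`, `sentence_id`.
#' @param phonemes Data frame: `onset_s`, `class` (9-class inventory).
#' @param sentences Data frame: `sentence_id`, `onset_s`, `offset_s`,
#'   `interrogative`.
#' @return Object of class `speech_annotation`.
#' @export
speech_annotation <- function(trial_id, duration_s, words, phonemes,
                              sentences) {
  stopifnot(duration_s > 0)
  if (nrow(words)) {
    if (any(words$onset_s < 0) || any(words$onset_s > duration_s))
      stop("word onsets must lie within [0, duration]", call. = FALSE)
    if (is.unsorted(words$onset_s, strictly = FALSE))
      stop("word onsets must be non-decreasing", call. = FALSE)
    if (!all(words$sentence_id %in% sentences$sentence_id))
      stop("every word's sentence_id must exist", call. = FALSE)
  }
  if (nrow(phonemes) && !all(phonemes$class %in% phoneme_classes()))
    stop("phoneme classes must come from the 9-class inventory",
         call. = FALSE)
  structure(list(trial_id = trial_id, duration_s = duration_s,
                 words = words, phonemes = phonemes, sentences = sentences),
            class = "speech_annotation")
}

#' @export
print.speech_annotation <- function(x, ...) {
  cat(sprintf("<speech_annotation> trial %s: %.1f s, %d words, %d phonemes, %d sentences\n",
              x$trial_id, x$duration_s, nrow(x$words), nrow(x$phonemes),
              nrow(x$sentences)))
  invisible(x)
}

#' Speech rate of a sentence in syllables per minute
#'
#' Syllables are counted as vowel-nucleus phonemes (short vowel, long vowel,
#' diphthong) with onsets inside the sentence interval;
#' `spm = syllables * 60 / (offset - onset)`.  Sentences at or above 230 SPM
#' are `fast`, below are `slow`.
#'
#' @param annotation A [speech_annotation()].
#' @param sentence_id Sentence to measure.
#' @param threshold_spm Fast/slow boundary (inclusive on the fast side).
#' @return List: `spm`, `rate_class`.
#' @export
compute_speech_rate <- function(annotation, sentence_id,
                                threshold_spm = 230) {
  s <- annotation$sentences
  row <- s[s$sentence_id == sentence_id, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown sentence_id", call. = FALSE)
  dur <- row$offset_s - row$onset_s
  if (dur <= 0) stop("sentence duration must be positive", call. = FALSE)
  ph <- annotation$phonemes
  syl <- sum(ph$class %in% vowel_nuclei() &
               ph$onset_s >= row$onset_s & ph$onset_s < row$offset_s)
  spm <- syl * 60 / dur
  list(spm = spm, rate_class = if (spm >= threshold_spm) "fast" else "slow")
}

#' Word position within a trial
#'
#' Words belonging to a trial-final interrogative sentence are `excluded`
#' (these sentences are task probes at the end of the stimulus); the
#' remaining words are split by their ordinal into first/middle/last
#' tertiles with boundaries at `ceil(n/3)` and `ceil(2n/3)`.
#'
#' @param annotation A [speech_annotation()].
#' @param word_index Index into `annotation$words` (vectorized; defaults to
#'   all words).
#' @return Character vector: `beginning`, `middle`, `end`, or `excluded`.
#' @export
assign_position <- function(annotation,
                            word_index = seq_len(nrow(annotation$words))) {
  w <- annotation$words
  if (any(word_index < 1 | word_index > nrow(w)))
    stop("word_index out of range", call. = FALSE)
  s <- annotation$sentences
  excluded_sent <- integer(0)
  if (nrow(s)) {
    last <- s$sentence_id[which.max(s$offset_s)]
    if (s$interrogative[s$sentence_id == last]) excluded_sent <- last
  }
  keep <- !(w$sentence_id %in% excluded_sent)
  pos <- rep(NA_character_, nrow(w))
  pos[!keep] <- "excluded"
  idx <- which(keep)
  n <- length(idx)
  if (n) {
    ord <- seq_len(n)              # words are onset-ordered
    b1 <- ceiling(n / 3); b2 <- ceiling(2 * n / 3)
    pos[idx] <- ifelse(ord <= b1, "beginning",
                       ifelse(ord <= b2, "middle", "end"))
  }
  pos[word_index]
}

# word-feature rows of each scheme (before phoneme/sentence augmentation)
scheme_word_features <- function(scheme) {
  switch(scheme,
         word_class = c("open", "closed"),
         word_position = c("beginning", "middle", "end"),
         speech_rate = c("fast", "slow"),
         parts_of_speech = setdiff(pos_classes()$pos_class, "others"),
         stop("unknown scheme: ", scheme, call. = FALSE))
}

#' Impulse stimulus-matrix container
#' @param scheme Scheme name.
#' @param feature_names Ordered row names.
#' @param values Binary features x time matrix.
#' @param fs Sampling rate (Hz).
#' @param trial_id Trial identifier.
#' @return Object of class `stimulus_matrix`.
#' @export
stimulus_matrix <- function(scheme, feature_names, values, fs, trial_id) {
  stopifnot(nrow(values) == length(feature_names), fs > 0,
            all(values %in% c(0, 1)))
  structure(list(scheme = scheme, feature_names = feature_names,
                 values = values, fs = fs, trial_id = trial_id),
            class = "stimulus_matrix")
}

#' @export
print.stimulus_matrix <- function(x, ...) {
  cat(sprintf("<stimulus_matrix> scheme %s, trial %s: %d features x %d samples @ %g Hz (%d impulses)\n",
              x$scheme, x$trial_id, nrow(x$values), ncol(x$values), x$fs,
              sum(x$values)))
  invisible(x)
}

#' Build an impulse stimulus matrix from a speech annotation
#'
#' Places a time-aligned impulse of value 1 at the onset sample of every
#' event on its feature row (0 elsewhere).  Onsets are discretized by
#' rounding half away from zero to the nearest sample (0-based sample
#' indices, time 0 = trial start); coinciding impulses clip at 1.  Word rows
#' depend on the scheme; the 9 phoneme-class rows and sentence
#' beginning/ending rows are appended by default.
#'
#' @param annotation A [speech_annotation()].
#' @param scheme One of `word_class`, `word_position`, `speech_rate`,
#'   `parts_of_speech`.
#' @param fs Sampling rate in Hz (> 0).
#' @param include_phonemes,include_sentence Append phoneme-class /
#'   sentence-boundary rows.
#' @param rate_word_classes Word classes entering the `speech_rate` scheme
#'   (default pools open and closed words; set to `"open"` to restrict).
#' @return A [stimulus_matrix()].
#' @export
build_stimulus_matrix <- function(annotation, scheme = "word_class",
                                  fs = 200,
                                  include_phonemes = TRUE,
                                  include_sentence = TRUE,
                                  rate_word_classes = c("open", "closed")) {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  word_feats <- scheme_word_features(scheme)
  feats <- c(word_feats,
             if (include_phonemes) phoneme_classes(),
             if (include_sentence) c("sentence_beginning", "sentence_ending"))
  Tn <- max(1L, as.integer(round(annotation$duration_s * fs)))
  M <- matrix(0, length(feats), Tn, dimnames = list(feats, NULL))

  put <- function(feature, onsets) {
    if (!length(onsets)) return()
    if (any(onsets < 0 | onsets > annotation$duration_s))
      stop("event onset outside trial duration", call. = FALSE)
    col <- pmin(pmax(round_half_away(onsets * fs) + 1L, 1L), Tn)
    M[feature, col] <<- 1
  }

  w <- annotation$words
  if (nrow(w)) {
    cls <- classify_word(w$pos_tag)
    if (scheme == "word_class") {
      for (f in word_feats) put(f, w$onset_s[cls$word_class == f])
    } else if (scheme == "parts_of_speech") {
      for (f in word_feats) put(f, w$onset_s[cls$pos_class == f])
    } else if (scheme == "word_position") {
      posn <- assign_position(annotation)
      for (f in word_feats) put(f, w$onset_s[posn == f])
    } else if (scheme == "speech_rate") {
      keep <- cls$word_class %in% rate_word_classes
      rate <- vapply(annotation$sentences$sentence_id, function(sid)
        compute_speech_rate(annotation, sid)$rate_class, character(1))
      names(rate) <- annotation$sentences$sentence_id
      wr <- rate[as.character(w$sentence_id)]
      for (f in word_feats) put(f, w$onset_s[keep & wr == f])
    }
  }
  if (include_phonemes && nrow(annotation$phonemes)) {
    ph <- annotation$phonemes
    for (f in phoneme_classes()) put(f, ph$onset_s[ph$class == f])
  }
  if (include_sentence && nrow(annotation$sentences)) {
    put("sentence_beginning", annotation$sentences$onset_s)
    put("sentence_ending", annotation$sentences$offset_s)
  }
  stimulus_matrix(scheme, feats, M, fs, annotation$trial_id)
}
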