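## File interfaces: long-format annotation TSV, scores TSV, a raw-binary +
## JSON-sidecar container for EEG recordings and TRF sets, feature-table TSV
## with a JSON manifest sidecar, and a minimal Praat TextGrid reader
## (interval tiers named words/phones/sentences).

#' Write speech annotations to a long-format TSV
#'
#' One row per event with columns `trial_id`, `kind`
#' (`word`/`phoneme`/`sentence_on`/`sentence_off`), `onset_s`, `label`,
#' `pos_tag`, `sentence_id`, `interrogative_flag`.  Trial durations are kept
#' in `# trial_duration <id> <seconds>` comment headers so empty trials
#' survive a round trip.
#'
#' @param annotations List of [speech_annotation()].
#' @param path Output file.
#' @export
write_annotation_tsv <- function(annotations, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (a in annotations)
    writeLines(sprintf("# trial_duration\t%s\t%.10g", a$trial_id,
                       a$duration_s), con)
  writeLines(paste(c("trial_id", "kind", "onset_s", "label", "pos_tag",
                     "sentence_id", "interrogative_flag"), collapse = "\t"),
             con)
  row <- function(trial, kind, onset, label = "", pos = "", sid = "",
                  flag = "")
    sprintf("%s\t%s\t%.10g\t%s\t%s\t%s\t%s", trial, kind, onset, label, pos,
            sid, flag)
  for (a in annotations) {
    w <- a$words
    for (i in seq_len(nrow(w)))
      writeLines(row(a$trial_id, "word", w$onset_s[i], w$form[i],
                     w$pos_tag[i], w$sentence_id[i]), con)
    ph <- a$phonemes
    for (i in seq_len(nrow(ph)))
      writeLines(row(a$trial_id, "phoneme", ph$onset_s[i], ph$class[i]), con)
    s <- a$sentences
    for (i in seq_len(nrow(s))) {
      fl <- if (s$interrogative[i]) "1" else "0"
      writeLines(row(a$trial_id, "sentence_on", s$onset_s[i],
                     sid = s$sentence_id[i], flag = fl), con)
      writeLines(row(a$trial_id, "sentence_off", s$offset_s[i],
                     sid = s$sentence_id[i], flag = fl), con)
    }
  }
  invisible(path)
}

#' Read speech annotations from the long-format TSV
#' @param path File written by [write_annotation_tsv()].
#' @return List of [speech_annotation()], one per trial.
#' @export
read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  durl <- grep("^# trial_duration", lines, value = TRUE)
  durs <- do.call(rbind, strsplit(durl, "\t"))
  duration <- as.numeric(durs[, 3]); names(duration) <- durs[, 2]
  d <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                         colClasses = "character")
  d$onset_s <- as.numeric(d$onset_s)
  lapply(names(duration), function(tid) {
    x <- d[d$trial_id == tid, , drop = FALSE]
    w <- x[x$kind == "word", , drop = FALSE]
    ph <- x[x$kind == "phoneme", , drop = FALSE]
    so <- x[x$kind == "sentence_on", , drop = FALSE]
    sf <- x[x$kind == "sentence_off", , drop = FALSE]
    words <- if (nrow(w)) data.frame(onset_s = w$onset_s, form = w$label,
                                     pos_tag = w$pos_tag,
                                     sentence_id = as.integer(w$sentence_id),
                                     stringsAsFactors = FALSE)
             else empty_words()
    phon <- if (nrow(ph)) data.frame(onset_s = ph$onset_s, class = ph$label,
                                     stringsAsFactors = FALSE)
            else empty_phonemes()
    sid <- as.integer(so$sentence_id)
    sents <- if (nrow(so))
      data.frame(sentence_id = sid, onset_s = so$onset_s,
                 offset_s = sf$onset_s[match(sid,
                                             as.integer(sf$sentence_id))],
                 interrogative = so$interrogative_flag == "1")
      else empty_sentences()
    speech_annotation(tid, duration[[tid]], words[order(words$onset_s), ,
                                                  drop = FALSE],
                      phon, sents)
  })
}

#' Write / read participant scores as TSV
#' @param scores Numeric vector (names become participant ids).
#' @param path File path.
#' @return `read_scores_tsv` returns a named numeric vector.
#' @export
write_scores_tsv <- function(scores, path) {
  ids <- names(scores) %||% as.character(seq_along(scores))
  utils::write.table(data.frame(participant_id = ids, score = scores),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  d <- utils::read.delim(path)
  stats::setNames(d$score, d$participant_id)
}

#' Write / read EEG recordings as raw binary with a JSON sidecar
#'
#' `<stem>.bin` holds little-endian doubles (channel-major within each
#' trial, trials concatenated); `<stem>.json` records the sampling rate,
#' channel names and per-trial sample counts.
#'
#' @param recordings List of [eeg_recording()] sharing fs and channels.
#' @param stem Path stem (without extension).
#' @return `read_eeg_bin` returns the list of recordings.
#' @export
write_eeg_bin <- function(recordings, stem) {
  fs <- recordings[[1]]$fs
  chans <- recordings[[1]]$channel_names
  meta <- list(fs = fs, channel_names = chans,
               trial_id = lapply(recordings, function(r)
                 r$trial_id %||% NA),
               n_samples = vapply(recordings, function(r)
                 ncol(r$values), integer(1)))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".bin"), "wb"); on.exit(close(con))
  for (r in recordings) writeBin(as.vector(r$values), con, size = 8,
                                 endian = "little")
  invisible(stem)
}

#' @rdname write_eeg_bin
#' @export
read_eeg_bin <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  nch <- length(meta$channel_names)
  con <- file(paste0(stem, ".bin"), "rb"); on.exit(close(con))
  lapply(seq_along(meta$n_samples), function(i) {
    n <- meta$n_samples[i]
    v <- readBin(con, "double", nch * n, size = 8, endian = "little")
    tid <- meta$trial_id[[i]]
    eeg_recording(matrix(v, nch, n), meta$fs, meta$channel_names,
                  trial_id = if (is.null(tid) || is.na(tid)) NULL else tid)
  })
}

#' Write / read a TRF set (binary weights + JSON lag-axis metadata)
#' @param trfset A [trf_set()].
#' @param stem Path stem.
#' @return `read_trf_set` returns the [trf_set()].
#' @export
write_trf_set <- function(trfset, stem) {
  lax <- trfset$lag_axis
  meta <- list(scheme = trfset$scheme, feature_names = trfset$feature_names,
               channel_names = trfset$channel_names,
               participant_id = trfset$participant_id,
               lambda = trfset$lambda, intercept = trfset$intercept,
               residual_variance = trfset$residual_variance,
               lag_axis = list(lag_min_ms = lax$lag_min_ms,
                               lag_max_ms = lax$lag_max_ms, fs = lax$fs))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".bin"), "wb"); on.exit(close(con))
  writeBin(as.vector(trfset$W), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_trf_set
#' @export
read_trf_set <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  lax <- lag_axis(meta$lag_axis$lag_min_ms, meta$lag_axis$lag_max_ms,
                  meta$lag_axis$fs)
  nf <- length(meta$feature_names); nch <- length(meta$channel_names)
  con <- file(paste0(stem, ".bin"), "rb"); on.exit(close(con))
  v <- readBin(con, "double", nf * lax$n_lags * nch, size = 8,
               endian = "little")
  trf_set(array(v, c(nf, lax$n_lags, nch)), lax, meta$scheme,
          meta$feature_names, meta$channel_names, meta$participant_id,
          meta$lambda, meta$intercept, meta$residual_variance)
}

#' Write / read a feature table as TSV with a JSON manifest sidecar
#' @param table Feature table (e.g. from [assemble_feature_table()]).
#' @param path TSV path; the manifest goes to `<path>.manifest.json`.
#' @return `read_feature_table` returns the table with its manifest
#'   attribute restored.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man <- attr(table, "manifest")
  if (!is.null(man))
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  mp <- paste0(path, ".manifest.json")
  if (file.exists(mp))
    attr(tab, "manifest") <- as.data.frame(
      jsonlite::read_json(mp, simplifyVector = TRUE))
  tab
}

# ARPABET phone -> articulatory class (stress digits stripped)
arpabet_classes <- function() {
  c(AE = "short_vowel", AH = "short_vowel", EH = "short_vowel",
    IH = "short_vowel", UH = "short_vowel", AA = "short_vowel",
    AO = "long_vowel", ER = "long_vowel", IY = "long_vowel",
    UW = "long_vowel",
    AW = "diphthong", AY = "diphthong", EY = "diphthong", OW = "diphthong",
    OY = "diphthong",
    B = "plosive", D = "plosive", G = "plosive", K = "plosive",
    P = "plosive", T = "plosive",
    CH = "affricate", JH = "affricate",
    DH = "fricative", F = "fricative", S = "fricative", SH = "fricative",
    TH = "fricative", V = "fricative", Z = "fricative", ZH = "fricative",
    HH = "fricative",
    M = "nasal", N = "nasal", NG = "nasal",
    L = "liquid", R = "liquid",
    W = "semivowel", Y = "semivowel")
}

#' Read a Praat TextGrid into a speech annotation
#'
#' Minimal long-format TextGrid parser.  Expects interval tiers named
#' `words` (labels either the surface form or `form|pos_tag`), `phones`
#' (ARPABET labels, mapped to the 9 articulatory classes) and `sentences`
#' (non-empty labels; a trailing `?` marks interrogative).  Empty-label
#' intervals are silences and are skipped.
#'
#' @param path TextGrid file (long text format).
#' @param trial_id Trial identifier for the returned annotation.
#' @return A [speech_annotation()].
#' @export
read_textgrid <- function(path, trial_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  num <- function(x) as.numeric(sub(".*= *", "", x))
  str <- function(x) gsub("\"", "", sub(".*= *", "", x))
  xmax_global <- num(grep("^xmax", trimws(lines), value = TRUE)[1])
  tier_starts <- grep("item *\\[[0-9]+\\]", lines)
  tiers <- list()
  bounds <- c(tier_starts, length(lines) + 1L)
  for (t in seq_along(tier_starts)) {
    chunk <- lines[bounds[t]:(bounds[t + 1] - 1L)]
    nm <- str(grep("name *=", chunk, value = TRUE)[1])
    ci <- trimws(chunk)
    xmin <- num(grep("^xmin", ci, value = TRUE)[-1])
    xmax <- num(grep("^xmax", ci, value = TRUE)[-1])
    text <- str(grep("^text", ci, value = TRUE))
    keep <- nzchar(trimws(text))
    tiers[[tolower(nm)]] <- data.frame(xmin = xmin[keep],
                                       xmax = xmax[keep],
                                       text = trimws(text[keep]),
                                       stringsAsFactors = FALSE)
  }
  wt <- tiers[["words"]] %||% empty_words()
  st <- tiers[["sentences"]]
  sentences <- if (!is.null(st) && nrow(st))
    data.frame(sentence_id = seq_len(nrow(st)), onset_s = st$xmin,
               offset_s = st$xmax,
               interrogative = grepl("\\?$", st$text))
    else empty_sentences()
  words <- if (nrow(wt)) {
    parts <- strsplit(wt$text, "|", fixed = TRUE)
    sid <- vapply(wt$xmin, function(on) {
      hit <- which(sentences$onset_s <= on + 1e-9 &
                     on < sentences$offset_s + 1e-9)
      if (length(hit)) sentences$sentence_id[hit[1]] else NA_integer_
    }, integer(1))
    data.frame(onset_s = wt$xmin,
               form = vapply(parts, `[`, "", 1),
               pos_tag = vapply(parts, function(p)
                 if (length(p) > 1) p[2] else "others", ""),
               sentence_id = sid, stringsAsFactors = FALSE)
  } else empty_words()
  pt <- tiers[["phones"]]
  phonemes <- if (!is.null(pt) && nrow(pt)) {
    lab <- toupper(gsub("[0-9]", "", pt$text))
    cls <- unname(arpabet_classes()[lab])
    keep <- !is.na(cls)
    data.frame(onset_s = pt$xmin[keep], class = cls[keep],
               stringsAsFactors = FALSE)
  } else empty_phonemes()
  speech_annotation(trial_id, xmax_global, words, phonemes, sentences)
}
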