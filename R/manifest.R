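## The default feature manifest: which component x measure x word-feature x
## electrode combinations enter the participant-by-feature table.
##
## Composition (117 entries at the three midline electrodes Fz/Cz/Pz):
##   word_class      open/closed x {N1, P2, late} x {amplitude, latency} = 36
##   speech_rate     fast/slow x late x {amplitude, latency}             = 12
##   word_position   3 pairwise contrasts x late x {amplitude, latency}  = 18
##   parts_of_speech late amplitude for 10 analyzed classes              = 30
##                   late latency for 7 of them                          = 21
## Late windows: 300-600 ms for open-class word features (incl. speech rate
## and word position), 500-800 ms for closed-class features.  Exclusions:
## latency is dropped for pronouns/BE verbs/auxiliary verbs (no clear peak
## in their grand averages) and numbers/interrogative words/relative
## pronouns/conjunctions carry no late component at all.

pos_amp_features <- function() {
  c("general_noun", "proper_noun", "verb", "adjective", "adverb",
    "article_determiner", "pronoun", "be_verb", "auxiliary_verb",
    "preposition")
}
pos_lat_features <- function() {
  setdiff(pos_amp_features(), c("pronoun", "be_verb", "auxiliary_verb"))
}
open_pos <- function() c("general_noun", "proper_noun", "verb", "adjective",
                         "adverb")

late_component_for <- function(scheme, word_feature) {
  if (scheme == "parts_of_speech")
    return(if (word_feature %in% open_pos()) "late_open" else "late_closed")
  if (scheme == "word_class")
    return(if (word_feature == "open") "late_open" else "late_closed")
  "late_open"   # speech rate and word position analyze open-class words
}

#' Default feature manifest (117 entries)
#'
#' Enumerates the component amplitude/latency features extracted from the
#' four TRF schemes at the midline electrodes, honouring the documented
#' exclusions (no latency for pronouns, BE verbs and auxiliary verbs; no
#' late component for numbers, interrogative words, relative pronouns and
#' conjunctions).  Word-position entries are the three pairwise contrasts
#' between beginning, middle and end.
#'
#' @param channels Electrodes entering the manifest.
#' @return Data frame with columns `scheme`, `word_feature`, `component`,
#'   `measure`, `channel`, `kind` (feature id without the channel) and
#'   `column` (table column name).
#' @export
default_feature_manifest <- function(channels = c("Fz", "Cz", "Pz")) {
  rows <- list()
  add <- function(scheme, word_feature, component, measure) {
    for (ch in channels)
      rows[[length(rows) + 1L]] <<- data.frame(
        scheme = scheme, word_feature = word_feature,
        component = component, measure = measure, channel = ch,
        stringsAsFactors = FALSE)
  }
  for (wf in c("open", "closed"))
    for (comp in c("N1", "P2", late_component_for("word_class", wf)))
      for (m in c("amplitude", "latency"))
        add("word_class", wf, comp, m)
  for (wf in c("fast", "slow"))
    for (m in c("amplitude", "latency"))
      add("speech_rate", wf, "late_open", m)
  for (pair in c("beginning_minus_middle", "beginning_minus_end",
                 "middle_minus_end"))
    for (m in c("amplitude", "latency"))
      add("word_position", pair, "late_open", m)
  for (wf in pos_amp_features())
    add("parts_of_speech", wf, late_component_for("parts_of_speech", wf),
        "amplitude")
  for (wf in pos_lat_features())
    add("parts_of_speech", wf, late_component_for("parts_of_speech", wf),
        "latency")
  out <- do.call(rbind, rows)
  out$kind <- paste(out$scheme, out$word_feature, out$component,
                    out$measure, sep = ".")
  out$column <- paste(out$kind, out$channel, sep = "__")
  out
}

is_contrast <- function(word_feature) grepl("_minus_", word_feature)

# per-(scheme, feature, component, channel) amplitude or latency vectors
extract_base_feature <- function(trfsets_scheme, feature, component,
                                 measure, channel, windows) {
  wrow <- windows[windows$component == component, ]
  lax <- trfsets_scheme[[1]]$lag_axis
  win <- c(wrow$lo_ms, wrow$hi_ms)
  if (measure == "amplitude") {
    vapply(trfsets_scheme, function(ts)
      window_amplitude(trf_series(ts, feature, channel), lax, win),
      numeric(1))
  } else {
    ga <- grand_average(trfsets_scheme, feature, channel)
    gp <- find_grand_peak(ga, lax, win, wrow$polarity)
    if (is.na(gp)) return(rep(NA_real_, length(trfsets_scheme)))
    vapply(trfsets_scheme, function(ts)
      map_peak_latency(trf_series(ts, feature, channel), ga, gp, lax),
      numeric(1))
  }
}

#' Assemble the participant-by-feature table
#'
#' Computes every manifest entry from the per-participant TRF sets:
#' amplitudes as windowed means, latencies by grand-average peak detection
#' followed by DTW transfer onto each individual TRF, and word-position
#' entries as pairwise contrasts of the per-position values.  Features whose
#' grand average has no peak of the required polarity come out as `NA`
#' (missing) for all participants.
#'
#' @param trfsets Nested list: `trfsets[[participant]][[scheme]]` is a
#'   [trf_set()]; every scheme named in the manifest must be present.
#' @param manifest A manifest data frame ([default_feature_manifest()]).
#' @param scores Numeric scores (one per participant), appended as `score`.
#' @param windows Component window table ([component_windows()]).
#' @return A `data.frame`: `participant`, one column per manifest entry,
#'   `score`; the manifest is attached as attribute `"manifest"`.
#' @export
assemble_feature_table <- function(trfsets, manifest, scores,
                                   windows = component_windows()) {
  n <- length(trfsets)
  stopifnot(n >= 1, length(scores) == n)
  need <- unique(manifest$scheme)
  have <- names(trfsets[[1]])
  if (!all(need %in% have))
    stop("missing TRF scheme(s): ", paste(setdiff(need, have),
                                          collapse = ", "), call. = FALSE)
  out <- data.frame(participant = seq_len(n))
  cache <- new.env(parent = emptyenv())
  base_vals <- function(scheme, feature, component, measure, channel) {
    key <- paste(scheme, feature, component, measure, channel, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sets <- lapply(trfsets, `[[`, scheme)
    v <- extract_base_feature(sets, feature, component, measure, channel,
                              windows)
    cache[[key]] <- v
    v
  }
  for (r in seq_len(nrow(manifest))) {
    mr <- manifest[r, ]
    if (is_contrast(mr$word_feature)) {
      parts <- strsplit(mr$word_feature, "_minus_")[[1]]
      a <- base_vals(mr$scheme, parts[1], mr$component, mr$measure,
                     mr$channel)
      b <- base_vals(mr$scheme, parts[2], mr$component, mr$measure,
                     mr$channel)
      out[[mr$column]] <- a - b
    } else {
      out[[mr$column]] <- base_vals(mr$scheme, mr$word_feature,
                                    mr$component, mr$measure, mr$channel)
    }
  }
  out$score <- scores
  attr(out, "manifest") <- manifest
  out
}
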