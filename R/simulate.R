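## Synthetic-cohort generator: speech annotations, proficiency scores,
## proficiency-dependent TRF kernels, and EEG synthesized as impulse trains
## convolved with those kernels plus noise at a target SNR.  Every downstream
## stage of the pipeline can be checked against the ground truth kept here.

#' Configuration for a synthetic listening cohort
#'
#' Bundles the study-level settings of the synthetic-cohort generator: cohort
#' size, trial structure, the distribution of the latent listening-proficiency
#' score, and the noise model used when rendering EEG.  Defaults emulate the
#' study conditions the package targets: 33 trials of natural speech, five
#' scalp channels sampled at 200 Hz, and listening scores with mean 539.1,
#' SD 67.4, truncated to [328, 687].
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_trials Number of speech trials per participant.
#' @param trial_duration_s Trial duration in seconds (> 0).
#' @param word_rate Mean word rate (words per second) of the simulated speech.
#' @param score_mean,score_sd Mean and SD of the latent listening score, in
#'   test-score points.
#' @param score_range Length-2 numeric, truncation bounds for the scores.
#' @param snr_db Signal-to-noise ratio in dB of the kernel-convolved signal
#'   relative to additive noise (variance ratio over the whole trial).
#'   `Inf` disables noise.
#' @param noise_model One of `"mixture"` (50/50 power split of 1/f and white
#'   noise, the default), `"white"`, or `"one_over_f"`.
#' @param noise_mix Fraction of noise power given to the 1/f component when
#'   `noise_model = "mixture"`.
#' @param fs Sampling rate in Hz of the rendered EEG.
#' @param channel_names Channel labels.
#' @param topography Named per-channel scale factors applied to the common
#'   kernel shape (midline channels largest by default).
#' @param seed Integer seed driving every random draw of the generator.
#'
#' @return An object of class `cohort_config` (a list of the above).
#' @export
cohort_config <- function(n_participants = 20,
                          n_trials = 33,
                          trial_duration_s = 30,
                          word_rate = 2.5,
                          score_mean = 539.1,
                          score_sd = 67.4,
                          score_range = c(328, 687),
                          snr_db = 10,
                          noise_model = c("mixture", "white", "one_over_f"),
                          noise_mix = 0.5,
                          fs = 200,
                          channel_names = c("Fz", "Cz", "Pz", "FC5", "FC6"),
                          topography = c(Fz = 0.8, Cz = 1.0, Pz = 0.9,
                                         FC5 = 0.4, FC6 = 0.4),
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_participants < 2) stop("n_participants must be >= 2", call. = FALSE)
  if (trial_duration_s <= 0) stop("trial_duration_s must be > 0", call. = FALSE)
  if (length(score_range) != 2 || score_range[1] > score_range[2])
    stop("score_range must be [min, max] with min <= max", call. = FALSE)
  if (word_rate < 0) stop("word_rate must be >= 0", call. = FALSE)
  if (!all(channel_names %in% names(topography)))
    stop("topography must name every channel", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 trial_duration_s = trial_duration_s,
                 word_rate = word_rate,
                 score_mean = score_mean, score_sd = score_sd,
                 score_range = score_range,
                 snr_db = snr_db, noise_model = noise_model,
                 noise_mix = noise_mix, fs = fs,
                 channel_names = channel_names,
                 topography = topography[channel_names],
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Component specifications for synthetic TRF kernels
#'
#' Each row describes one Gaussian bump of the planted kernel: its polarity,
#' base latency and amplitude, how latency and amplitude change per standard
#' deviation of the latent proficiency score, the bump width, and
#' participant-level latency jitter.  The defaults emulate an N1 (negative,
#' ~120 ms), a P2 (positive, ~215 ms) and a late negativity (~455 ms) whose
#' latencies shorten and whose amplitudes weaken with increasing proficiency,
#' i.e. negative latency/amplitude-score correlations.
#'
#' @param name Component labels.
#' @param polarity `"negative"` or `"positive"` per component.
#' @param base_latency_ms Bump centre at the cohort-average score.
#' @param latency_slope_ms_per_sd Change of the bump centre per +1 SD of
#'   proficiency (negative: faster responses in proficient listeners).
#' @param base_amplitude,amplitude_slope_per_sd Peak amplitude (arbitrary
#'   units, signed by polarity at render time) and its change per +1 SD.
#' @param width_ms Gaussian SD of the bump in ms (> 0).
#' @param jitter_sd_ms SD of participant-level latency jitter in ms.
#'
#' @return A `data.frame` with one row per component.
#' @export
component_specs <- function(name = c("N1", "P2", "late"),
                            polarity = c("negative", "positive", "negative"),
                            base_latency_ms = c(120, 215, 455),
                            latency_slope_ms_per_sd = c(-2, -12, -45),
                            base_amplitude = c(1.0, 1.2, 0.8),
                            amplitude_slope_per_sd = c(0, -0.15, -0.1),
                            width_ms = c(20, 30, 80),
                            jitter_sd_ms = c(2, 2, 5)) {
  if (any(width_ms <= 0)) stop("width_ms must be > 0", call. = FALSE)
  if (!all(polarity %in% c("negative", "positive")))
    stop("polarity must be 'negative' or 'positive'", call. = FALSE)
  data.frame(name = name, polarity = polarity,
             base_latency_ms = base_latency_ms,
             latency_slope_ms_per_sd = latency_slope_ms_per_sd,
             base_amplitude = base_amplitude,
             amplitude_slope_per_sd = amplitude_slope_per_sd,
             width_ms = width_ms, jitter_sd_ms = jitter_sd_ms,
             stringsAsFactors = FALSE)
}

# default POS frequencies; weighted toward nouns/verbs/determiners/prepositions
default_pos_frequencies <- function() {
  c(general_noun = 0.22, proper_noun = 0.03, verb = 0.16, adjective = 0.07,
    adverb = 0.05, number = 0.02, article_determiner = 0.11, pronoun = 0.08,
    interrogative_word = 0.02, relative_pronoun = 0.02, be_verb = 0.05,
    auxiliary_verb = 0.04, preposition = 0.09, conjunction = 0.03,
    others = 0.01)
}

#' Simulate timed speech annotations for a set of trials
#'
#' Words arrive by a homogeneous renewal process with lognormal inter-word
#' intervals whose mean matches `word_rate`; each word carries a
#' part-of-speech tag drawn from a fixed 15-class frequency table and a small
#' train of phonemes (at least one vowel nucleus, so syllables are countable).
#' Consecutive words are grouped into sentences whose onset/offset intervals
#' tile the trial; the final sentence of a trial may be flagged interrogative.
#'
#' @param n_trials Number of trials to generate.
#' @param trial_duration_s Duration of each trial in seconds (> 0); recycled.
#' @param word_rate Mean words per second (0 gives empty trials).
#' @param pos_frequencies Named sampling weights over the 15 POS classes.
#' @param p_interrogative Probability that a trial's final sentence is
#'   interrogative.
#' @param words_per_sentence Mean sentence length in words.
#' @param seed Integer seed.
#'
#' @return A list of [speech_annotation()] objects, one per trial.
#' @export
simulate_annotations <- function(n_trials = 33, trial_duration_s = 30,
                                 word_rate = 2.5,
                                 pos_frequencies = default_pos_frequencies(),
                                 p_interrogative = 0.5,
                                 words_per_sentence = 8,
                                 seed = 1L) {
  if (any(trial_duration_s <= 0))
    stop("trial_duration_s must be > 0", call. = FALSE)
  if (word_rate < 0) stop("word_rate must be >= 0", call. = FALSE)
  set.seed(seed)
  dur <- rep_len(trial_duration_s, n_trials)
  lapply(seq_len(n_trials), function(tr)
    simulate_one_annotation(tr, dur[tr], word_rate, pos_frequencies,
                            p_interrogative, words_per_sentence))
}

simulate_one_annotation <- function(trial_id, duration_s, word_rate,
                                    pos_freq, p_inter, wps) {
  # renewal process: lognormal inter-word intervals with mean 1/rate
  onsets <- numeric(0)
  if (word_rate > 0) {
    mu_iwi <- 1 / word_rate
    sdlog <- 0.5
    meanlog <- log(mu_iwi) - sdlog^2 / 2
    n_guess <- ceiling(duration_s * word_rate * 2 + 20)
    gaps <- rlnorm(n_guess, meanlog, sdlog)
    onsets <- cumsum(gaps)
    while (sum(onsets < duration_s) == length(onsets)) {
      onsets <- c(onsets, onsets[length(onsets)] +
                    cumsum(rlnorm(n_guess, meanlog, sdlog)))
    }
    onsets <- onsets[onsets < duration_s]
  }
  n_words <- length(onsets)
  if (n_words == 0) {
    return(speech_annotation(trial_id, duration_s,
                             words = empty_words(),
                             phonemes = empty_phonemes(),
                             sentences = empty_sentences()))
  }
  pos_tags <- sample(names(pos_freq), n_words, replace = TRUE,
                     prob = pos_freq)

  # group words into sentences of ~wps words; sentences tile [0, duration]
  sent_len <- pmax(1L, rpois(n_words, wps))
  sent_id <- rep(seq_along(sent_len), sent_len)[seq_len(n_words)]
  sent_id <- as.integer(factor(sent_id))
  n_sent <- max(sent_id)
  first_on <- tapply(onsets, sent_id, min)
  bounds <- c(0, (first_on[-1] + tapply(onsets, sent_id, max)[-n_sent]) / 2,
              duration_s)
  interrog <- rep(FALSE, n_sent)
  interrog[n_sent] <- runif(1) < p_inter
  sentences <- data.frame(sentence_id = seq_len(n_sent),
                          onset_s = unname(bounds[seq_len(n_sent)]),
                          offset_s = unname(bounds[-1]),
                          interrogative = interrog)

  # phonemes: 1-4 per word, first is always a vowel nucleus
  nuclei <- c("short_vowel", "long_vowel", "diphthong")
  consonants <- c("plosive", "affricate", "fricative", "nasal", "liquid",
                  "semivowel")
  ph_on <- list(); ph_cl <- list()
  for (w in seq_len(n_words)) {
    k <- sample(1:4, 1)
    cls <- c(sample(nuclei, 1),
             if (k > 1) sample(c(nuclei, consonants), k - 1, replace = TRUE,
                               prob = c(rep(0.1, 3), rep(0.7 / 6, 6))))
    ph_on[[w]] <- onsets[w] + (seq_len(k) - 1) * 0.07
    ph_cl[[w]] <- cls
  }
  phonemes <- data.frame(onset_s = unlist(ph_on),
                         class = unlist(ph_cl), stringsAsFactors = FALSE)
  phonemes <- phonemes[phonemes$onset_s < duration_s, , drop = FALSE]
  phonemes <- phonemes[order(phonemes$onset_s), , drop = FALSE]

  words <- data.frame(onset_s = onsets,
                      form = sprintf("w%03d", seq_len(n_words)),
                      pos_tag = pos_tags, sentence_id = sent_id,
                      stringsAsFactors = FALSE)
  speech_annotation(trial_id, duration_s, words, phonemes, sentences)
}

empty_words <- function()
  data.frame(onset_s = numeric(0), form = character(0),
             pos_tag = character(0), sentence_id = integer(0),
             stringsAsFactors = FALSE)
empty_phonemes <- function()
  data.frame(onset_s = numeric(0), class = character(0),
             stringsAsFactors = FALSE)
empty_sentences <- function()
  data.frame(sentence_id = integer(0), onset_s = numeric(0),
             offset_s = numeric(0), interrogative = logical(0))

#' Simulate listening-proficiency scores
#'
#' Draws scores from a normal distribution truncated (by rejection) to
#' `score_range`.  The parent normal's parameters are moment-matched so that
#' the truncated distribution itself has mean `score_mean` and SD
#' `score_sd` -- the configured values describe the observed (range-limited)
#' scores, not a hypothetical untruncated parent.
#'
#' @param config A [cohort_config()] (or anything with `n_participants`,
#'   `score_mean`, `score_sd`, `score_range`, `seed`).
#' @param n Optional override of the number of scores.
#' @param seed Optional override of the seed.
#' @return Numeric vector of scores.
#' @export
simulate_scores <- function(config, n = config$n_participants,
                            seed = config$seed) {
  set.seed(seed)
  lo <- config$score_range[1]; hi <- config$score_range[2]
  if (config$score_sd == 0 || lo == hi) {
    return(rep(if (lo == hi) lo else config$score_mean, n))
  }
  par <- truncnorm_parent(config$score_mean, config$score_sd, lo, hi)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n, par[1], par[2])
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# mean/sd of N(mu, s) truncated to [lo, hi]
truncnorm_moments <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s; b <- (hi - mu) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + s * (da - db) / Z
  v <- s^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(m, sqrt(v))
}

# parent parameters whose truncated moments match the target mean/sd
truncnorm_parent <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(fit$par[1], exp(fit$par[2]))
}

gaussian_bump <- function(lags_ms, center_ms, width_ms, amplitude, polarity) {
  s <- if (polarity == "negative") -1 else 1
  s * amplitude * exp(-0.5 * ((lags_ms - center_ms) / width_ms)^2)
}

#' Simulate proficiency-dependent TRF kernels
#'
#' For every participant and every kernel-bearing stimulus feature, the
#' kernel is a sum of Gaussian bumps (one per component spec).  For
#' participant \eqn{p} with standardized score \eqn{z_p}, the bump centre is
#' `base_latency_ms + latency_slope_ms_per_sd * z_p + jitter` and the bump
#' amplitude `base_amplitude + amplitude_slope_per_sd * z_p`; per-channel
#' kernels are the common shape scaled by the topography weights.  True
#' per-component latencies and amplitudes are recorded as ground truth.
#'
#' @param scores Numeric vector of proficiency scores (one per participant).
#' @param specs A [component_specs()] data frame.
#' @param lag_axis A [lag_axis()].
#' @param feature_names Features that receive score-dependent kernels.
#' @param channel_names,topography Channels and their scale factors.
#' @param score_center,score_scale Standardization used for \eqn{z_p};
#'   default the sample mean/SD of `scores`.
#' @param seed Integer seed (drives the latency jitter).
#'
#' @return List with `kernels` (per participant: array feature x lag x
#'   channel) and `truth` (data frame: participant, feature, component,
#'   latency_ms, amplitude).
#' @export
simulate_kernels <- function(scores, specs = component_specs(),
                             lag_axis = speechtrf::lag_axis(),
                             feature_names = c("open", "closed"),
                             channel_names = c("Fz", "Cz", "Pz", "FC5", "FC6"),
                             topography = c(Fz = 0.8, Cz = 1.0, Pz = 0.9,
                                            FC5 = 0.4, FC6 = 0.4),
                             score_center = mean(scores),
                             score_scale = stats::sd(scores),
                             seed = 1L) {
  lo <- lag_axis$lag_min_ms; hi <- lag_axis$lag_max_ms
  bad <- specs$base_latency_ms - 3 * specs$width_ms < lo |
         specs$base_latency_ms + 3 * specs$width_ms > hi
  if (any(bad))
    stop("component latency +/- 3*width outside the lag axis: ",
         paste(specs$name[bad], collapse = ", "), call. = FALSE)
  set.seed(seed)
  if (is.na(score_scale) || score_scale == 0) score_scale <- 1
  z <- (scores - score_center) / score_scale
  topo <- topography[channel_names]
  n_p <- length(scores); L <- lag_axis$n_lags
  kernels <- vector("list", n_p)
  truth <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    arr <- array(0, dim = c(length(feature_names), L, length(channel_names)),
                 dimnames = list(feature_names, NULL, channel_names))
    rows <- list()
    for (f in seq_along(feature_names)) {
      shape <- numeric(L)
      for (k in seq_len(nrow(specs))) {
        jit <- if (specs$jitter_sd_ms[k] > 0)
          rnorm(1, 0, specs$jitter_sd_ms[k]) else 0
        lat <- specs$base_latency_ms[k] +
          specs$latency_slope_ms_per_sd[k] * z[p] + jit
        amp <- specs$base_amplitude[k] +
          specs$amplitude_slope_per_sd[k] * z[p]
        shape <- shape + gaussian_bump(lag_axis$lags_ms, lat,
                                       specs$width_ms[k], amp,
                                       specs$polarity[k])
        rows[[length(rows) + 1]] <-
          data.frame(participant = p, feature = feature_names[f],
                     component = specs$name[k], latency_ms = lat,
                     amplitude = amp, stringsAsFactors = FALSE)
      }
      for (ch in seq_along(topo)) arr[f, , ch] <- shape * topo[ch]
    }
    kernels[[p]] <- arr
    truth[[p]] <- do.call(rbind, rows)
  }
  list(kernels = kernels, truth = do.call(rbind, truth),
       lag_axis = lag_axis, feature_names = feature_names,
       channel_names = channel_names)
}

# noise with unit variance and the requested spectral shape
make_noise <- function(n, n_chan, model, mix) {
  white <- matrix(rnorm(n_chan * n), n_chan, n)
  if (model == "white") return(white / apply_sd(white))
  pink <- matrix(0, n_chan, n)
  f <- c(1, seq_len(n - 1))            # guard DC
  shape <- 1 / sqrt(pmin(f, n - f + 1))
  for (ch in seq_len(n_chan)) {
    spec <- fft(rnorm(n)) * shape
    pink[ch, ] <- Re(fft(spec, inverse = TRUE)) / n
  }
  pink <- pink / apply_sd(pink)
  if (model == "one_over_f") return(pink)
  w <- sqrt(mix) * pink + sqrt(1 - mix) * white / apply_sd(white)
  w / apply_sd(w)
}
apply_sd <- function(m) {
  s <- apply(m, 1, stats::sd)
  s[s == 0] <- 1
  matrix(rep(s, ncol(m)), nrow(m), ncol(m))
}

#' Render an EEG recording from an annotation and planted kernels
#'
#' The clean signal on each channel is the sum over features of the feature's
#' impulse train convolved with its kernel; additive noise is scaled so that
#' the ratio of clean-signal variance to noise variance over the whole trial
#' matches `snr_db` (`Inf` returns the clean signal exactly).
#'
#' @param annotation A [speech_annotation()].
#' @param kernels Output of [simulate_kernels()] (the per-participant array
#'   is selected with `participant`), or a single feature x lag x channel
#'   array with dimnames.
#' @param participant Participant index into `kernels$kernels`.
#' @param scheme Stimulus scheme used to build the impulse matrix; its
#'   word-feature rows must match the kernel feature names.
#' @param snr_db Target SNR in dB; `Inf` for noiseless.
#' @param noise_model,noise_mix See [cohort_config()].
#' @param include_phonemes,include_sentence Whether the impulse matrix keeps
#'   phoneme-class and sentence-boundary rows (kernels for these rows must
#'   then be present).
#' @param seed Integer seed for the noise draw.
#'
#' @return List with `recording` (an [eeg_recording()]), `stimulus` (the
#'   [stimulus_matrix()] used) and `clean` (noiseless channel x time matrix).
#' @export
synthesize_recording <- function(annotation, kernels, participant = 1L,
                                 scheme = "word_class", snr_db = Inf,
                                 noise_model = "mixture", noise_mix = 0.5,
                                 include_phonemes = FALSE,
                                 include_sentence = FALSE, seed = 1L) {
  arr <- if (is.array(kernels)) kernels else kernels$kernels[[participant]]
  lax <- if (is.array(kernels)) attr(kernels, "lag_axis") else kernels$lag_axis
  if (is.null(lax)) stop("kernels must carry a lag_axis", call. = FALSE)
  stim <- build_stimulus_matrix(annotation, scheme = scheme, fs = lax$fs,
                                include_phonemes = include_phonemes,
                                include_sentence = include_sentence)
  feat <- dimnames(arr)[[1]]
  if (!setequal(feat, stim$feature_names))
    stop("feature scheme mismatch between kernels and stimulus matrix",
         call. = FALSE)
  arr <- arr[stim$feature_names, , , drop = FALSE]
  chans <- dimnames(arr)[[3]]
  Tn <- ncol(stim$values); L <- dim(arr)[2]
  clean <- matrix(0, length(chans), Tn, dimnames = list(chans, NULL))
  for (f in seq_along(stim$feature_names)) {
    cols <- which(stim$values[f, ] != 0)
    if (!length(cols)) next
    for (s0 in cols) {
      rows_t <- s0 + lax$lags_samp           # 1-based time indices
      ok <- rows_t >= 1 & rows_t <= Tn
      if (!any(ok)) next
      for (ch in seq_along(chans))
        clean[ch, rows_t[ok]] <- clean[ch, rows_t[ok]] + arr[f, ok, ch]
    }
  }
  values <- clean
  if (is.finite(snr_db)) {
    set.seed(seed)
    noise <- make_noise(Tn, length(chans), noise_model, noise_mix)
    cv <- mean(apply(clean, 1, stats::var))
    target_nv <- cv / 10^(snr_db / 10)
    values <- clean + noise * sqrt(target_nv)
  }
  list(recording = eeg_recording(values, lax$fs, chans,
                                 trial_id = annotation$trial_id),
       stimulus = stim, clean = clean)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: annotations, scores, kernels, and per-participant
#' per-trial recordings with their stimulus matrices.
#'
#' @param config A [cohort_config()].
#' @param specs A [component_specs()].
#' @param scheme Stimulus scheme for the planted kernels.
#' @param lag_axis A [lag_axis()]; its `fs` must match `config$fs`.
#' @param include_phonemes,include_sentence Passed to
#'   [synthesize_recording()]; when `TRUE` the corresponding rows receive
#'   small fixed (score-independent) kernels.
#' @return List: `annotations`, `scores`, `kernels` (with `$truth`),
#'   `recordings[[p]][[trial]]`, `stimuli[[trial]]`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            specs = component_specs(),
                            scheme = "word_class",
                            lag_axis = speechtrf::lag_axis(fs = config$fs),
                            include_phonemes = FALSE,
                            include_sentence = FALSE) {
  if (lag_axis$fs != config$fs)
    stop("lag_axis fs must match config fs", call. = FALSE)
  ann <- simulate_annotations(config$n_trials, config$trial_duration_s,
                              config$word_rate, seed = config$seed)
  scores <- simulate_scores(config)
  feat <- scheme_word_features(scheme)
  kern <- simulate_kernels(scores, specs, lag_axis, feature_names = feat,
                           channel_names = config$channel_names,
                           topography = config$topography,
                           score_center = config$score_mean,
                           score_scale = config$score_sd,
                           seed = config$seed + 1L)
  if (include_phonemes || include_sentence)
    kern <- add_nuisance_kernels(kern, include_phonemes, include_sentence)
  recordings <- vector("list", config$n_participants)
  stimuli <- NULL
  for (p in seq_len(config$n_participants)) {
    recs <- vector("list", config$n_trials)
    for (tr in seq_len(config$n_trials)) {
      out <- synthesize_recording(ann[[tr]], kern, participant = p,
                                  scheme = scheme, snr_db = config$snr_db,
                                  noise_model = config$noise_model,
                                  noise_mix = config$noise_mix,
                                  include_phonemes = include_phonemes,
                                  include_sentence = include_sentence,
                                  seed = config$seed + 1000L * p + tr)
      recs[[tr]] <- out$recording
      if (p == 1L) stimuli[[tr]] <- out$stimulus
    }
    recordings[[p]] <- recs
  }
  list(annotations = ann, scores = scores, kernels = kern,
       recordings = recordings, stimuli = stimuli, config = config)
}

# small fixed early bump on phoneme rows, nothing on sentence rows
add_nuisance_kernels <- function(kern, phonemes, sentence) {
  lax <- kern$lag_axis
  extra <- c(if (phonemes) phoneme_classes(),
             if (sentence) c("sentence_beginning", "sentence_ending"))
  bump <- gaussian_bump(lax$lags_ms, 80, 15, 0.3, "negative")
  for (p in seq_along(kern$kernels)) {
    old <- kern$kernels[[p]]
    chans <- dimnames(old)[[3]]
    arr <- array(0, dim = c(dim(old)[1] + length(extra), dim(old)[2],
                            dim(old)[3]),
                 dimnames = list(c(dimnames(old)[[1]], extra), NULL, chans))
    arr[dimnames(old)[[1]], , ] <- old
    for (e in extra) if (!startsWith(e, "sentence"))
      for (ch in seq_along(chans)) arr[e, , ch] <- bump
    kern$kernels[[p]] <- arr
  }
  kern$feature_names <- c(kern$feature_names, extra)
  kern
}

#' Simulate a participant-by-feature table with planted score correlations
#'
#' Generates the input of the screening/LASSO stage directly: `n_informative`
#' features are constructed with a true (population) Pearson correlation
#' `r_true` with the latent score, the remaining features are independent
#' noise.  Used for end-to-end recovery checks of the prediction module.
#'
#' @param n Participants.
#' @param n_features Total feature columns.
#' @param n_informative Number of planted score-correlated features.
#' @param r_true True correlation of each planted feature with the score
#'   (negative by default, as component latencies lengthen with lower
#'   proficiency).
#' @param score_mean,score_sd Score distribution.
#' @param seed Integer seed.
#' @return List: `table` (data.frame with `participant`, feature columns,
#'   `score`) and `informative` (planted column names).
#' @export
simulate_feature_table <- function(n = 100, n_features = 117,
                                   n_informative = 5, r_true = -0.3,
                                   score_mean = 539.1, score_sd = 67.4,
                                   seed = 1L) {
  stopifnot(n_informative <= n_features, abs(r_true) <= 1)
  set.seed(seed)
  z <- rnorm(n)
  score <- score_mean + score_sd * z
  X <- matrix(rnorm(n * n_features), n, n_features)
  for (j in seq_len(n_informative))
    X[, j] <- r_true * z + sqrt(1 - r_true^2) * X[, j]
  cols <- sprintf("f%03d", seq_len(n_features))
  tab <- data.frame(participant = seq_len(n), X, score = score)
  names(tab) <- c("participant", cols, "score")
  list(table = tab, informative = cols[seq_len(n_informative)])
}
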