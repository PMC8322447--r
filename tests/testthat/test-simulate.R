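# Synthetic-cohort generator: annotations, scores, kernels, EEG rendering.

# phoneme-free annotation frame
empty_ann_phonemes <- function()
  data.frame(onset_s = numeric(0), class = character(0),
             stringsAsFactors = FALSE)

test_that("simulated word process has the configured rate and valid structure", {
  ann <- simulate_annotations(n_trials = 4, trial_duration_s = 30,
                              word_rate = 2.5, seed = 7)
  n_words <- vapply(ann, function(a) nrow(a$words), integer(1))
  expect_true(all(abs(n_words - 75) <= 3 * sqrt(75)))
  for (a in ann) {
    expect_false(is.unsorted(a$words$onset_s, strictly = TRUE))
    expect_true(all(a$words$onset_s > 0 & a$words$onset_s < 30))
    expect_true(all(a$words$pos_tag %in% pos_classes()$pos_class))
    expect_true(all(a$words$sentence_id %in% a$sentences$sentence_id))
    expect_true(all(a$phonemes$class %in% phoneme_classes()))
    # every word has at least one vowel nucleus starting at its onset
    expect_true(all(a$words$onset_s %in%
                      a$phonemes$onset_s[a$phonemes$class %in%
                        c("short_vowel", "long_vowel", "diphthong")]))
    # sentences tile the trial
    s <- a$sentences[order(a$sentences$onset_s), ]
    expect_equal(s$onset_s[1], 0)
    expect_equal(s$offset_s[nrow(s)], a$duration_s)
    if (nrow(s) > 1) expect_equal(s$onset_s[-1], s$offset_s[-nrow(s)])
  }
})

test_that("empty and degenerate annotation configs behave", {
  ann <- simulate_annotations(1, trial_duration_s = 0.1, word_rate = 0,
                              seed = 1)
  expect_equal(nrow(ann[[1]]$words), 0)
  expect_equal(nrow(ann[[1]]$sentences), 0)
  expect_error(simulate_annotations(1, trial_duration_s = -1),
               "trial_duration_s")
})

test_that("annotation generation is deterministic under a fixed seed", {
  a1 <- simulate_annotations(3, 20, 2.5, seed = 42)
  a2 <- simulate_annotations(3, 20, 2.5, seed = 42)
  expect_identical(a1, a2)
})

test_that("scores match the configured distribution and truncation", {
  cfg <- cohort_config(n_participants = 2, seed = 1)
  s <- simulate_scores(cfg, n = 10000)
  expect_true(mean(s) > 537 && mean(s) < 541)
  expect_true(all(s >= 328 & s <= 687))
  cfg0 <- cohort_config(n_participants = 3, score_sd = 0, seed = 1)
  expect_equal(simulate_scores(cfg0), rep(539.1, 3))
  cfgd <- cohort_config(n_participants = 3,
                        score_range = c(539.1, 539.1), seed = 1)
  expect_equal(simulate_scores(cfgd), rep(539.1, 3))
})

test_that("kernel construction follows the component specs", {
  lax <- lag_axis(-100, 700, 100)
  flat <- component_specs(base_latency_ms = c(100, 200, 420),
                          width_ms = c(15, 25, 60),
                          latency_slope_ms_per_sd = c(0, 0, 0),
                          amplitude_slope_per_sd = c(0, 0, 0),
                          jitter_sd_ms = c(0, 0, 0))
  k <- simulate_kernels(c(450, 550, 650), flat, lax, seed = 1)
  expect_equal(k$kernels[[1]], k$kernels[[2]])
  expect_equal(k$kernels[[2]], k$kernels[[3]])

  # latency slope -10 ms/SD moves the bump centre by -10 ms at z = +1
  sl <- component_specs(base_latency_ms = c(100, 200, 420),
                        width_ms = c(15, 25, 60),
                        latency_slope_ms_per_sd = c(-10, -10, -10),
                        amplitude_slope_per_sd = c(0, 0, 0),
                        jitter_sd_ms = c(0, 0, 0))
  k2 <- simulate_kernels(c(500, 600), sl, lax, score_center = 500,
                         score_scale = 100, seed = 1)
  tr <- k2$truth
  expect_equal(tr$latency_ms[tr$participant == 2 & tr$component == "N1" &
                               tr$feature == "open"], 90)
  expect_equal(tr$latency_ms[tr$participant == 1 & tr$component == "N1" &
                               tr$feature == "open"], 100)
  # N1 is negative at its centre
  n1_idx <- which.min(abs(lax$lags_ms - 100))
  expect_lt(k$kernels[[1]]["open", n1_idx, "Cz"], 0)
  # planted correlation: zero jitter, negative slope -> r = -1 in the limit
  sc <- seq(400, 680, length.out = 20)
  k3 <- simulate_kernels(sc, sl, lax, seed = 2)
  lat <- k3$truth$latency_ms[k3$truth$component == "late" &
                               k3$truth$feature == "open"]
  expect_lt(cor(lat, sc), -0.999)
  # components too close to the axis edge are rejected
  expect_error(simulate_kernels(c(500, 600),
                                component_specs(base_latency_ms =
                                                  c(100, 200, 690),
                                                width_ms = c(15, 25, 60)),
                                lax),
               "lag axis")
})

test_that("rendered recordings are impulse trains convolved with kernels", {
  lax <- lag_axis(-100, 700, 100)
  specs <- component_specs(base_latency_ms = c(100, 200, 420),
                           width_ms = c(15, 25, 60),
                           jitter_sd_ms = c(0, 0, 0))
  kern <- simulate_kernels(c(480, 600), specs, lax, seed = 1)
  # single impulse, single feature: recording copies the kernel at t0+lags
  words <- data.frame(onset_s = 2, form = "w", pos_tag = "general_noun",
                      sentence_id = 1L)
  sent <- data.frame(sentence_id = 1L, onset_s = 0, offset_s = 10,
                     interrogative = FALSE)
  ann1 <- speech_annotation(1, 10, words, empty_ann_phonemes(), sent)
  out <- synthesize_recording(ann1, kern, 1, snr_db = Inf)
  s0 <- 2 * 100 + 1
  got <- out$recording$values["Cz", s0 + lax$lags_samp]
  expect_equal(got, kern$kernels[[1]]["open", , "Cz"], tolerance = 1e-12)

  # two impulses: linear superposition
  words2 <- data.frame(onset_s = c(2, 2.5), form = c("a", "b"),
                       pos_tag = "general_noun", sentence_id = 1L)
  ann2 <- speech_annotation(1, 10, words2, empty_ann_phonemes(), sent)
  out2 <- synthesize_recording(ann2, kern, 1, snr_db = Inf)
  shift <- function(s0) {
    v <- numeric(1000)
    idx <- s0 + lax$lags_samp
    ok <- idx >= 1 & idx <= 1000
    v[idx[ok]] <- kern$kernels[[1]]["open", ok, "Cz"]
    v
  }
  expect_equal(out2$recording$values["Cz", ], shift(201) + shift(251),
               tolerance = 1e-12)

  # snr 0 dB: clean/noise variance ratio near 1
  ann <- simulate_annotations(1, 30, 2.5, seed = 3)[[1]]
  outn <- synthesize_recording(ann, kern, 1, snr_db = 0, seed = 9)
  noise <- outn$recording$values - outn$clean
  ratio <- mean(apply(outn$clean, 1, var)) / mean(apply(noise, 1, var))
  expect_true(ratio > 0.9 && ratio < 1.1)

  # mismatched feature scheme errors
  expect_error(synthesize_recording(ann1, kern, 1,
                                    scheme = "parts_of_speech"),
               "mismatch")
})
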