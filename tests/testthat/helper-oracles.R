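# Independent oracles and small fixture builders used across the suite.

# Brute-force forward model: pred[ch, t] = b0 + sum_f sum_k W[f,k,ch] *
# S[f, t - lag_k], zero outside the trial.  Plain double loop, no shared
# code with build_lagged_design/predict_response.
brute_force_predict <- function(stim_values, W, lags_samp, intercept = NULL) {
  nf <- dim(W)[1]; L <- dim(W)[2]; nch <- dim(W)[3]
  Tn <- ncol(stim_values)
  pred <- matrix(0, nch, Tn)
  for (f in seq_len(nf)) {
    for (k in seq_len(L)) {
      src <- seq_len(Tn) - lags_samp[k]      # S index feeding each t
      ok <- src >= 1 & src <= Tn
      s <- numeric(Tn)
      s[ok] <- stim_values[f, src[ok]]
      for (ch in seq_len(nch)) pred[ch, ] <- pred[ch, ] + W[f, k, ch] * s
    }
  }
  if (!is.null(intercept)) pred <- pred + intercept
  pred
}

# Reference DTW by a plain R dynamic-programming table (cost only);
# independent of the compiled implementation.
dtw_cost_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) D[i, j] <- c0
    else D[i, j] <- c0 + min(if (i > 1 && j > 1) D[i - 1, j - 1] else Inf,
                             if (i > 1) D[i - 1, j] else Inf,
                             if (j > 1) D[i, j - 1] else Inf)
  }
  D[n, m]
}

# Exhaustive recursive enumeration of all monotone warping paths (tiny n
# only); the minimum total cost over every path.
dtw_cost_exhaustive <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    c0 + best
  }
  rec(length(a), length(b))
}

# random small stimulus matrix on a given axis
random_stim <- function(nf, Tn, fs, n_impulses = 8, trial_id = 1) {
  M <- matrix(0, nf, Tn,
              dimnames = list(sprintf("f%d", seq_len(nf)), NULL))
  for (f in seq_len(nf)) M[f, sample(Tn, n_impulses)] <- 1
  stimulus_matrix("word_class", rownames(M), M, fs, trial_id)
}

# small noiseless single-participant cohort on a reduced lag axis
tiny_cohort <- function(n_trials = 3, duration = 10, fs = 100,
                        snr_db = Inf, seed = 5) {
  lax <- lag_axis(-100, 700, fs)
  ann <- simulate_annotations(n_trials, duration, 2.5, seed = seed)
  specs <- component_specs(base_latency_ms = c(100, 200, 420),
                           width_ms = c(15, 25, 60),
                           jitter_sd_ms = c(0, 0, 0))
  scores <- c(480, 600)
  kern <- simulate_kernels(scores, specs, lax, seed = seed + 1)
  stims <- list(); recs <- list()
  for (tr in seq_len(n_trials)) {
    out <- synthesize_recording(ann[[tr]], kern, 1, snr_db = snr_db,
                                seed = seed + tr)
    stims[[tr]] <- out$stimulus
    recs[[tr]] <- out$recording
  }
  list(lax = lax, ann = ann, kern = kern, stims = stims, recs = recs)
}

# synthetic individual TRF series: shifted bump plus band-limited noise
shifted_bump_series <- function(lags_ms, center_ms, shift_ms, snr_db, fs,
                                width_ms = 20) {
  sig <- -exp(-0.5 * ((lags_ms - center_ms - shift_ms) / width_ms)^2)
  if (!is.finite(snr_db)) return(sig)
  noise <- stats::rnorm(length(sig))
  h <- signal::fir1(60, 7 / (fs / 2), type = "low")
  noise <- stats::convolve(noise, rev(h), type = "open")
  noise <- noise[seq_along(sig) + 30]
  noise <- noise / stats::sd(noise) * sqrt(stats::var(sig) / 10^(snr_db / 10))
  sig + noise
}
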