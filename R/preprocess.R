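## Deterministic signal conditioning: re-reference to the earlobe average,
## 0.5-50 Hz bandpass FIR (order 3300, designed at the 500 Hz acquisition
## rate), resampling to 200 Hz, and a 7 Hz low-pass FIR (order 1320).
## Filters are linear-phase windowed-sinc (Hamming) designs and are applied
## zero-phase by default (group delay compensated), so component latencies
## are not shifted.

#' Multichannel EEG recording container
#'
#' @param values Channels x time numeric matrix.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Channel labels (rownames of `values` if missing).
#' @param trial_id Optional trial identifier.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(values, fs, channel_names = rownames(values),
                          trial_id = NULL) {
  values <- as.matrix(values)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(values)))
  stopifnot(fs > 0, nrow(values) >= 1,
            length(channel_names) == nrow(values))
  rownames(values) <- channel_names
  structure(list(values = values, fs = fs, channel_names = channel_names,
                 trial_id = trial_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$values), ncol(x$values), x$fs, ncol(x$values) / x$fs))
  invisible(x)
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts the average of the reference channels from every other channel
#' and drops the references from the output.
#'
#' @param recording An [eeg_recording()].
#' @param reference_channels Channel names to average as the reference.
#' @return Re-referenced [eeg_recording()] without the reference channels.
#' @export
rereference <- function(recording, reference_channels) {
  miss <- setdiff(reference_channels, recording$channel_names)
  if (length(miss))
    stop("missing reference channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ref <- colMeans(recording$values[reference_channels, , drop = FALSE])
  keep <- setdiff(recording$channel_names, reference_channels)
  if (!length(keep)) stop("no channels left after re-referencing",
                          call. = FALSE)
  out <- sweep(recording$values[keep, , drop = FALSE], 2, ref, "-")
  eeg_recording(out, recording$fs, keep, recording$trial_id)
}

# Hamming-window FIR taps for the two pipeline filters
design_fir <- function(kind = c("bandpass", "lowpass"), fs,
                       order = NULL, band = NULL) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    order <- order %||% 3300
    band <- band %||% c(0.5, 50)
    if (band[2] >= fs / 2) stop("cutoff must be below Nyquist", call. = FALSE)
    h <- signal::fir1(order, band / (fs / 2), type = "pass")
    h - mean(h)   # exact null at DC (drift must not leak through)
  } else {
    order <- order %||% 1320
    band <- band %||% 7
    if (band >= fs / 2) stop("cutoff must be below Nyquist", call. = FALSE)
    signal::fir1(order, band / (fs / 2), type = "low")
  }
}

#' Apply a pipeline FIR filter
#'
#' `kind = "bandpass"` is the 0.5-50 Hz, order-3300 filter (designed at the
#' acquisition rate); `kind = "lowpass"` the 7 Hz, order-1320 filter
#' (designed at the 200 Hz analysis rate).  Linear-phase windowed-sinc
#' (Hamming) design.  With `mode = "zero_phase"` (default) the constant group
#' delay of `order/2` samples is compensated so peaks are not shifted;
#' `mode = "causal"` applies the filter as-is.
#'
#' @param recording An [eeg_recording()].
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param mode `"zero_phase"` or `"causal"`.
#' @param order,band Optional overrides of filter order and cutoff(s) in Hz.
#' @return Filtered [eeg_recording()].
#' @export
fir_filter <- function(recording, kind = c("bandpass", "lowpass"),
                       mode = c("zero_phase", "causal"),
                       order = NULL, band = NULL) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  h <- design_fir(kind, recording$fs, order, band)
  nh <- length(h)
  delay <- (nh - 1) / 2
  n <- ncol(recording$values)
  out <- recording$values
  for (ch in seq_len(nrow(out))) {
    y <- stats::convolve(recording$values[ch, ], rev(h), type = "open")
    out[ch, ] <- if (mode == "zero_phase")
      y[seq_len(n) + delay] else y[seq_len(n)]
  }
  eeg_recording(out, recording$fs, recording$channel_names,
                recording$trial_id)
}

#' Resample a recording to a target rate
#'
#' Polyphase rational-rate resampling (via `signal::resample`); duration is
#' preserved and the output has `round(n * target_fs / fs)` samples.
#'
#' @param recording An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return Resampled [eeg_recording()].
#' @export
resample_recording <- function(recording, target_fs = 200) {
  if (target_fs <= 0) stop("target_fs must be > 0", call. = FALSE)
  if (target_fs == recording$fs) return(recording)
  ratio <- target_fs / recording$fs
  pq <- rational_ratio(ratio)
  n_out <- round(ncol(recording$values) * ratio)
  out <- matrix(0, nrow(recording$values), n_out,
                dimnames = list(recording$channel_names, NULL))
  for (ch in seq_len(nrow(out))) {
    y <- signal::resample(recording$values[ch, ], pq[1], pq[2])
    out[ch, ] <- y[seq_len(n_out)]
  }
  eeg_recording(out, target_fs, recording$channel_names, recording$trial_id)
}

rational_ratio <- function(x, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("resampling ratio is not a small rational number", call. = FALSE)
}

#' Run the full preprocessing chain
#'
#' Fixed order: re-reference, bandpass at the acquisition rate, resample to
#' the analysis rate, low-pass at the analysis rate.  (Transient-artifact
#' removal sits between resampling and the low-pass in the full laboratory
#' pipeline and is outside this package's scope.)
#'
#' @param recording An [eeg_recording()] at the acquisition rate.
#' @param reference_channels Passed to [rereference()]; `NULL` skips.
#' @param target_fs Analysis rate.
#' @param mode Filter phase mode, see [fir_filter()].
#' @return Preprocessed [eeg_recording()] at `target_fs`.
#' @export
preprocess_recording <- function(recording, reference_channels = NULL,
                                 target_fs = 200, mode = "zero_phase") {
  x <- recording
  if (!is.null(reference_channels)) x <- rereference(x, reference_channels)
  x <- fir_filter(x, "bandpass", mode = mode)
  x <- resample_recording(x, target_fs)
  fir_filter(x, "lowpass", mode = mode)
}
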