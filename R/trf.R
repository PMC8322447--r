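## Multivariate temporal response functions by lagged ridge regression.
##
## The EEG response is modelled as the sum over stimulus features of the
## feature's impulse train convolved with an unknown kernel over lags
## -200..1500 ms, plus a residual.  Unrolling the convolution gives a sparse
## lagged design matrix; kernels are the ridge solution
## (X'X + lambda I)^-1 X'y with an unpenalized intercept.  TRFs are fit per
## trial and averaged; the regularization weight is chosen by trial-rotation
## (leave-one-trial-out) cross-validation.

#' Lag axis for TRF estimation
#'
#' @param lag_min_ms,lag_max_ms Lag range in ms relative to feature onset.
#' @param fs Sampling rate in Hz.
#' @return Object of class `lag_axis` with integer sample lags `lags_samp`,
#'   lag times `lags_ms`, and `n_lags` (341 for the defaults).
#' @export
lag_axis <- function(lag_min_ms = -200, lag_max_ms = 1500, fs = 200) {
  stopifnot(fs > 0, lag_min_ms < lag_max_ms)
  lags_samp <- seq.int(round(lag_min_ms * fs / 1000),
                       round(lag_max_ms * fs / 1000))
  structure(list(lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms, fs = fs,
                 lags_samp = lags_samp, lags_ms = lags_samp * 1000 / fs,
                 n_lags = length(lags_samp)),
            class = "lag_axis")
}

#' Build the sparse lagged design matrix
#'
#' Column `(i, tau)` holds the i-th stimulus feature delayed by lag `tau`:
#' entry at row `t` equals `S_i(t - tau)`.  Rows outside the trial are
#' zero-padded (contributions falling off the trial are dropped).  Columns
#' are ordered feature-major with lags ascending within each feature.
#'
#' @param stim A [stimulus_matrix()].
#' @param lag_axis A [lag_axis()]; `lag_axis$fs` must equal `stim$fs`.
#' @return A `Matrix::sparseMatrix` of size time x (features * lags).
#' @export
build_lagged_design <- function(stim, lag_axis) {
  if (stim$fs != lag_axis$fs)
    stop("stimulus and lag axis sampling rates differ", call. = FALSE)
  Tn <- ncol(stim$values); L <- lag_axis$n_lags
  nf <- nrow(stim$values)
  ii <- list(); jj <- list(); idx <- 1L
  for (f in seq_len(nf)) {
    cols <- which(stim$values[f, ] != 0)
    if (!length(cols)) next
    for (k in seq_len(L)) {
      rows <- cols + lag_axis$lags_samp[k]
      rows <- rows[rows >= 1 & rows <= Tn]
      if (length(rows)) {
        ii[[idx]] <- rows
        jj[[idx]] <- rep.int((f - 1L) * L + k, length(rows))
        idx <- idx + 1L
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii) %||% integer(0),
                       j = unlist(jj) %||% integer(0), x = 1,
                       dims = c(Tn, nf * L))
}

#' Ridge solution for the lagged regression
#'
#' Solves `(X'X + lambda I) w = X'y` through a Cholesky factorization for
#' one or many response channels at once; the intercept column is appended
#' internally and left unpenalized.
#'
#' @param design Sparse or dense design matrix (time x features*lags).
#' @param response Numeric vector, or channels x time matrix.
#' @param lambda Ridge weight (>= 0).
#' @param n_features,n_lags Used to reshape the weights; if both given the
#'   result carries a `(feature, lag, channel)` array.
#' @param intercept Include an unpenalized intercept (default TRUE).
#' @return List: `weights` ((features*lags) x channels matrix), `intercept`
#'   per channel, and `W` array if shapes were supplied.
#' @export
fit_ridge <- function(design, response, lambda, n_features = NULL,
                      n_lags = NULL, intercept = TRUE) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  Y <- if (is.matrix(response)) t(response) else matrix(response, ncol = 1)
  if (nrow(Y) != nrow(design))
    stop("response length must match design rows", call. = FALSE)
  p <- ncol(design)
  X <- if (intercept) cbind(design, rep(1, nrow(design))) else design
  A <- as.matrix(Matrix::crossprod(X))
  pen <- rep(lambda, ncol(X))
  if (intercept) pen[ncol(X)] <- 0
  diag(A) <- diag(A) + pen
  b <- as.matrix(Matrix::crossprod(X, Y))
  ch <- tryCatch(chol(A), error = function(e)
    stop("normal equations are singular (rank-deficient design with ",
         "lambda = 0?)", call. = FALSE))
  W <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  b0 <- if (intercept) W[p + 1, ] else rep(0, ncol(W))
  W <- W[seq_len(p), , drop = FALSE]
  out <- list(weights = W, intercept = b0)
  if (!is.null(n_features) && !is.null(n_lags)) {
    arr <- array(0, dim = c(n_features, n_lags, ncol(W)))
    for (chn in seq_len(ncol(W)))
      arr[, , chn] <- matrix(W[, chn], n_features, n_lags, byrow = TRUE)
    out$W <- arr
  }
  out
}

#' Per-participant TRF set
#'
#' @param W Array feature x lag x channel of kernel weights.
#' @param lag_axis A [lag_axis()].
#' @param scheme Stimulus scheme name.
#' @param feature_names,channel_names Dimension labels.
#' @param participant_id Optional identifier.
#' @param lambda Ridge weight used.
#' @param intercept Per-channel intercepts.
#' @param residual_variance Optional per-channel residual variance.
#' @return Object of class `trf_set`.
#' @export
trf_set <- function(W, lag_axis, scheme, feature_names, channel_names,
                    participant_id = NULL, lambda = NULL, intercept = NULL,
                    residual_variance = NULL) {
  stopifnot(dim(W)[1] == length(feature_names),
            dim(W)[2] == lag_axis$n_lags,
            dim(W)[3] == length(channel_names))
  dimnames(W) <- list(feature_names, NULL, channel_names)
  structure(list(W = W, lag_axis = lag_axis, scheme = scheme,
                 feature_names = feature_names,
                 channel_names = channel_names,
                 participant_id = participant_id, lambda = lambda,
                 intercept = intercept,
                 residual_variance = residual_variance),
            class = "trf_set")
}

#' @export
print.trf_set <- function(x, ...) {
  cat(sprintf("<trf_set> scheme %s: %d features x %d lags x %d channels (lambda = %s)\n",
              x$scheme, dim(x$W)[1], dim(x$W)[2], dim(x$W)[3],
              format(x$lambda %||% NA)))
  invisible(x)
}

# extract one kernel series
trf_series <- function(trfset, feature, channel) {
  trfset$W[feature, , channel]
}

#' Predict the neural response from a TRF set
#'
#' `prediction(t) = sum_i sum_tau w_i(tau) S_i(t - tau) + intercept`, i.e.
#' the lagged design times the flattened weights.
#'
#' @param trfset A [trf_set()].
#' @param stim A [stimulus_matrix()] with matching scheme and features.
#' @return Channels x time matrix.
#' @export
predict_response <- function(trfset, stim) {
  if (!identical(trfset$feature_names, stim$feature_names))
    stop("scheme/feature mismatch between TRF set and stimulus",
         call. = FALSE)
  X <- build_lagged_design(stim, trfset$lag_axis)
  nf <- length(trfset$feature_names); L <- trfset$lag_axis$n_lags
  nch <- length(trfset$channel_names)
  Wmat <- matrix(0, nf * L, nch)
  for (ch in seq_len(nch))
    Wmat[, ch] <- as.vector(t(trfset$W[, , ch]))
  pred <- as.matrix(X %*% Wmat)
  b0 <- trfset$intercept %||% rep(0, nch)
  t(sweep(pred, 2, -b0))
}

# fit one trial, returning weights in trf_set form (internal)
fit_trial_trf <- function(stim, recording, lambda, lag_axis) {
  X <- build_lagged_design(stim, lag_axis)
  fit <- fit_ridge(X, recording$values, lambda,
                   n_features = nrow(stim$values), n_lags = lag_axis$n_lags)
  fit
}

#' Estimate a participant's TRFs (per-trial fits averaged)
#'
#' Single-trial ridge TRFs are computed for every trial and averaged with
#' equal weight, one scheme at a time.
#'
#' @param stims List of [stimulus_matrix()] (one per trial).
#' @param recordings List of [eeg_recording()] (same order).
#' @param lambda Ridge weight (default 100, the grid-selected value).
#' @param lag_axis A [lag_axis()].
#' @param participant_id Optional identifier.
#' @return A [trf_set()].
#' @export
estimate_trfs <- function(stims, recordings, lambda = 100,
                          lag_axis = speechtrf::lag_axis(),
                          participant_id = NULL) {
  stopifnot(length(stims) >= 1, length(stims) == length(recordings))
  feat <- stims[[1]]$feature_names
  chans <- recordings[[1]]$channel_names
  L <- lag_axis$n_lags
  Wsum <- array(0, dim = c(length(feat), L, length(chans)))
  b0sum <- rep(0, length(chans))
  rv <- rep(0, length(chans))
  for (tr in seq_along(stims)) {
    if (!identical(stims[[tr]]$feature_names, feat))
      stop("trials disagree on the feature scheme", call. = FALSE)
    fit <- fit_trial_trf(stims[[tr]], recordings[[tr]], lambda, lag_axis)
    Wsum <- Wsum + fit$W
    b0sum <- b0sum + fit$intercept
  }
  W <- Wsum / length(stims); b0 <- b0sum / length(stims)
  out <- trf_set(W, lag_axis, stims[[1]]$scheme, feat, chans,
                 participant_id, lambda, b0)
  for (tr in seq_along(stims)) {
    res <- recordings[[tr]]$values - predict_response(out, stims[[tr]])
    rv <- rv + apply(res, 1, stats::var) / length(stims)
  }
  out$residual_variance <- rv
  out
}

#' Select the ridge weight by trial-rotation cross-validation
#'
#' For each candidate lambda, single-trial TRFs are fit on the training
#' trials, averaged, and used to predict the held-out trial; trials are
#' rotated so each serves as test once.  MSEs are averaged over rotations,
#' channels (and participants, if several are given); the lambda with the
#' lowest mean MSE wins (ties go to the smaller lambda).
#'
#' @param stims List of [stimulus_matrix()], or a list of such lists (one
#'   per participant, in which case `recordings` matches).
#' @param recordings List of [eeg_recording()] (or list of lists).
#' @param grid Candidate lambdas (default `c(1, 10, 100, 1000, 10000)`).
#' @param lag_axis A [lag_axis()].
#' @return List: `lambda` (selected), `mse` (named mean MSE per lambda).
#' @export
select_lambda <- function(stims, recordings,
                          grid = c(1, 10, 100, 1000, 10000),
                          lag_axis = speechtrf::lag_axis()) {
  multi <- !inherits(stims[[1]], "stimulus_matrix")
  plist <- if (multi) Map(list, stims = stims, recs = recordings)
           else list(list(stims = stims, recs = recordings))
  mse_all <- matrix(0, length(plist), length(grid))
  for (p in seq_along(plist)) {
    st <- plist[[p]]$stims; rc <- plist[[p]]$recs
    n_tr <- length(st)
    if (n_tr < 2) stop("lambda selection needs at least 2 trials",
                       call. = FALSE)
    feat <- st[[1]]$feature_names; L <- lag_axis$n_lags
    nch <- nrow(rc[[1]]$values)
    # cache designs and sufficient statistics per trial
    designs <- lapply(st, build_lagged_design, lag_axis = lag_axis)
    for (g in seq_along(grid)) {
      fits <- vector("list", n_tr)
      for (tr in seq_len(n_tr))
        fits[[tr]] <- fit_ridge(designs[[tr]], rc[[tr]]$values, grid[g],
                                n_features = length(feat), n_lags = L)
      err <- 0
      for (test in seq_len(n_tr)) {
        train <- setdiff(seq_len(n_tr), test)
        Wbar <- Reduce(`+`, lapply(fits[train], `[[`, "W")) / length(train)
        b0 <- Reduce(`+`, lapply(fits[train], `[[`, "intercept")) /
          length(train)
        ts <- trf_set(Wbar, lag_axis, st[[test]]$scheme, feat,
                      rc[[test]]$channel_names, lambda = grid[g],
                      intercept = b0)
        pred <- predict_response(ts, st[[test]])
        err <- err + mean((rc[[test]]$values - pred)^2)
      }
      mse_all[p, g] <- err / n_tr
    }
  }
  mse <- colMeans(mse_all)
  names(mse) <- format(grid, scientific = FALSE, trim = TRUE)
  list(lambda = grid[which.min(mse)], mse = mse)
}
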