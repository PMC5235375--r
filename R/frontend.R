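# Audio front end. The fixed processing chain is:
#   AGC rescale -> resample to 24 kHz -> order-10 Butterworth high-pass at
#   1 kHz (zero-phase) -> 20-ms frames with 75 % overlap (5-ms hop) ->
#   35 LFCC + 35 delta + 20 delta-delta = 90 descriptors per frame,
# plus a -50 dBFS frame-energy activity gate referenced to the *pre-AGC*
# signal (the gate mimics a fixed threshold on the recorder's raw input, so
# the AGC gain is subtracted from the processed frame energies).

FRONTEND_RATE <- 24000
FRAME_LEN <- 480L    # 20 ms at 24 kHz
FRAME_HOP <- 120L    # 5 ms
DB_FLOOR <- -120

#' Adaptive gain control: rescale a clip to peak full scale
#'
#' Multiplies the clip so that `max(abs(samples)) == 1` and records the gain
#' applied (in dB) for later energy bookkeeping.
#'
#' @param clip an [audio_clip()].
#' @return the rescaled clip, with attribute `agc_gain_db`.
#' @export
agc_rescale <- function(clip) {
  pk <- max(abs(clip$samples))
  if (pk == 0) stop("all-zero clip: AGC gain undefined")
  out <- clip
  out$samples <- clip$samples / pk
  attr(out, "agc_gain_db") <- -dbfs(pk)  # gain applied, +dB for quiet clips
  out
}

#' Down-sample a clip to 24 kHz
#'
#' Anti-aliased resampling to the front end's working rate; content above
#' 12 kHz (e.g. insect song) is removed by the anti-alias stage. Upsampling
#' is out of contract.
#'
#' @param clip an [audio_clip()] with `rate_hz >= 24000`.
#' @return a 24 kHz [audio_clip()] (attributes preserved).
#' @export
resample_24k <- function(clip) {
  if (clip$rate_hz < FRONTEND_RATE)
    stop("input rate ", clip$rate_hz, " Hz < 24 kHz: upsampling not supported")
  g <- attr(clip, "agc_gain_db")
  out <- resample_clip(clip, FRONTEND_RATE)
  attr(out, "agc_gain_db") <- g
  out
}

#' High-pass filter a 24 kHz clip
#'
#' Order-10 Butterworth, 1 kHz cut-off, applied forward-backward
#' (zero-phase), suppressing wind and other low-frequency interference.
#'
#' @param clip a 24 kHz [audio_clip()].
#' @param fc cut-off frequency, Hz.
#' @param order filter order.
#' @return filtered clip (attributes preserved).
#' @export
highpass <- function(clip, fc = 1000, order = 10) {
  filt <- butter_design(order, fc, clip$rate_hz, type = "high")
  g <- attr(clip, "agc_gain_db")
  out <- clip
  out$samples <- filtfilt_sos(clip$samples, filt)
  attr(out, "agc_gain_db") <- g
  out
}

#' Cut a clip into overlapping frames
#'
#' 480-sample (20-ms) windows every 120 samples (5 ms, 75 percent overlap).
#' Frame energy is the frame RMS in dBFS, where 0 dBFS is defined as RMS 1.0
#' (a full-scale square wave; a full-scale sine reads -3.01 dBFS). If the
#' clip carries an `agc_gain_db` attribute the gain is subtracted so the
#' energies refer to the recorder's raw input.
#'
#' @param clip a 24 kHz [audio_clip()].
#' @return list with `frames` (matrix n_frames x 480), `frame_start_s`,
#'   `frame_energy_dbfs`, `rate_hz`.
#' @export
frame_clip <- function(clip) {
  stopifnot(clip$rate_hz == FRONTEND_RATE)
  x <- clip$samples
  n <- length(x)
  if (n < FRAME_LEN) {
    warning("clip shorter than one 20-ms window: zero frames")
    return(list(frames = matrix(numeric(0), 0, FRAME_LEN),
                frame_start_s = numeric(0), frame_energy_dbfs = numeric(0),
                rate_hz = FRONTEND_RATE))
  }
  n_frames <- (n - FRAME_LEN) %/% FRAME_HOP + 1L
  starts <- (seq_len(n_frames) - 1L) * FRAME_HOP
  idx <- outer(starts, seq_len(FRAME_LEN), `+`)
  frames <- matrix(x[idx], nrow = n_frames)
  rms <- sqrt(rowMeans(frames^2))
  energy <- dbfs(rms)
  g <- attr(clip, "agc_gain_db")
  if (!is.null(g)) energy <- pmax(energy - g, DB_FLOOR)
  list(frames = frames, frame_start_s = starts / FRONTEND_RATE,
       frame_energy_dbfs = energy, rate_hz = FRONTEND_RATE)
}

#' Frame activity gate
#'
#' A frame is active when its energy is at or above the threshold (default
#' -50 dBFS relative to the raw recorder input). Only active frames are
#' scored by the detector; below the threshold target calls are too faint to
#' annotate with confidence even for an expert.
#'
#' @param framed result of [frame_clip()].
#' @param threshold_dbfs gate threshold.
#' @return logical vector, one element per frame.
#' @export
activity_gate <- function(framed, threshold_dbfs = -50) {
  framed$frame_energy_dbfs >= threshold_dbfs
}

# ---- LFCC -------------------------------------------------------------------

# triangular filterbank, M filters linearly spaced over [0, fmax] on an
# nfft/2+1-bin power spectrum
linear_filterbank <- function(m, nfft, fs, fmax = fs / 2) {
  edges <- seq(0, fmax, length.out = m + 2)
  bins <- 0:(nfft / 2) * fs / nfft
  fb <- matrix(0, m, nfft / 2 + 1)
  for (j in seq_len(m)) {
    lo <- edges[j]; ce <- edges[j + 1]; hi <- edges[j + 2]
    up <- bins >= lo & bins <= ce
    dn <- bins > ce & bins <= hi
    fb[j, up] <- (bins[up] - lo) / (ce - lo)
    fb[j, dn] <- (hi - bins[dn]) / (hi - ce)
  }
  fb
}

# orthonormal DCT-II matrix (rows = coefficients 0..m-1)
dct_matrix <- function(m) {
  d <- sqrt(2 / m) * cos(pi * outer(0:(m - 1), (0:(m - 1)) + 0.5) / m)
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

#' Linear-frequency cepstral coefficients
#'
#' Per frame: Hamming window, power spectrum (512-point FFT), `n_filters`
#' linearly spaced triangular filters over 0-12 kHz, log filter energies
#' (floored at `log(energy_floor)`), orthonormal DCT-II, keep coefficients
#' c1..c35. c0 (the overall log gain) is dropped so the features are
#' invariant to amplitude scaling.
#'
#' @param framed result of [frame_clip()].
#' @param n_keep number of cepstral coefficients kept (c1..c`n_keep`).
#' @param n_filters filterbank size.
#' @param energy_floor floor for filter energies before the log.
#' @return matrix n_frames x `n_keep`.
#' @export
lfcc <- function(framed, n_keep = 35, n_filters = 40, energy_floor = 1e-12) {
  frames <- framed$frames
  n_frames <- nrow(frames)
  nfft <- 512L
  if (n_frames == 0) return(matrix(numeric(0), 0, n_keep))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(FRAME_LEN - 1)) / (FRAME_LEN - 1))
  fw <- sweep(frames, 2, w, `*`)
  fw <- cbind(fw, matrix(0, n_frames, nfft - FRAME_LEN))
  spec <- stats::mvfft(t(fw))[1:(nfft / 2 + 1), , drop = FALSE]
  pow <- Mod(spec)^2
  fb <- linear_filterbank(n_filters, nfft, framed$rate_hz)
  fe <- log(pmax(fb %*% pow, energy_floor))
  dct <- dct_matrix(n_filters)
  cc <- dct %*% fe
  t(cc[2:(n_keep + 1), , drop = FALSE])
}

#' Temporal derivatives of a feature matrix
#'
#' First derivatives via the symmetric +/-2-frame least-squares regression
#' slope, second derivatives as the derivative of the first; edges use
#' replicated padding. The returned matrix holds all first derivatives plus
#' the first `n_keep_dd` second derivatives.
#'
#' @param feat matrix n_frames x d (>= 5 frames for meaningful derivatives).
#' @param n_keep_dd number of second-derivative columns kept.
#' @return matrix n_frames x (d + n_keep_dd).
#' @export
deltas <- function(feat, n_keep_dd = 20) {
  d1 <- delta_regression(feat)
  d2 <- delta_regression(d1)
  cbind(d1, d2[, seq_len(min(n_keep_dd, ncol(d2))), drop = FALSE])
}

delta_regression <- function(x) {
  n <- nrow(x)
  if (n == 0) return(x)
  pad <- function(i) pmin(pmax(i, 1L), n)
  (1 * (x[pad(1:n + 1), , drop = FALSE] - x[pad(1:n - 1), , drop = FALSE]) +
   2 * (x[pad(1:n + 2), , drop = FALSE] - x[pad(1:n - 2), , drop = FALSE])) / 10
}

#' Fit / apply per-dimension feature standardization
#'
#' Maps each feature dimension affinely to \[-1, 1\] using the training-set
#' min/max ("uniform dynamic range"). Values outside the training range are
#' clipped; a constant dimension maps to 0. Statistics must be estimated on
#' training data only and are persisted with the model.
#'
#' @param feat training feature matrix.
#' @return `fit_standardizer`: a `feature_stats` object.
#' @export
fit_standardizer <- function(feat) {
  structure(list(min = apply(feat, 2, min), max = apply(feat, 2, max),
                 dim = ncol(feat)),
            class = "feature_stats")
}

#' @rdname fit_standardizer
#' @param stats a `feature_stats` object from [fit_standardizer()].
#' @param new_feat matrix to transform (same dimensionality as training).
#' @return `apply_standardizer`: matrix with all values in \[-1, 1\].
#' @export
apply_standardizer <- function(stats, new_feat) {
  if (ncol(new_feat) != stats$dim)
    stop("feature dimension ", ncol(new_feat), " != stats dimension ", stats$dim)
  rng <- stats$max - stats$min
  out <- matrix(0, nrow(new_feat), ncol(new_feat))
  ok <- rng > 0
  out[, ok] <- sweep(sweep(new_feat[, ok, drop = FALSE], 2, stats$min[ok]),
                     2, rng[ok], `/`) * 2 - 1
  pmin(pmax(out, -1), 1)
}

#' Run the full front end on a clip
#'
#' AGC -> 24 kHz -> high-pass -> frames -> 90 descriptors (35 LFCC, 35
#' delta, 20 delta-delta), with pre-AGC frame energies and the -50 dBFS
#' activity mask. Standardization is applied only if `stats` is supplied
#' (training-time statistics).
#'
#' @param clip an [audio_clip()] at any rate >= 24 kHz.
#' @param stats optional `feature_stats` from [fit_standardizer()].
#' @param gate_threshold_dbfs activity-gate threshold.
#' @return a `frame_features` list: `features` (n x 90), `frame_start_s`,
#'   `frame_energy_dbfs`, `active_mask`.
#' @export
extract_features <- function(clip, stats = NULL, gate_threshold_dbfs = -50) {
  framed <- clip |> agc_rescale() |> resample_24k() |> highpass() |> frame_clip()
  feat <- lfcc(framed)
  feat <- cbind(feat, deltas(feat))
  if (!is.null(stats)) feat <- apply_standardizer(stats, feat)
  structure(list(features = feat, frame_start_s = framed$frame_start_s,
                 frame_energy_dbfs = framed$frame_energy_dbfs,
                 active_mask = activity_gate(framed, gate_threshold_dbfs)),
            class = "frame_features")
}
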