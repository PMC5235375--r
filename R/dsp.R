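# Signal-processing primitives: IIR (Butterworth) design + zero-phase
# filtering, Kaiser-windowed FIR design, and FFT convolution. These are kept
# deliberately small: only what the front end and the scene synthesiser need.

#' Design a digital Butterworth filter in second-order sections
#'
#' Analog prototype poles mapped by the low-pass-to-low/high-pass transform
#' with frequency prewarping, then the bilinear transform. Returned as an
#' `n_sections x 6` SOS matrix (b0 b1 b2 a0 a1 a2, a0 = 1), gain folded into
#' the first section.
#'
#' @param order filter order (>= 1).
#' @param fc cut-off frequency, Hz (-3 dB point per pass).
#' @param fs sampling rate, Hz.
#' @param type `"high"` or `"low"`.
#' @return list with `sos` matrix and the design parameters.
#' @export
butter_design <- function(order, fc, fs, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  k <- seq_len(order)
  # analog low-pass prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * fc / fs)  # prewarped cut-off (rad/s)
  if (type == "high") {
    p <- wc / p                      # LP -> HP: n zeros at s = 0
  } else {
    p <- wc * p
  }
  # bilinear transform of poles; zeros map to z = 1 (HP) or z = -1 (LP)
  zp <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))
  zz <- if (type == "high") 1 else -1
  # pair complex-conjugate poles into biquads; poles come in conjugate pairs
  # except possibly one real pole for odd order
  idx <- order(abs(Im(zp)) < 1e-12, Re(zp))  # real poles last
  zp <- zp[idx]
  n_pairs <- order %/% 2
  sos <- matrix(0, nrow = ceiling(order / 2), ncol = 6)
  used <- rep(FALSE, order)
  row <- 1L
  for (i in seq_along(zp)) {
    if (used[i]) next
    pi1 <- zp[i]
    if (abs(Im(pi1)) > 1e-12) {
      j <- which(!used & abs(zp - Conj(pi1)) < 1e-8)[1]
      used[c(i, j)] <- TRUE
      a1 <- -2 * Re(pi1); a2 <- Mod(pi1)^2
      sos[row, ] <- c(1, -2 * zz, zz^2, 1, a1, a2)
    } else {
      used[i] <- TRUE
      a1 <- -Re(pi1)
      sos[row, ] <- c(1, -zz, 0, 1, a1, 0)
    }
    row <- row + 1L
  }
  # normalise gain: HP unity at Nyquist (z = -1), LP unity at DC (z = 1)
  zref <- if (type == "high") -1 + 0i else 1 + 0i
  g <- sos_response(sos, zref)
  sos[1, 1:3] <- sos[1, 1:3] / Mod(g)
  list(sos = sos, order = order, fc = fc, fs = fs, type = type)
}

# complex response of an SOS cascade at point(s) z on the unit circle
sos_response <- function(sos, z) {
  h <- rep(1 + 0i, length(z))
  zi1 <- 1 / z; zi2 <- zi1^2
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] * zi1 + sos[s, 3] * zi2) /
      (sos[s, 4] + sos[s, 5] * zi1 + sos[s, 6] * zi2)
  }
  h
}

#' Magnitude response of a designed filter
#'
#' @param filt result of [butter_design()].
#' @param f frequencies in Hz.
#' @param zero_phase if TRUE, report the forward-backward (squared) magnitude.
#' @return magnitude in dB at each frequency.
#' @export
filter_response_db <- function(filt, f, zero_phase = FALSE) {
  z <- exp(1i * 2 * pi * f / filt$fs)
  m <- Mod(sos_response(filt$sos, z))
  db <- 20 * log10(pmax(m, 1e-300))
  if (zero_phase) db <- 2 * db
  db
}

#' Apply an SOS filter zero-phase (forward-backward)
#'
#' Odd-reflection padding at both ends reduces edge transients, after which
#' the cascade is run forward and then backward. The effective magnitude
#' response is the square of the single-pass response and the phase is zero,
#' so event timestamps are not skewed.
#'
#' @param x numeric signal.
#' @param filt result of [butter_design()].
#' @return filtered signal, same length.
#' @export
filtfilt_sos <- function(x, filt) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (2L * nrow(filt$sos) + 1L) * 10L)
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_ref <- 2 * x[n] - x[seq(n - 1, n - pad)]
    ext <- c(head_ref, x, tail_ref)
  } else ext <- x
  y <- sos_filter_cpp(ext, filt$sos)
  y <- rev(sos_filter_cpp(rev(y), filt$sos))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

# ---- FIR ---------------------------------------------------------------------

kaiser_beta <- function(atten_db) {
  if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
}

kaiser_window <- function(n, beta) {
  m <- n - 1
  t <- (0:m - m / 2) / (m / 2)
  besselI(beta * sqrt(pmax(0, 1 - t^2)), 0) / besselI(beta, 0)
}

#' Design a Kaiser-windowed low-pass FIR
#'
#' @param fc cut-off (end of passband), Hz.
#' @param fs sampling rate, Hz.
#' @param trans_hz transition bandwidth, Hz.
#' @param atten_db stopband attenuation, dB.
#' @return numeric vector of taps (odd length, linear phase).
#' @export
fir_lowpass <- function(fc, fs, trans_hz = 0.1 * fc, atten_db = 80) {
  beta <- kaiser_beta(atten_db)
  dw <- 2 * pi * trans_hz / fs
  n <- ceiling((atten_db - 8) / (2.285 * dw))
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  fn <- (fc + trans_hz / 2) / fs   # cut at mid-transition
  k <- -m:m
  h <- 2 * fn * sinc(2 * fn * k)
  h * kaiser_window(n, beta)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' FFT-based linear convolution, centred
#'
#' Convolves `x` with odd-length linear-phase taps `h` and removes the group
#' delay, returning a vector the same length as `x`.
#' @param x signal.
#' @param h FIR taps (odd length).
#' @return filtered signal, length of `x`.
#' @export
fir_filter <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  n <- length(x); m <- length(h)
  nfft <- 2^ceiling(log2(n + m - 1))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  H <- stats::fft(c(h, rep(0, nfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  d <- (m - 1) / 2
  y[(d + 1):(d + n)]
}

#' Resample a clip to a target rate
#'
#' Rational-ratio resampling with a Kaiser anti-alias FIR. The common field
#' case (an integer decimation such as 48 kHz to 24 kHz) avoids upsampling
#' entirely; arbitrary ratios go through zero-stuffing, so they are intended
#' for short clips only.
#'
#' @param clip an [audio_clip()].
#' @param target_hz target rate (Hz).
#' @param atten_db anti-alias stopband attenuation.
#' @return resampled [audio_clip()].
#' @export
resample_clip <- function(clip, target_hz, atten_db = 80) {
  fs <- clip$rate_hz
  if (fs == target_hz) return(clip)
  g <- gcd_int(round(fs), round(target_hz))
  L <- round(target_hz) / g
  M <- round(fs) / g
  nyq <- target_hz / 2
  if (L == 1) {
    h <- fir_lowpass(0.92 * nyq, fs, trans_hz = 0.08 * nyq, atten_db = atten_db)
    y <- fir_filter(clip$samples, h)
    out <- y[seq(1, length(y), by = M)]
  } else {
    fs_up <- fs * L
    up <- numeric(length(clip$samples) * L)
    up[seq(1, length(up), by = L)] <- clip$samples
    h <- fir_lowpass(0.92 * min(nyq, fs / 2), fs_up,
                     trans_hz = 0.08 * min(nyq, fs / 2), atten_db = atten_db)
    y <- L * fir_filter(up, h)
    out <- y[seq(1, length(y), by = M)]
  }
  audio_clip(out, target_hz, source_id = clip$source_id, channel = clip$channel)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
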