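# Synthetic soundscapes with exact ground truth. The target call is modelled
# as a harmonic stack (fundamental plus integer harmonics with 1/k amplitude
# roll-off), which reproduces the salient property of lapwing calls -- energy
# spread over many harmonics in roughly 1-10 kHz -- without attempting to
# mimic the actual repertoire. Backgrounds are chosen to exercise the front
# end's filtering ranges: broadband noise, a low-frequency "wind" band
# (< 640 Hz) and a high-frequency tonal "insect" cluster (>= 12 kHz).

#' Specification of one synthetic call
#'
#' @param onset_s onset within the scene, seconds.
#' @param n_notes number of notes in the call (series).
#' @param note_dur_s duration of each note, seconds (>= 0.05 for target calls).
#' @param gap_s silent gap between notes, seconds.
#' @param f0_hz fundamental frequency, Hz.
#' @param n_harmonics number of harmonics including the fundamental.
#' @param peak_dbfs peak level of the rendered call, dBFS (<= 0).
#' @param label `"target"` (harmonic stack) or `"nontarget"` (the scene
#'   renderer gives nontarget calls a single harmonic, i.e. a plain whistle).
#' @return a `call_spec` object.
#' @export
call_spec <- function(onset_s = 0, n_notes = 3L, note_dur_s = 0.12,
                      gap_s = 0.08, f0_hz = 1300, n_harmonics = 6L,
                      peak_dbfs = -20, label = c("target", "nontarget")) {
  label <- match.arg(label)
  if (peak_dbfs > 0) stop("peak_dbfs must be <= 0 (dB relative to full scale)")
  stopifnot(f0_hz > 0, gap_s >= 0, n_notes >= 1, n_harmonics >= 1)
  if (label == "target" && note_dur_s < 0.05)
    stop("target call notes must last >= 0.05 s")
  structure(list(onset_s = onset_s, n_notes = as.integer(n_notes),
                 note_dur_s = note_dur_s, gap_s = gap_s, f0_hz = f0_hz,
                 n_harmonics = as.integer(n_harmonics), peak_dbfs = peak_dbfs,
                 label = label),
            class = "call_spec")
}

call_duration <- function(spec)
  spec$n_notes * spec$note_dur_s + (spec$n_notes - 1) * spec$gap_s

#' Render a call specification as a waveform
#'
#' Each note is a sum of sinusoids at `k * f0` with `1/k` amplitude roll-off
#' (harmonics at or above Nyquist are dropped) and 5-ms raised-cosine edges.
#' The finished clip is scaled so its peak sample equals
#' `10^(peak_dbfs / 20)` of full scale.
#'
#' @param spec a [call_spec()].
#' @param rate sampling rate, Hz.
#' @param f0_jitter fractional per-note jitter of the fundamental (e.g. 0.02
#'   for +/-2 percent); drawn from the current RNG stream when > 0.
#' @return an [audio_clip()] of duration
#'   `n_notes * note_dur_s + (n_notes - 1) * gap_s`.
#' @export
make_call_waveform <- function(spec, rate, f0_jitter = 0) {
  if (spec$peak_dbfs > 0) stop("peak_dbfs must be <= 0")
  n_note <- round(spec$note_dur_s * rate)
  n_gap <- round(spec$gap_s * rate)
  edge <- min(round(0.005 * rate), floor(n_note / 2))
  env <- rep(1, n_note)
  if (edge > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
    env[seq_len(edge)] <- ramp
    env[n_note + 1 - seq_len(edge)] <- ramp
  }
  t <- (seq_len(n_note) - 1) / rate
  notes <- vector("list", spec$n_notes)
  for (i in seq_len(spec$n_notes)) {
    f0 <- spec$f0_hz
    if (f0_jitter > 0) f0 <- f0 * (1 + stats::runif(1, -f0_jitter, f0_jitter))
    ks <- seq_len(spec$n_harmonics)
    ks <- ks[ks * f0 < rate / 2]
    y <- numeric(n_note)
    for (k in ks) y <- y + sin(2 * pi * k * f0 * t) / k
    notes[[i]] <- y * env
  }
  gap <- numeric(n_gap)
  pieces <- vector("list", 2 * spec$n_notes - 1)
  pieces[seq(1, length(pieces), by = 2)] <- notes
  if (spec$n_notes > 1) pieces[seq(2, length(pieces) - 1, by = 2)] <- list(gap)
  x <- unlist(pieces)
  pk <- max(abs(x))
  if (pk > 0) x <- x * db_to_amp(spec$peak_dbfs) / pk
  audio_clip(x, rate)
}

#' Specification of a synthetic soundscape scene
#'
#' Background levels are RMS levels in dBFS; call levels are peak dBFS.
#'
#' @param duration_s scene length, seconds.
#' @param sample_rate_hz sampling rate, Hz.
#' @param broadband_level_dbfs RMS level of Gaussian broadband noise.
#' @param wind_band_level_dbfs RMS level of the low-passed (< 640 Hz) wind
#'   band.
#' @param insect_band_level_dbfs RMS level of the tonal insect cluster
#'   (>= 12 kHz; silently absent when the rate cannot represent it).
#' @param calls list of [call_spec()] objects.
#' @param seed integer; the whole scene is a deterministic function of it.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(duration_s, sample_rate_hz = 48000,
                       broadband_level_dbfs = -45,
                       wind_band_level_dbfs = -35,
                       insect_band_level_dbfs = -40,
                       calls = list(), seed = 1L) {
  stopifnot(duration_s > 0, sample_rate_hz > 0,
            broadband_level_dbfs <= 0, wind_band_level_dbfs <= 0,
            insect_band_level_dbfs <= 0)
  for (cs in calls) {
    stopifnot(inherits(cs, "call_spec"))
    if (cs$onset_s + call_duration(cs) > duration_s)
      stop("call at onset ", cs$onset_s, " s extends past the scene end")
  }
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 broadband_level_dbfs = broadband_level_dbfs,
                 wind_band_level_dbfs = wind_band_level_dbfs,
                 insect_band_level_dbfs = insect_band_level_dbfs,
                 calls = calls, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a scene: audio plus ground-truth annotations
#'
#' Mixes the scene's calls (targets as harmonic stacks with +/-2 percent
#' per-note fundamental jitter, nontargets as single-harmonic whistles) over
#' the three background layers. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return list with `clip` (an [audio_clip()]) and `annotations`, a
#'   data.frame with columns `start_s`, `end_s`, `label`, `peak_dbfs`, sorted
#'   by start time.
#' @export
render_scene <- function(spec) {
  withr::with_seed(spec$seed, {
    fs <- spec$sample_rate_hz
    n <- round(spec$duration_s * fs)
    x <- stats::rnorm(n) * db_to_amp(spec$broadband_level_dbfs)
    # wind: low-passed noise, rescaled to the requested RMS after filtering
    wind <- stats::rnorm(n)
    wind <- fir_filter(wind, fir_lowpass(640, fs, trans_hz = 200))
    wind <- wind / sqrt(mean(wind^2)) * db_to_amp(spec$wind_band_level_dbfs)
    x <- x + wind
    if (fs / 2 > 12500) {
      tt <- (seq_len(n) - 1) / fs
      f_ins <- stats::runif(4, 12500, min(16000, fs / 2 * 0.95))
      ins <- rowSums(vapply(f_ins, function(f)
        sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)), numeric(n)))
      ins <- ins / sqrt(mean(ins^2)) * db_to_amp(spec$insect_band_level_dbfs)
      x <- x + ins
    }
    ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0), peak_dbfs = numeric(0))
    for (cs in spec$calls) {
      cs_r <- cs
      if (cs$label == "nontarget") {
        cs_r$n_harmonics <- 1L
        cs_r$f0_hz <- if (cs$f0_hz >= 2000 && cs$f0_hz <= 4000) cs$f0_hz
          else stats::runif(1, 2000, 4000)
      }
      w <- make_call_waveform(cs_r, fs, f0_jitter = 0.02)
      i0 <- round(cs$onset_s * fs) + 1L
      idx <- i0:(i0 + length(w$samples) - 1L)
      x[idx] <- x[idx] + w$samples
      ann <- rbind(ann, data.frame(
        start_s = cs$onset_s, end_s = cs$onset_s + call_duration(cs),
        label = cs$label, peak_dbfs = cs$peak_dbfs))
    }
    if (max(abs(x)) > 1)
      stop("scene clips: mixed peak ", round(max(abs(x)), 3),
           " exceeds full scale; lower the component levels")
    ann <- ann[order(ann$start_s), , drop = FALSE]
    rownames(ann) <- NULL
    list(clip = audio_clip(x, fs, source_id = sprintf("scene_seed%d", spec$seed)),
         annotations = ann)
  })
}

#' Write a rendered scene to disk
#'
#' Writes `scene.wav` (16-bit PCM) and `scene_annotations.csv`
#' (start_s, end_s, label, peak_dbfs) into `dir`.
#'
#' @param scene result of [render_scene()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the two paths.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wav <- file.path(dir, "scene.wav")
  csv <- file.path(dir, "scene_annotations.csv")
  write_wav(scene$clip, wav)
  utils::write.csv(scene$annotations, csv, row.names = FALSE)
  invisible(c(wav, csv))
}
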