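# Desk-scale end-to-end detector study. The full-scale configuration of this
# architecture (a 512-component UBM trained on 75 h of soundscapes) is not
# reproducible on a desktop, so the package ships a scaled-down but complete
# study: a 64-component UBM trained on ~10 min of synthetic background,
# means-only adaptation on ~2 min of synthetic target calls, threshold
# calibration on a development scene, and event-level evaluation on a
# held-out scene whose target calls are all at or above -40 dBFS.

target_training_calls <- function(n, duration_s, peaks = c(-30, -10)) {
  # dense call series so ~35 s of each minute is voiced
  onsets <- seq(1, duration_s - 2.5, length.out = n)
  lapply(seq_len(n), function(i) {
    call_spec(onset_s = onsets[i], n_notes = 6L, note_dur_s = 0.15,
              gap_s = 0.1, f0_hz = stats::runif(1, 1100, 1600),
              n_harmonics = 6L,
              peak_dbfs = stats::runif(1, peaks[1], peaks[2]),
              label = "target")
  })
}

eval_scene_calls <- function(n_target, n_nontarget, duration_s,
                             target_peaks = c(-35, -15)) {
  slots <- sample(seq(1, duration_s - 3, by = 3))
  stopifnot(length(slots) >= n_target + n_nontarget)
  c(
    lapply(slots[seq_len(n_target)], function(o)
      call_spec(onset_s = o, n_notes = sample(3:6, 1), note_dur_s = 0.15,
                gap_s = 0.12, f0_hz = stats::runif(1, 1100, 1600),
                n_harmonics = 6L,
                peak_dbfs = stats::runif(1, target_peaks[1], target_peaks[2]),
                label = "target")),
    lapply(slots[n_target + seq_len(n_nontarget)], function(o)
      call_spec(onset_s = o, n_notes = sample(2:4, 1), note_dur_s = 0.2,
                gap_s = 0.15, f0_hz = stats::runif(1, 2000, 4000),
                n_harmonics = 1L,
                peak_dbfs = stats::runif(1, -35, -15),
                label = "nontarget"))
  )
}

# frames of a scene restricted to annotated intervals of a label
frames_in_annotations <- function(feats, annotations, label) {
  ann <- annotations[annotations$label == label, , drop = FALSE]
  keep <- rep(FALSE, length(feats$frame_start_s))
  for (i in seq_len(nrow(ann))) {
    keep <- keep | (feats$frame_start_s >= ann$start_s[i] &
                      feats$frame_start_s + 0.02 <= ann$end_s[i])
  }
  keep & feats$active_mask
}

#' Run the desk-scale detector study
#'
#' Trains the UBM on `n_bg_scenes` one-minute background scenes (no target
#' calls, nontarget whistles present), adapts the target model on target-call
#' frames from call-dense scenes totalling about `n_target_scenes` minutes,
#' calibrates the decision threshold for best event F1 on a development
#' scene, and evaluates event-level precision and miss rate on a held-out
#' scene (disjoint seeds) whose target calls are >= -40 dBFS. All scenes are
#' rendered at 24 kHz.
#'
#' @param seed master seed; scene seeds are derived from it.
#' @param k UBM components.
#' @param n_bg_scenes one-minute background scenes for UBM training.
#' @param n_target_scenes one-minute call-dense scenes for adaptation.
#' @param relevance_factor MAP relevance factor.
#' @param max_iter EM iteration cap for the desk-scale run.
#' @return list: `precision`, `miss_rate`, `threshold`, `f1_dev`, `summary`
#'   (the held-out [match_events()] result), `sweep` (dev threshold sweep),
#'   `ubm`, `target`, `stats`, and `eval_scores`/`eval_annotations` for ROC
#'   inspection.
#' @export
detector_study <- function(seed = 1L, k = 64, n_bg_scenes = 10,
                           n_target_scenes = 2, relevance_factor = 16,
                           max_iter = 100) {
  seed <- as.integer(seed)
  scene_seed <- function(off) (seed * 1000L + off) %% .Machine$integer.max
  bg_feats <- list()
  for (i in seq_len(n_bg_scenes)) {
    sc <- render_scene(withr::with_seed(scene_seed(i), scene_spec(
      60, sample_rate_hz = 24000,
      calls = eval_scene_calls(0, 4, 60), seed = scene_seed(i))))
    fe <- extract_features(sc$clip)
    bg_feats[[i]] <- fe$features[fe$active_mask, , drop = FALSE]
  }
  bg <- do.call(rbind, bg_feats)
  stats <- fit_standardizer(bg)
  bg <- apply_standardizer(stats, bg)
  ubm <- train_ubm(bg, k = k, seed = seed, max_iter = max_iter)

  tg_feats <- list()
  for (i in seq_len(n_target_scenes)) {
    sc <- render_scene(withr::with_seed(scene_seed(100L + i), scene_spec(
      60, sample_rate_hz = 24000,
      calls = target_training_calls(25, 60), seed = scene_seed(100L + i))))
    fe <- extract_features(sc$clip, stats = stats)
    keep <- frames_in_annotations(fe, sc$annotations, "target")
    tg_feats[[i]] <- fe$features[keep, , drop = FALSE]
  }
  target <- adapt_means(ubm, do.call(rbind, tg_feats),
                        relevance_factor = relevance_factor)

  score_scene <- function(off, n_t, n_nt, peaks) {
    sc <- render_scene(withr::with_seed(scene_seed(off), scene_spec(
      90, sample_rate_hz = 24000,
      calls = eval_scene_calls(n_t, n_nt, 90, target_peaks = peaks),
      seed = scene_seed(off))))
    fe <- extract_features(sc$clip, stats = stats)
    list(scores = score_frames(fe, ubm, target), annotations = sc$annotations)
  }
  dev <- score_scene(200L, 15, 8, c(-38, -15))
  cal <- calibrate_threshold(dev$scores, dev$annotations)
  ev <- score_scene(300L, 15, 8, c(-40, -15))
  events <- smooth_decisions(decide(ev$scores, cal$threshold),
                             ev$scores$frame_start_s, llr = ev$scores$llr)
  m <- match_events(events, ev$annotations)
  list(precision = if (m$H + m$I > 0) m$H / (m$H + m$I) else NA_real_,
       miss_rate = m$misses / m$N, threshold = cal$threshold,
       f1_dev = cal$f1, summary = m, sweep = cal$sweep,
       ubm = ubm, target = target, stats = stats,
       eval_scores = ev$scores, eval_annotations = ev$annotations)
}

#' Frame-level ROC of a scored scene under a threshold sweep
#'
#' Frames whose span lies inside a target annotation are positives, all
#' other active frames negatives. Because the per-frame decision
#' `llr >= theta` is pointwise monotone in theta, both rates are
#' non-increasing as the threshold rises. (Event-level rates after the
#' series-merging smoothing are deliberately not monotone: a very low
#' threshold fuses the whole scene into one event that can credit only one
#' annotation.)
#'
#' @param scores `frame_scores`.
#' @param annotations ground-truth annotations.
#' @param thresholds ascending threshold grid.
#' @return data.frame `theta`, `tpr`, `fpr`.
#' @export
roc_sweep <- function(scores, annotations, thresholds) {
  ann <- annotations[annotations$label == "target", , drop = FALSE]
  pos <- rep(FALSE, length(scores$frame_start_s))
  for (i in seq_len(nrow(ann))) {
    pos <- pos | (scores$frame_start_s >= ann$start_s[i] &
                    scores$frame_start_s + 0.02 <= ann$end_s[i])
  }
  act <- scores$active_mask & !is.na(scores$llr)
  rows <- lapply(thresholds, function(th) {
    d <- decide(scores, th)
    data.frame(theta = th,
               tpr = sum(d & pos & act) / max(sum(pos & act), 1),
               fpr = sum(d & !pos & act) / max(sum(!pos & act), 1))
  })
  do.call(rbind, rows)
}
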