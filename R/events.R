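# Frame decisions -> timestamped call events. Two domain rules drive the
# smoothing: a call lasts at least 50 ms, and calls separated by gaps of at
# most 0.6 s belong to one call series (so cohesive sequences are detected
# as a single event and long choruses do not get more weight than single
# calls). Implemented as morphological close -> duration filter -> merge on
# the boolean frame sequence; gap lengths are measured frame-start to
# frame-start (gap_frames * hop) and event durations include the tail of the
# last frame's 20-ms window, so a single positive frame has nonzero duration.

#' Smooth per-frame decisions into detection events
#'
#' Steps: (1) positive runs separated by gaps `<= min_call` are joined
#' (fragmentation smoothing); (2) runs whose duration (`n * hop + win - hop`)
#' is below `min_call` are discarded; (3) surviving events separated by gaps
#' `<= merge_gap` are merged into one call-series event. Event timestamps run
#' from the first positive frame's start to the last positive frame's start
#' plus the window length.
#'
#' @param decisions logical vector of frame decisions (uniform hop).
#' @param frame_start_s frame start times; defaults to `hop * (0:(n-1))`.
#' @param hop frame hop, seconds.
#' @param win frame window length, seconds.
#' @param min_call minimum call duration / maximum fragmentation gap, s.
#' @param merge_gap maximum pause inside one call series, s.
#' @param llr optional per-frame score vector; events then carry `mean_llr`.
#' @param recording_id identifier copied onto the events.
#' @return data.frame with columns `recording_id`, `start_s`, `end_s`,
#'   `mean_llr`; zero rows if nothing survives.
#' @export
smooth_decisions <- function(decisions, frame_start_s = NULL, hop = 0.005,
                             win = 0.020, min_call = 0.05, merge_gap = 0.6,
                             llr = NULL, recording_id = NA_character_) {
  n <- length(decisions)
  empty <- data.frame(recording_id = character(0), start_s = numeric(0),
                      end_s = numeric(0), mean_llr = numeric(0))
  if (n == 0 || !any(decisions)) return(empty)
  if (is.null(frame_start_s)) frame_start_s <- hop * (seq_len(n) - 1)
  close_frames <- floor(min_call / hop + 1e-9)
  merge_frames <- floor(merge_gap / hop + 1e-9)

  runs <- decision_runs(decisions)
  runs <- close_gaps(runs, close_frames)
  dur <- (runs$end - runs$start) * hop + win
  runs <- runs[dur >= min_call - 1e-9, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  runs <- close_gaps(runs, merge_frames)

  mean_llr <- rep(NA_real_, nrow(runs))
  if (!is.null(llr)) {
    mean_llr <- vapply(seq_len(nrow(runs)), function(i) {
      v <- llr[runs$start[i]:runs$end[i]]
      v <- v[decisions[runs$start[i]:runs$end[i]] & !is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  data.frame(recording_id = recording_id,
             start_s = frame_start_s[runs$start],
             end_s = frame_start_s[runs$end] + win,
             mean_llr = mean_llr)
}

# start/end frame indices (1-based, inclusive) of TRUE runs
decision_runs <- function(decisions) {
  r <- rle(as.logical(decisions))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# join runs whose inter-run gap (in frames, start-to-start of the silence)
# is <= max_gap frames
close_gaps <- function(runs, max_gap) {
  if (nrow(runs) <= 1) return(runs)
  gap <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
  grp <- cumsum(c(0L, as.integer(gap > max_gap)))
  data.frame(start = tapply(runs$start, grp, min),
             end = tapply(runs$end, grp, max), row.names = NULL)
}

#' Attach absolute timestamps to events
#'
#' @param events data.frame from [smooth_decisions()].
#' @param recording_start `POSIXct` start of the recording, or a filename in
#'   the Song-Meter convention `<station>_<YYYYMMDD>_<HHMMSS>.wav` (pattern
#'   configurable).
#' @param pattern regex with three capture groups (date, time) used when
#'   `recording_start` is a filename.
#' @return `events` with an `absolute_start` POSIXct column (UTC clock).
#' @export
to_absolute <- function(events, recording_start,
                        pattern = "^(.+)_([0-9]{8})_([0-9]{6})\\.wav$") {
  if (is.character(recording_start)) {
    m <- regmatches(recording_start, regexec(pattern, basename(recording_start)))[[1]]
    if (length(m) != 4)
      stop("cannot parse recording start from '", recording_start,
           "'; expected pattern <station>_<YYYYMMDD>_<HHMMSS>.wav")
    recording_start <- as.POSIXct(paste(m[3], m[4]), format = "%Y%m%d %H%M%S",
                                  tz = "UTC")
    if (is.na(events$recording_id[1]) && nrow(events)) events$recording_id <- m[2]
  }
  events$absolute_start <- recording_start + events$start_s
  events
}

#' Write / read a detection list CSV
#'
#' Columns: `recording_id`, `start_s`, `end_s`, `absolute_start` (ISO 8601,
#' written to the second exactly as stored), `mean_llr`.
#' @param events detection data.frame (with `absolute_start`).
#' @param path CSV path.
#' @return the path / the data.frame (timestamps restored as POSIXct UTC).
#' @export
write_detections_csv <- function(events, path) {
  out <- events
  if (!is.null(out$absolute_start))
    out$absolute_start <- format(out$absolute_start, "%Y-%m-%dT%H:%M:%OS3",
                                 tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  x <- utils::read.csv(path)
  if (!is.null(x$absolute_start))
    x$absolute_start <- as.POSIXct(x$absolute_start,
                                   format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  x
}
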