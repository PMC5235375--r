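# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the smoothing reference walks runs
# explicitly, the matcher is a literal transcription of the pairing rules,
# and spectral checks go through plain stats::fft.

# naive run-length smoothing reference: close gaps <= close_frames, drop
# runs shorter than min_call (duration n*hop + win - hop), merge gaps <=
# merge_frames; returns start/end frame indices (1-based)
naive_smooth <- function(decisions, hop = 0.005, win = 0.020,
                         min_call = 0.05, merge_gap = 0.6) {
  runs <- list()
  i <- 1; n <- length(decisions)
  while (i <= n) {
    if (decisions[i]) {
      j <- i
      while (j < n && decisions[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  join <- function(runs, max_gap_frames) {
    if (length(runs) <= 1) return(runs)
    out <- list(runs[[1]])
    for (r in runs[-1]) {
      prev <- out[[length(out)]]
      if (r[1] - prev[2] - 1 <= max_gap_frames) {
        out[[length(out)]] <- c(prev[1], r[2])
      } else out[[length(out) + 1]] <- r
    }
    out
  }
  runs <- join(runs, floor(min_call / hop + 1e-9))
  runs <- Filter(function(r) (r[2] - r[1]) * hop + win >= min_call - 1e-9, runs)
  runs <- join(runs, floor(merge_gap / hop + 1e-9))
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(vapply(runs, `[`, numeric(1), 1)),
             end = as.integer(vapply(runs, `[`, numeric(1), 2)))
}

# literal interval-overlap matcher: walks detections in time order and
# applies the first-hit / double / excluded / insertion rules directly
naive_match <- function(detections, annotations) {
  ann <- annotations[order(annotations$start_s), ]
  credited <- rep(FALSE, nrow(ann))
  H <- I <- doubles <- excluded <- 0
  for (i in order(detections$start_s)) {
    overlaps <- which(pmin(detections$end_s[i], ann$end_s) -
                        pmax(detections$start_s[i], ann$start_s) > 0)
    tgt <- overlaps[ann$label[overlaps] == "target"]
    unc <- overlaps[ann$label[overlaps] == "unconfirmed"]
    if (length(tgt)) {
      if (credited[tgt[1]]) doubles <- doubles + 1
      else { credited[tgt[1]] <- TRUE; H <- H + 1 }
    } else if (length(unc)) excluded <- excluded + 1
    else I <- I + 1
  }
  list(H = H, I = I, N = sum(ann$label == "target"),
       doubles = doubles, excluded = excluded)
}

# dominant FFT peak frequencies of a clip (top n bins by magnitude, merged
# within merge_hz)
fft_peaks <- function(clip, n = 6, merge_hz = 100) {
  x <- clip$samples
  sp <- Mod(stats::fft(x))[1:(length(x) %/% 2)]
  f <- (seq_along(sp) - 1) * clip$rate_hz / length(x)
  ord <- order(sp, decreasing = TRUE)
  peaks <- numeric(0)
  for (i in ord) {
    if (!length(peaks) || all(abs(f[i] - peaks) > merge_hz)) {
      peaks <- c(peaks, f[i])
      if (length(peaks) == n) break
    }
  }
  sort(peaks)
}

# band power of a clip in [f_lo, f_hi], linear scale
band_power <- function(clip, f_lo, f_hi) {
  x <- clip$samples
  sp <- Mod(stats::fft(x))[1:(length(x) %/% 2)]^2
  f <- (seq_along(sp) - 1) * clip$rate_hz / length(x)
  sum(sp[f >= f_lo & f <= f_hi])
}

# textbook one-way ANOVA from sums of squares
textbook_anova <- function(y, g) {
  g <- factor(g)
  means <- tapply(y, g, mean); ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  df1 <- nlevels(g) - 1; df2 <- length(y) - nlevels(g)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df = c(df1, df2), p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
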