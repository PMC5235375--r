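# Performance assessment: random-sample precision and validation-library
# metrics. The four percentages are
#   precision = H / (H + I) * 100
#   accuracy  = (H - I) / N * 100
#   correct   = H / N * 100
#   missed    = (N - H) / N * 100
# with H hits, I insertions (false positives), N confirmed target events.
# Detections that repeat an already-credited annotation are "double hits"
# (excluded from H and I); detections overlapping only unconfirmed
# annotations are excluded from the valid sample entirely.

#' Round a percentage half-up to one decimal
#'
#' Validation tables in this workflow are reported to one decimal with
#' half-up rounding (35.78 -> 35.8, 0.65 -> 0.7), not banker's rounding.
#' @param x numeric.
#' @return numeric rounded half-up to 1 decimal.
#' @export
round_pct <- function(x) floor(x * 10 + 0.5) / 10

#' Validation sample size for a month of detections
#'
#' At least 150 assessed detections for low-activity months, 2 percent of
#' all detections for high-activity months, capped at the number available:
#' `min(D, max(150, round(0.02 * D)))`.
#'
#' @param monthly_detections detection count (>= 0).
#' @return sample size.
#' @export
sample_size <- function(monthly_detections) {
  stopifnot(monthly_detections >= 0)
  pmin(monthly_detections, pmax(150, round(0.02 * monthly_detections)))
}

#' Draw a reproducible uniform random sample of detections
#'
#' @param detections data.frame of detections.
#' @param n sample size (<= rows of `detections`).
#' @param seed integer seed.
#' @return the sampled subset (original order preserved).
#' @export
draw_sample <- function(detections, n, seed) {
  if (n > nrow(detections))
    stop("sample size ", n, " exceeds the ", nrow(detections), " detections")
  idx <- withr::with_seed(seed, sort(sample.int(nrow(detections), n)))
  detections[idx, , drop = FALSE]
}

#' Match detections against expert annotations
#'
#' A detection overlapping at least one annotated target event is a hit if
#' it is the first detection to overlap that event, otherwise a double hit.
#' A detection overlapping no target or unconfirmed annotation is an
#' insertion. A detection overlapping only unconfirmed annotations is
#' excluded from the valid sample. A detection spanning several annotations
#' is credited to the earliest. Overlap means temporal intersection longer
#' than `min_overlap` seconds (default 0: any positive intersection).
#'
#' @param detections data.frame with `start_s`, `end_s`, sorted by start.
#' @param annotations data.frame with `start_s`, `end_s`, `label` in
#'   `{"target", "unconfirmed", "nontarget"}`.
#' @param min_overlap minimum overlap in seconds to count as intersection.
#' @return a `validation_summary` list: `H`, `I`, `N`, `doubles`,
#'   `excluded`, `misses`, and `matched` (per-detection verdict vector).
#' @export
match_events <- function(detections, annotations, min_overlap = 0) {
  ann <- annotations[order(annotations$start_s), , drop = FALSE]
  tgt <- which(ann$label == "target")
  unc <- which(ann$label == "unconfirmed")
  n_det <- nrow(detections)
  verdict <- character(n_det)
  credited <- rep(FALSE, nrow(ann))
  ord <- order(detections$start_s)
  for (i in ord) {
    ds <- detections$start_s[i]; de <- detections$end_s[i]
    ov <- pmin(de, ann$end_s) - pmax(ds, ann$start_s)
    hit_t <- tgt[ov[tgt] > min_overlap]
    if (length(hit_t)) {
      first <- hit_t[1]  # earliest annotation gets the credit
      if (credited[first]) {
        verdict[i] <- "double"
      } else {
        credited[first] <- TRUE
        verdict[i] <- "hit"
      }
    } else if (length(unc[ov[unc] > min_overlap])) {
      verdict[i] <- "excluded"
    } else {
      verdict[i] <- "insertion"
    }
  }
  H <- sum(verdict == "hit"); I <- sum(verdict == "insertion")
  N <- length(tgt)
  structure(list(H = H, I = I, N = N,
                 doubles = sum(verdict == "double"),
                 excluded = sum(verdict == "excluded"),
                 misses = N - H, matched = verdict),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("<validation_summary> H=%d I=%d N=%d doubles=%d excluded=%d\n",
              x$H, x$I, x$N, x$doubles, x$excluded))
  invisible(x)
}

#' Detection performance percentages
#'
#' @param H hits (true positives).
#' @param I insertions (false positives).
#' @param N total confirmed target events.
#' @return percentage, rounded half-up to 1 decimal.
#' @export
precision_pct <- function(H, I) {
  if (H + I <= 0) stop("precision undefined: H + I = 0")
  round_pct(H / (H + I) * 100)
}

#' @rdname precision_pct
#' @export
accuracy_pct <- function(H, I, N) {
  if (N <= 0) stop("accuracy undefined: N = 0")
  round_pct((H - I) / N * 100)
}

#' @rdname precision_pct
#' @export
correct_pct <- function(H, N) {
  if (N <= 0) stop("correct undefined: N = 0")
  round_pct(H / N * 100)
}

#' @rdname precision_pct
#' @export
missed_pct <- function(H, N) {
  if (N <= 0) stop("missed undefined: N = 0")
  round_pct((N - H) / N * 100)
}

#' Cumulative amplitude table of annotated events
#'
#' Bins annotated events by the loudest-call peak level into 5-dB
#' categories (`(-5, 0]`, `(-10, -5]`, ...; events below the last finite
#' edge fall into a bottom catch-all bin) and accumulates them into
#' "0 to -X" rows with the percentage of unconfirmed events per row
#' (1 decimal, half-up; `NA` when a row is empty).
#'
#' @param events data.frame with `peak_dbfs` (<= 0) and `label` in
#'   `{"target", "unconfirmed"}` (other labels are ignored).
#' @param bin_width bin width in dB.
#' @param floor_db last finite bin edge (default -50).
#' @return data.frame `range`, `n_target`, `n_unconfirmed`, `n_total`,
#'   `pct_unconfirmed`, one row per cumulative range plus a final
#'   "0 to -Inf" row.
#' @export
bin_by_db <- function(events, bin_width = 5, floor_db = -50) {
  ev <- events[events$label %in% c("target", "unconfirmed"), , drop = FALSE]
  if (any(ev$peak_dbfs > 0)) stop("peak_dbfs must be <= 0 dBFS")
  n_bins <- ceiling(-floor_db / bin_width)
  idx <- pmax(1, ceiling(-ev$peak_dbfs / bin_width))
  idx[!is.finite(ev$peak_dbfs) | idx > n_bins] <- n_bins + 1  # below floor
  tab <- function(lab) {
    counts <- tabulate(idx[ev$label == lab], nbins = n_bins + 1)
    counts
  }
  nt <- tab("target"); nu <- tab("unconfirmed")
  edges <- -bin_width * seq_len(n_bins)
  cum_t <- cumsum(nt); cum_u <- cumsum(nu)
  total <- cum_t + cum_u
  pct <- ifelse(total > 0, round_pct(cum_u / total * 100), NA_real_)
  data.frame(
    range = c(paste0("0 to ", edges), "0 to -Inf"),
    n_target = cum_t, n_unconfirmed = cum_u, n_total = total,
    pct_unconfirmed = pct)
}

#' Full validation report
#'
#' Convenience wrapper computing all four metrics from a
#' `validation_summary`.
#' @param summary result of [match_events()].
#' @return data.frame with H, I, N, doubles, excluded and the four
#'   percentages.
#' @export
validation_report <- function(summary) {
  data.frame(H = summary$H, I = summary$I, N = summary$N,
             doubles = summary$doubles, excluded = summary$excluded,
             precision = precision_pct(summary$H, summary$I),
             accuracy = accuracy_pct(summary$H, summary$I, summary$N),
             correct = correct_pct(summary$H, summary$N),
             missed = missed_pct(summary$H, summary$N))
}
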