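# Bundled example tallies from a 12-month Southern Lapwing monitoring
# campaign at a Pantanal recording station (season April-September 2013):
# the per-period day/night detection counts with their sampled validation
# verdicts, and the validation-library amplitude table. They let the
# correction and binning arithmetic be exercised (and demonstrated) without
# any audio.

#' Example activity periods with sampled validation verdicts
#'
#' Eight acoustic activity periods covering April-September 2013 at a
#' Pantanal station: raw daytime/nighttime detection counts of a lapwing
#' call recognizer and, per period, the number of sampled detections judged
#' correct, false, or excluded as ambiguous by a bird-sound expert.
#'
#' @return an [activity_table()] with 8 rows.
#' @export
lapwing_periods <- function() {
  p <- utils::read.csv(system.file("extdata", "pantanal_periods_2013.csv",
                                   package = "quero"))
  activity_table(p$id, p$start_date, p$end_date, p$raw_day, p$raw_night,
                 p$n_correct, p$n_false, p$n_excluded)
}

#' Example validation-library amplitude bins
#'
#' Counts of expert-confirmed target and unconfirmed call events per 5-dB
#' amplitude category (loudest call, dBFS) from 26 annotated 14-min
#' soundscapes; the bottom row collects events below -50 dBFS.
#'
#' @return data.frame `bin_top_db`, `bin_bottom_db`, `n_target`,
#'   `n_unconfirmed`.
#' @export
lapwing_validation_bins <- function() {
  utils::read.csv(system.file("extdata", "pantanal_validation_bins_2013.csv",
                              package = "quero"))
}

#' Expand binned validation counts into per-event rows
#'
#' Places each counted event at its bin midpoint (events in the bottom,
#' unbounded bin get `-Inf`), producing an event table [bin_by_db()] can
#' consume; binning the expansion reproduces the source table.
#'
#' @param bins data.frame as returned by [lapwing_validation_bins()].
#' @return data.frame `peak_dbfs`, `label`.
#' @export
expand_db_bins <- function(bins) {
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    bot <- suppressWarnings(as.numeric(bins$bin_bottom_db[i]))
    mid <- if (is.finite(bot)) (bins$bin_top_db[i] + bot) / 2 else -Inf
    data.frame(
      peak_dbfs = rep(mid, bins$n_target[i] + bins$n_unconfirmed[i]),
      label = rep(c("target", "unconfirmed"),
                  c(bins$n_target[i], bins$n_unconfirmed[i])))
  })
  do.call(rbind, rows)
}

#' Estimate the hatching date from a daily activity series
#'
#' Hatching shows as the largest *sustained* jump of the `window`-day
#' smoothed counts: for each candidate day the mean of the following
#' `window` days is compared with the mean of the preceding `window` days
#' (equivalently, the smoothed series evaluated just after versus just
#' before the day), and the day with the largest rise is returned. Comparing
#' block means rather than single-day differences separates a one-day step
#' (hatching) from the more gradual build-up of defence activity during
#' early incubation. A descriptive heuristic used for synthetic parameter
#' recovery, not a formal change-point model.
#'
#' @param daily data.frame `date` and either `total` or
#'   `corrected_day`/`corrected_night`.
#' @param window block length, days (odd).
#' @return a `Date`: the first day of the elevated block.
#' @export
estimate_hatch_date <- function(daily, window = 5) {
  stopifnot(window %% 2 == 1)
  tot <- if (!is.null(daily$total)) daily$total
    else daily$corrected_day + daily$corrected_night
  n <- length(tot)
  if (n < 2 * window + 1) stop("series too short")
  cand <- (window + 1):(n - window + 1)
  jump <- vapply(cand, function(t)
    mean(tot[t:(t + window - 1)]) - mean(tot[(t - window):(t - 1)]),
    numeric(1))
  daily$date[cand[which.max(jump)]]
}
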