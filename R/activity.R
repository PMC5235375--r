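# Phenology analysis of detection streams: day/night partition relative to
# sunrise/sunset, false-positive correction of period counts by sampled
# precision, daily and diel activity profiles, and the two inferential
# tests (water-level rank correlation, lunar-phase ANOVA with Tukey HSD).

#' Build an activity-period table
#'
#' One row per acoustic activity period (a date range with an approximately
#' homogeneous false-positive rate): raw day/night detection counts plus the
#' verdicts of the assessed random sample (correct / false / excluded).
#'
#' @param id period identifiers.
#' @param start_date,end_date inclusive date ranges (`Date` or string).
#' @param raw_day,raw_night raw detection counts.
#' @param n_correct,n_false,n_excluded sampled verdict counts.
#' @return data.frame of class `activity_table`.
#' @export
activity_table <- function(id, start_date, end_date, raw_day, raw_night,
                           n_correct, n_false, n_excluded = 0) {
  df <- data.frame(id = id, start_date = as.Date(start_date),
                   end_date = as.Date(end_date),
                   raw_day = raw_day, raw_night = raw_night,
                   n_correct = n_correct, n_false = n_false,
                   n_excluded = n_excluded)
  stopifnot(all(df$end_date >= df$start_date),
            all(df$n_correct + df$n_false > 0))
  class(df) <- c("activity_table", "data.frame")
  df
}

#' Per-period precision from sampled verdicts
#'
#' `n_correct / (n_correct + n_false) * 100`, half-up to 1 decimal.
#' @param periods an [activity_table()].
#' @return numeric vector of percentages.
#' @export
period_precision <- function(periods) {
  n_valid <- periods$n_correct + periods$n_false
  if (any(n_valid == 0)) stop("period with no valid sampled detections")
  round_pct(periods$n_correct / n_valid * 100)
}

#' Correct raw day/night counts by sampled precision
#'
#' `corrected = raw * n_correct / n_valid`, kept unrounded internally;
#' display values round half-up to integers. Totals are computed by summing
#' the unrounded per-period values and rounding the sum (so the grand total
#' is consistent, not a sum of rounded cells).
#'
#' @param periods an [activity_table()].
#' @return `periods` with columns `precision_pct`, `corrected_day`,
#'   `corrected_night` (unrounded) added.
#' @export
correct_counts <- function(periods) {
  frac <- periods$n_correct / (periods$n_correct + periods$n_false)
  periods$precision_pct <- period_precision(periods)
  periods$corrected_day <- periods$raw_day * frac
  periods$corrected_night <- periods$raw_night * frac
  periods
}

round_half_up <- function(x) floor(x + 0.5)

#' Render the corrected activity table with display rounding and totals
#'
#' @param periods an [activity_table()].
#' @return data.frame: one row per period plus a `total` row; corrected
#'   counts rounded half-up, precision to 1 decimal. The total row's
#'   precision pools all sampled verdicts; its corrected counts round the
#'   sums of unrounded values.
#' @export
activity_report <- function(periods) {
  cc <- correct_counts(periods)
  out <- data.frame(
    id = as.character(cc$id),
    raw_day = cc$raw_day, raw_night = cc$raw_night,
    raw_total = cc$raw_day + cc$raw_night,
    n_sampled = cc$n_correct + cc$n_false + cc$n_excluded,
    n_correct = cc$n_correct, n_false = cc$n_false,
    n_excluded = cc$n_excluded,
    n_valid = cc$n_correct + cc$n_false,
    precision_pct = cc$precision_pct,
    corrected_day = round_half_up(cc$corrected_day),
    corrected_night = round_half_up(cc$corrected_night),
    corrected_total = round_half_up(cc$corrected_day + cc$corrected_night))
  tot <- data.frame(
    id = "total",
    raw_day = sum(cc$raw_day), raw_night = sum(cc$raw_night),
    raw_total = sum(cc$raw_day + cc$raw_night),
    n_sampled = sum(out$n_sampled), n_correct = sum(cc$n_correct),
    n_false = sum(cc$n_false), n_excluded = sum(cc$n_excluded),
    n_valid = sum(out$n_valid),
    precision_pct = round_pct(sum(cc$n_correct) / sum(out$n_valid) * 100),
    corrected_day = round_half_up(sum(cc$corrected_day)),
    corrected_night = round_half_up(sum(cc$corrected_night)),
    corrected_total = round_half_up(sum(cc$corrected_day + cc$corrected_night)))
  rbind(out, tot)
}

#' Classify event timestamps as day or night
#'
#' "Day" is the extended daylight window from one hour before sunrise to 45
#' minutes after sunset (closed interval), so the dawn and dusk activity
#' peaks count as daytime.
#'
#' @param times POSIXct event times on the station clock.
#' @param solar a [solar_context()].
#' @return character vector `"day"` / `"night"`.
#' @export
classify_day_night <- function(times, solar) {
  dates <- as.Date(times, tz = "UTC")
  st <- sun_times(solar, unique(dates))
  i <- match(dates, st$date)
  if (anyNA(i)) stop("missing solar data for some event dates")
  day <- times >= (st$sunrise[i] - 3600) & times <= (st$sunset[i] + 45 * 60)
  ifelse(day, "day", "night")
}

#' Per-date corrected day/night counts
#'
#' Counts events per date and day/night class, scaled by the precision
#' fraction of the owning activity period (period date ranges are inclusive
#' of both ends).
#'
#' @param times POSIXct event times.
#' @param periods an [activity_table()].
#' @param solar a [solar_context()].
#' @return data.frame `date`, `corrected_day`, `corrected_night` (unrounded),
#'   one row per date in the period range (zero-count dates included).
#' @export
daily_series <- function(times, periods, solar) {
  dates <- as.Date(times, tz = "UTC")
  all_dates <- seq(min(periods$start_date), max(periods$end_date), by = 1)
  pidx <- vapply(as.numeric(all_dates), function(d) {
    w <- which(d >= as.numeric(periods$start_date) &
                 d <= as.numeric(periods$end_date))
    if (length(w) == 0) NA_integer_ else w[1]
  }, integer(1))
  if (anyNA(pidx)) {
    gaps <- all_dates[is.na(pidx)]
    stop("dates outside all activity periods: ",
         paste(utils::head(gaps, 5), collapse = ", "))
  }
  ev_idx <- match(dates, all_dates)
  if (anyNA(ev_idx)) stop("event dates outside the period table")
  dn <- classify_day_night(times, solar)
  frac <- (periods$n_correct / (periods$n_correct + periods$n_false))[pidx]
  cd <- tabulate(ev_idx[dn == "day"], nbins = length(all_dates)) * frac
  cn <- tabulate(ev_idx[dn == "night"], nbins = length(all_dates)) * frac
  data.frame(date = all_dates, corrected_day = cd, corrected_night = cn)
}

#' Diel activity profile
#'
#' Histogram of detections over the 24-h clock at hourly or quarter-hourly
#' resolution; optionally normalised so the maximum bin reads 100 percent.
#'
#' @param times POSIXct event times on the station clock.
#' @param resolution `"hour"` or `"quarter_hour"`.
#' @param normalize express bins as percent of the maximum bin.
#' @return data.frame `bin_start_h`, `count` (and `pct_of_max` if
#'   normalised).
#' @export
diel_profile <- function(times, resolution = c("hour", "quarter_hour"),
                         normalize = FALSE) {
  resolution <- match.arg(resolution)
  width <- if (resolution == "hour") 1 else 0.25
  h <- as.numeric(times - as.POSIXct(paste(as.Date(times, tz = "UTC"),
                                           "00:00:00"), tz = "UTC"),
                  units = "hours")
  bins <- seq(0, 24 - width, by = width)
  idx <- pmin(floor(h / width) + 1, length(bins))
  out <- data.frame(bin_start_h = bins,
                    count = tabulate(idx, nbins = length(bins)))
  if (normalize) {
    mx <- max(out$count)
    out$pct_of_max <- if (mx > 0) out$count / mx * 100 else NA_real_
  }
  out
}

# ---- statistics -------------------------------------------------------------

#' One-tailed Spearman rank correlation (negative alternative)
#'
#' Rank correlation with average ranks for ties. The p-value is for the
#' alternative "rho < 0": exact by full enumeration of rank permutations for
#' n <= 10 without ties, otherwise the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.
#'
#' @param x,y numeric vectors of equal length (n >= 4); in the water-level
#'   use case `x` is the water level (cm) and `y` the 5-day average of
#'   corrected detections.
#' @return list `rho`, `p`, `method`.
#' @export
spearman_one_tailed <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!ties && n <= 10) {
    d_obs <- sum((rx - ry)^2)
    p <- spearman_exact_p_cpp(n, d_obs)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- stats::pt(tstat, df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, method = method)
}

#' Pair water-level readings with windowed activity averages
#'
#' For each water-level reading, averages the corrected daily totals over a
#' `window`-day window centred on the reading date (the alignment used for
#' the flood-suppression correlation test).
#'
#' @param water data.frame `date`, `cm`.
#' @param daily data.frame `date`, `corrected_day`, `corrected_night` (or a
#'   `total` column).
#' @param window window length in days (odd; centred).
#' @return data.frame `date`, `cm`, `activity`.
#' @export
pair_water_activity <- function(water, daily, window = 5) {
  stopifnot(window %% 2 == 1)
  half <- (window - 1) / 2
  tot <- if (!is.null(daily$total)) daily$total
    else daily$corrected_day + daily$corrected_night
  act <- vapply(as.Date(water$date), function(d) {
    sel <- daily$date >= d - half & daily$date <= d + half
    if (!any(sel)) NA_real_ else mean(tot[sel])
  }, numeric(1))
  data.frame(date = as.Date(water$date), cm = water$cm, activity = act)
}

#' Group nights by lunar phase
#'
#' Forms three samples of `nights_per_group` consecutive nights centred on
#' (a) the new moon preceding the full moon under test, (b) the full moon,
#' and (c) the following new moon; the nights around the quarter moons fall
#' between the groups and are excluded, keeping the groups disjoint.
#'
#' @param dates available nights (`Date`), spanning at least one synodic
#'   month around the full moon of interest.
#' @param nights_per_group nights per sample (default 13).
#' @return data.frame `date`, `group` in `{"new_A", "full", "new_B"}`.
#' @export
lunar_groups <- function(dates, nights_per_group = 13) {
  dates <- sort(as.Date(dates))
  age <- lunar_age(dates)
  full_i <- which.min(abs(age - SYNODIC_MONTH / 2))
  full_d <- dates[full_i]
  # nearest new moons before and after, from the synodic cycle
  k <- (as.numeric(full_d) + 0.5 - NEW_MOON_EPOCH) / SYNODIC_MONTH
  new_a <- as.Date(round(NEW_MOON_EPOCH + floor(k) * SYNODIC_MONTH))
  new_b <- as.Date(round(NEW_MOON_EPOCH + ceiling(k) * SYNODIC_MONTH))
  half <- (nights_per_group - 1) %/% 2
  take <- function(center, label) {
    span <- seq(center - half, center + (nights_per_group - 1 - half), by = 1)
    if (!all(span %in% dates))
      stop("insufficient nights around ", format(center), " for group ", label)
    data.frame(date = span, group = label)
  }
  g <- rbind(take(new_a, "new_A"), take(full_d, "full"), take(new_b, "new_B"))
  if (anyDuplicated(g$date)) stop("lunar groups overlap; too few nights between phases")
  g
}

#' One-way ANOVA with Tukey HSD on lunar night groups
#'
#' Nightly counts are `log10(x + 1)`-transformed (the +1 guards zero-count
#' nights), then a one-way ANOVA across the three lunar groups is computed,
#' followed by pairwise Tukey honestly-significant-difference comparisons
#' using the studentized-range distribution at `alpha`.
#'
#' @param groups data.frame `date`, `group` from [lunar_groups()].
#' @param nightly_counts data.frame `date`, `count` of nocturnal detections.
#' @param alpha significance level for the Tukey table (default 0.01).
#' @return list `F`, `df` (c(between, within)), `p`, `group_means` (on the
#'   log scale), `tukey` (data.frame comparison/diff/q/p_adj/significant).
#' @export
lunar_anova <- function(groups, nightly_counts, alpha = 0.01) {
  m <- merge(groups, nightly_counts, by = "date")
  if (nrow(m) < nrow(groups))
    warning("dropping ", nrow(groups) - nrow(m), " night(s) with no count data")
  y <- log10(m$count + 1)
  g <- factor(m$group)
  k <- nlevels(g); n <- length(y)
  means <- tapply(y, g, mean); ns <- tapply(y, g, length)
  gm <- mean(y)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- k - 1; df2 <- n - k
  if (ssw == 0) stop("zero within-group variance in all groups")
  msb <- ssb / df1; msw <- ssw / df2
  f <- msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  cmb <- utils::combn(levels(g), 2)
  tk <- apply(cmb, 2, function(pr) {
    d <- means[pr[1]] - means[pr[2]]
    se <- sqrt(msw / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(d) / se
    data.frame(comparison = paste(pr[1], "-", pr[2]), diff = unname(d),
               q = unname(q),
               p_adj = stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE))
  })
  tk <- do.call(rbind, tk)
  tk$significant <- tk$p_adj < alpha
  list(F = f, df = c(df1, df2), p = p,
       group_means = means, tukey = tk)
}
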