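# Seasonal detection-count simulator. It generates per-quarter-hour Poisson
# counts whose daily intensity follows the life-cycle phase structure of a
# breeding season in a seasonally flooded wetland: suppressed calling while
# the territory is inundated, a stable territorial level as waters recede, a
# slight dip around egg-laying, a ramp through incubation, a sudden step at
# hatching, a high plateau while chicks are tended, a slow decay, and a
# post-breeding minimum. Nocturnal intensity is boosted on moonlit nights,
# and an independent Poisson stream of false positives with phase-specific
# rates contaminates the counts, so the downstream correction machinery has
# something honest to correct.

PHASE_NAMES <- c("flood_low", "territory", "laying_dip", "incubation_ramp",
                 "hatch_step", "tending_plateau", "decay", "post_breeding")

#' Specification of a simulated detection season
#'
#' Defaults describe a season patterned on a 2013 Pantanal breeding cycle:
#' phase mean rates of 19, 110, 90, 467, 766, 489, 220 and 43 events/day
#' (the hatch-step rate is `incubation_ramp * (1 + hatch_step_fraction)`,
#' 467 * 1.64 = 766), an April-September window, and false-positive
#' fractions per phase mirroring the wide seasonal swing of recognizer
#' precision (high contamination during the flood and post-breeding, low at
#' the activity peak).
#'
#' @param start_date,end_date season window (`Date` or string), inclusive.
#' @param phase_boundaries named `Date` vector: the first date of each of the
#'   eight phases, strictly increasing, names as in `PHASE_NAMES`.
#' @param phase_mean_rates named numeric vector of true call events/day for
#'   the seven free phases (the `hatch_step` rate is derived).
#' @param hatch_step_fraction relative jump of daily rate at hatching
#'   (default 0.64, i.e. +64 percent over the incubation plateau).
#' @param fp_rate_by_phase named numeric vector, fraction of all detections
#'   in the phase that are false positives (0 <= r < 1).
#' @param diel_profile named character vector, `"two_peak"` or `"all_day"`
#'   per phase.
#' @param territory_ramp_days days over which the daily rate climbs linearly
#'   from the flood minimum to the territorial level, ending at the
#'   `territory` boundary (lapwings resume patrolling while waters are still
#'   receding).
#' @param incubation_ramp_days days over which the rate climbs linearly from
#'   the laying dip to the incubation plateau at the start of the
#'   `incubation_ramp` phase (defence builds up over the first week or so of
#'   incubation); all other phase transitions are steps.
#' @param lunar_night_multiplier factor >= 1 applied to nocturnal intensity
#'   on moonlit nights.
#' @param water_level_curve data.frame `date`, `cm`: the receding flood.
#' @param solar a [solar_context()]; defaults to the Pantanal station.
#' @param seed integer master seed.
#' @return a `season_spec` object.
#' @export
season_spec <- function(
    start_date = "2013-04-01", end_date = "2013-09-30",
    phase_boundaries = as.Date(c(
      flood_low = "2013-04-01", territory = "2013-04-26",
      laying_dip = "2013-05-11", incubation_ramp = "2013-05-21",
      hatch_step = "2013-06-13", tending_plateau = "2013-06-29",
      decay = "2013-07-09", post_breeding = "2013-09-01")),
    phase_mean_rates = c(
      flood_low = 19, territory = 110, laying_dip = 90,
      incubation_ramp = 467, tending_plateau = 489, decay = 220,
      post_breeding = 43),
    hatch_step_fraction = 0.64,
    fp_rate_by_phase = c(
      flood_low = 0.642, territory = 0.29, laying_dip = 0.29,
      incubation_ramp = 0.177, hatch_step = 0.065, tending_plateau = 0.05,
      decay = 0.059, post_breeding = 0.313),
    diel_profile = c(
      flood_low = "two_peak", territory = "two_peak", laying_dip = "two_peak",
      incubation_ramp = "two_peak", hatch_step = "all_day",
      tending_plateau = "all_day", decay = "all_day",
      post_breeding = "two_peak"),
    territory_ramp_days = 8,
    incubation_ramp_days = 8,
    lunar_night_multiplier = 2,
    water_level_curve = data.frame(
      date = seq(as.Date("2013-04-01"), by = 7, length.out = 11),
      cm = c(42, 38, 33, 28, 23, 18, 13, 9, 5, 2, 0)),
    solar = solar_context(-16.50303, -56.74533, -4),
    seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  stopifnot(identical(names(phase_boundaries), PHASE_NAMES),
            all(diff(as.numeric(phase_boundaries)) > 0),
            all(phase_mean_rates >= 0),
            all(fp_rate_by_phase >= 0 & fp_rate_by_phase < 1),
            lunar_night_multiplier >= 1,
            hatch_step_fraction >= 0)
  rates <- numeric(8); names(rates) <- PHASE_NAMES
  rates[names(phase_mean_rates)] <- phase_mean_rates
  rates["hatch_step"] <- rates["incubation_ramp"] * (1 + hatch_step_fraction)
  structure(list(start_date = start_date, end_date = end_date,
                 phase_boundaries = phase_boundaries,
                 phase_mean_rates = rates,
                 hatch_step_fraction = hatch_step_fraction,
                 territory_ramp_days = territory_ramp_days,
                 incubation_ramp_days = incubation_ramp_days,
                 fp_rate_by_phase = fp_rate_by_phase[PHASE_NAMES],
                 diel_profile = diel_profile[PHASE_NAMES],
                 lunar_night_multiplier = lunar_night_multiplier,
                 water_level_curve = water_level_curve,
                 solar = solar, seed = as.integer(seed)),
            class = "season_spec")
}

#' Phase owning each date
#' @param spec a [season_spec()].
#' @param dates `Date` vector within the season.
#' @return character vector of phase names.
#' @export
season_phase_of <- function(spec, dates) {
  dates <- as.Date(dates)
  idx <- findInterval(as.numeric(dates), as.numeric(spec$phase_boundaries))
  if (any(idx < 1)) stop("date before the season start")
  PHASE_NAMES[idx]
}

#' Deterministic daily intensity of a season specification
#'
#' The piecewise daily rate before diel spreading and lunar modulation:
#' constant at each phase's mean, except for the linear climb into the
#' `territory` phase (over `territory_ramp_days`, ending at the boundary)
#' and the linear climb at the start of the `incubation_ramp` phase (over
#' `incubation_ramp_days`). The hatch-day transition and all remaining
#' boundaries are steps.
#'
#' @param spec a [season_spec()].
#' @param dates `Date` vector.
#' @return numeric vector of expected true events/day.
#' @export
season_daily_rate <- function(spec, dates) {
  dates <- as.Date(dates)
  ph <- season_phase_of(spec, dates)
  r <- unname(spec$phase_mean_rates[ph])
  b <- spec$phase_boundaries
  # climb into territory establishment (late flood phase)
  t0 <- b[["territory"]] - spec$territory_ramp_days
  sel <- dates >= t0 & dates < b[["territory"]]
  if (any(sel)) {
    f <- as.numeric(dates[sel] - t0) / spec$territory_ramp_days
    r[sel] <- spec$phase_mean_rates[["flood_low"]] * (1 - f) +
      spec$phase_mean_rates[["territory"]] * f
  }
  # climb out of the laying dip to the incubation plateau
  i0 <- b[["incubation_ramp"]]
  sel <- dates >= i0 & dates < i0 + spec$incubation_ramp_days
  if (any(sel)) {
    f <- as.numeric(dates[sel] - i0 + 1) / spec$incubation_ramp_days
    r[sel] <- spec$phase_mean_rates[["laying_dip"]] * (1 - f) +
      spec$phase_mean_rates[["incubation_ramp"]] * f
  }
  r
}

# quarter-hour weights (length 96, summing to 1 over the unscaled day) plus
# night flags for one date
diel_weights <- function(profile, sunrise_h, sunset_h) {
  tc <- (0:95) / 4 + 0.125  # bin centres in hours
  g <- function(mu) exp(-(tc - mu)^2 / (2 * 0.75^2))
  floor_w <- 0.02
  w <- floor_w + g(sunrise_h) + g(sunset_h)
  if (profile == "all_day") {
    day <- tc > sunrise_h & tc < sunset_h
    w[day] <- pmax(w[day], 0.8)
  }
  w / sum(w)
}

#' Simulate a season of quarter-hour detection counts
#'
#' For each date, the phase's mean daily rate is spread over the 96
#' quarter-hours of the day according to the phase's diel profile (two-peak:
#' dawn/dusk Gaussian peaks over a near-zero floor; all-day: the same peaks
#' over a sustained daytime floor at 44 percent of the peak). Night bins (the
#' complement of the sunrise - 1 h to sunset + 45 min day window) are
#' multiplied by `lunar_night_multiplier` on moonlit nights, which raises
#' that day's expected total. True counts and false positives are independent
#' Poisson draws; the false-positive intensity is
#' `rate * fp / (1 - fp)` of the phase's true intensity, spread uniformly
#' over the day. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [season_spec()].
#' @return data.frame with one row per date x quarter-hour: `date`,
#'   `quarter_hour_index` (0-95), `true_count`, `fp_count`, `night_flag`.
#' @export
simulate_season <- function(spec) {
  dates <- seq(spec$start_date, spec$end_date, by = 1)
  phases <- season_phase_of(spec, dates)
  sun <- sun_times(spec$solar, dates)
  sunrise_h <- as.numeric(sun$sunrise - as.POSIXct(paste(dates, "00:00:00"),
                                                   tz = "UTC"), units = "hours")
  sunset_h <- as.numeric(sun$sunset - as.POSIXct(paste(dates, "00:00:00"),
                                                  tz = "UTC"), units = "hours")
  moonlit <- is_moonlit(dates)
  rate <- season_daily_rate(spec, dates)
  withr::with_seed(spec$seed, {
    out <- vector("list", length(dates))
    tc <- (0:95) / 4 + 0.125
    for (i in seq_along(dates)) {
      ph <- phases[i]
      w <- diel_weights(spec$diel_profile[[ph]], sunrise_h[i], sunset_h[i])
      night <- !(tc >= sunrise_h[i] - 1 & tc <= sunset_h[i] + 0.75)
      lam <- rate[i] * w
      if (moonlit[i]) lam[night] <- lam[night] * spec$lunar_night_multiplier
      r <- spec$fp_rate_by_phase[[ph]]
      lam_fp <- rate[i] * r / (1 - r) / 96
      out[[i]] <- data.frame(
        date = dates[i], quarter_hour_index = 0:95,
        true_count = stats::rpois(96, lam),
        fp_count = stats::rpois(96, lam_fp),
        night_flag = night)
    }
    do.call(rbind, out)
  })
}

#' Expected daily totals of a season specification
#'
#' The analytic mean of `true_count` summed per day, including the moonlit-
#' night inflation, used as the injected truth in parameter-recovery checks.
#'
#' @param spec a [season_spec()].
#' @return data.frame `date`, `phase`, `expected_true` (events/day).
#' @export
season_expected_daily <- function(spec) {
  dates <- seq(spec$start_date, spec$end_date, by = 1)
  phases <- season_phase_of(spec, dates)
  sun <- sun_times(spec$solar, dates)
  sunrise_h <- as.numeric(sun$sunrise - as.POSIXct(paste(dates, "00:00:00"),
                                                   tz = "UTC"), units = "hours")
  sunset_h <- as.numeric(sun$sunset - as.POSIXct(paste(dates, "00:00:00"),
                                                  tz = "UTC"), units = "hours")
  moonlit <- is_moonlit(dates)
  rate <- season_daily_rate(spec, dates)
  tc <- (0:95) / 4 + 0.125
  exp_true <- vapply(seq_along(dates), function(i) {
    ph <- phases[i]
    w <- diel_weights(spec$diel_profile[[ph]], sunrise_h[i], sunset_h[i])
    night <- !(tc >= sunrise_h[i] - 1 & tc <= sunset_h[i] + 0.75)
    lam <- rate[i] * w
    if (moonlit[i]) lam[night] <- lam[night] * spec$lunar_night_multiplier
    sum(lam)
  }, numeric(1))
  data.frame(date = dates, phase = phases, expected_true = exp_true)
}

#' Write / read a simulated season as CSV
#'
#' Columns: `date` (ISO 8601), `quarter_hour_index` (0-95), `true_count`,
#' `fp_count`, `night_flag`.
#' @param season data.frame from [simulate_season()].
#' @param path CSV path.
#' @return the path ([write_season_csv()]) or the data.frame
#'   ([read_season_csv()]).
#' @export
write_season_csv <- function(season, path) {
  utils::write.csv(season, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_season_csv
#' @export
read_season_csv <- function(path) {
  x <- utils::read.csv(path)
  x$date <- as.Date(x$date)
  x$night_flag <- as.logical(x$night_flag)
  x
}
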