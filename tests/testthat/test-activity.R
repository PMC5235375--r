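station <- solar_context(-16.50303, -56.74533, -4)

test_that("sunrise and sunset land where the tropics put them", {
  st <- sun_times(station, as.Date(c("2013-06-21", "2013-03-21")))
  # winter solstice at 16.5 S: sunrise a bit after 06:00, sunset before 18:00
  h <- function(t, d) as.numeric(t - as.POSIXct(paste(d, "00:00:00"),
                                                tz = "UTC"), units = "hours")
  expect_gt(h(st$sunrise[1], st$date[1]), 5.9)
  expect_lt(h(st$sunrise[1], st$date[1]), 6.6)
  expect_gt(h(st$sunset[1], st$date[1]), 17.0)
  expect_lt(h(st$sunset[1], st$date[1]), 17.8)
  # near the equinox the day is ~12 h
  expect_equal(h(st$sunset[2], st$date[2]) - h(st$sunrise[2], st$date[2]),
               12, tolerance = 0.25)
  expect_true(all(st$sunrise < st$sunset))
})

test_that("day/night classification uses the extended daylight window", {
  st <- sun_times(station, as.Date("2013-06-15"))
  expect_equal(classify_day_night(st$sunrise - 30 * 60, station), "day")
  expect_equal(classify_day_night(st$sunrise - 90 * 60, station), "night")
  expect_equal(classify_day_night(st$sunset + 3600, station), "night")
  # boundary: sunset + 45 min exactly is still day (closed interval)
  expect_equal(classify_day_night(st$sunset + 45 * 60, station), "day")
  expect_equal(classify_day_night(st$sunset + 46 * 60, station), "night")
})

test_that("period precision and corrected counts reproduce the bundled table", {
  periods <- lapwing_periods()
  expect_equal(period_precision(periods),
               c(35.8, 71.0, 77.2, 87.7, 93.5, 97.0, 92.6, 68.7))
  rep <- activity_report(periods)
  expect_equal(rep$corrected_day[1:8],
               c(823, 2905, 3418, 5085, 11548, 8631, 3777, 1128))
  expect_equal(rep$corrected_night[1:8],
               c(75, 149, 989, 533, 1626, 454, 573, 105))
  expect_equal(rep$corrected_total[1:8],
               c(898, 3054, 4407, 5618, 13175, 9085, 4350, 1233))
  tot <- rep[rep$id == "total", ]
  expect_equal(tot$precision_pct, 81.6)
  expect_equal(tot$corrected_day, 37315)
  expect_equal(tot$corrected_night, 4504)
  # the grand total comes from summing unrounded values (41819), which
  # differs from summing the rounded per-period cells (41820)
  expect_equal(tot$corrected_total, 41819)
  expect_equal(sum(rep$corrected_total[1:8]), 41820)

  # conservation: corrected day+night = raw_total * precision fraction
  cc <- correct_counts(periods)
  frac <- periods$n_correct / (periods$n_correct + periods$n_false)
  expect_equal(cc$corrected_day + cc$corrected_night,
               (periods$raw_day + periods$raw_night) * frac)

  # 100% precision -> corrected = raw
  p1 <- activity_table(1, "2013-04-01", "2013-04-30", 100, 10, 50, 0)
  expect_equal(correct_counts(p1)$corrected_day, 100)
})

test_that("daily series scales counts by the owning period's precision", {
  periods <- activity_table(1:2, c("2013-06-01", "2013-06-03"),
                            c("2013-06-02", "2013-06-04"),
                            raw_day = c(0, 0), raw_night = c(0, 0),
                            n_correct = c(50, 90), n_false = c(50, 10))
  times <- as.POSIXct(c("2013-06-01 10:00", "2013-06-01 11:00",
                        "2013-06-03 10:00", "2013-06-03 23:30"), tz = "UTC")
  d <- daily_series(times, periods, station)
  expect_equal(d$corrected_day[d$date == as.Date("2013-06-01")], 2 * 0.5)
  expect_equal(d$corrected_day[d$date == as.Date("2013-06-03")], 1 * 0.9)
  expect_equal(d$corrected_night[d$date == as.Date("2013-06-03")], 1 * 0.9)
  expect_equal(nrow(d), 4)  # zero-count dates included

  out <- as.POSIXct("2013-07-01 10:00", tz = "UTC")
  expect_error(daily_series(out, periods, station), "outside")
})

test_that("diel profiles aggregate and normalise correctly", {
  times <- as.POSIXct("2013-06-15 00:00", tz = "UTC") +
    c(rep(6 * 3600 + 600, 8), rep(6 * 3600 + 2000, 4), 17 * 3600)
  q <- diel_profile(times, "quarter_hour", normalize = TRUE)
  h <- diel_profile(times, "hour")
  # hour view equals the sum of its four quarter-hour bins
  expect_equal(h$count[h$bin_start_h == 6],
               sum(q$count[q$bin_start_h >= 6 & q$bin_start_h < 7]))
  expect_equal(max(q$pct_of_max), 100)
  expect_equal(q$pct_of_max[q$bin_start_h == 6.00], 100)  # 8 events at 06:10
  expect_equal(sum(q$count), length(times))

  one <- diel_profile(times[1:3], "hour", normalize = TRUE)
  expect_equal(one$pct_of_max[one$bin_start_h == 6], 100)
  expect_true(all(one$pct_of_max[one$bin_start_h != 6] == 0))
})

test_that("simulated diel modes separate midday activity as designed", {
  spec <- season_spec(seed = 77)
  season <- simulate_season(spec)
  season$phase <- season_phase_of(spec, season$date)
  prof <- function(ph) {
    s <- season[season$phase == ph, ]
    agg <- aggregate(true_count ~ quarter_hour_index, s, sum)
    agg$true_count / max(agg$true_count) * 100
  }
  midday <- 41:56  # 10:15-14:00 bins
  all_day <- prof("tending_plateau")
  two_peak <- prof("territory")
  expect_gt(min(all_day[midday]), 40)
  expect_lt(max(two_peak[midday]), 10)
})

test_that("one-tailed Spearman handles the stated cases and matches a Monte-Carlo null", {
  s <- spearman_one_tailed(10:1, 1:10)
  expect_equal(s$rho, -1)
  expect_lt(s$p, 1e-6)
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9, 7, 8)
  s2 <- spearman_one_tailed(x, x)
  expect_equal(s2$rho, 1)
  expect_gt(s2$p, 0.99)
  expect_error(spearman_one_tailed(rep(1, 10), 1:10), "constant")

  # exact permutation p agrees with a Monte-Carlo estimate
  withr::with_seed(5, {
    y <- rnorm(10)
    z <- rnorm(10)
    s3 <- spearman_one_tailed(y, z)
    expect_equal(s3$method, "exact permutation")
    d_obs <- sum((rank(y) - rank(z))^2)
    mc <- mean(replicate(20000, sum((rank(y) - sample(rank(z)))^2) >= d_obs))
    expect_equal(s3$p, mc, tolerance = 0.02)
  })

  # ties fall back to the t approximation
  st <- spearman_one_tailed(c(1, 1, 2, 3, 4), c(5, 4, 3, 2, 1))
  expect_equal(st$method, "t approximation")
})

test_that("lunar machinery groups nights around the synodic cycle", {
  # synodic spacing: consecutive full moons ~29.5 days apart
  ages <- lunar_age(seq(as.Date("2013-06-01"), as.Date("2013-08-31"), by = 1))
  fulls <- which(diff(sign(ages - 29.530588853 / 2)) > 0)
  if (length(fulls) >= 2) expect_equal(diff(fulls)[1], 29.5, tolerance = 1.5)

  dates <- seq(as.Date("2013-06-01"), as.Date("2013-07-25"), by = 1)
  g <- lunar_groups(dates)
  expect_equal(as.vector(table(g$group)[c("new_A", "full", "new_B")]),
               c(13L, 13L, 13L))
  expect_equal(anyDuplicated(g$date), 0)
  # group centres are ~half a synodic month apart
  cen <- tapply(as.numeric(g$date), g$group, median)
  expect_equal(unname(cen["full"] - cen["new_A"]), 14.8, tolerance = 2)
  expect_equal(unname(cen["new_B"] - cen["full"]), 14.8, tolerance = 2)
  # known ephemeris cross-check: June 2013 full moon fell on 23 June
  full_dates <- g$date[g$group == "full"]
  expect_true(as.Date("2013-06-23") %in% full_dates)

  expect_error(lunar_groups(dates[1:10]), "insufficient")
})

test_that("lunar ANOVA matches aov/TukeyHSD and the textbook formulas", {
  dates <- seq(as.Date("2013-06-01"), as.Date("2013-07-25"), by = 1)
  g <- lunar_groups(dates)
  withr::with_seed(42, {
    counts <- data.frame(date = g$date,
                         count = rpois(nrow(g), ifelse(g$group == "full", 60, 20)))
  })
  res <- lunar_anova(g, counts)
  expect_equal(res$df, c(2, 36))

  y <- log10(counts$count + 1)
  grp <- factor(g$group[match(counts$date, g$date)])
  # textbook sums of squares
  tb <- textbook_anova(y, grp)
  expect_equal(res$F, tb$F, tolerance = 1e-10)
  expect_equal(res$p, tb$p, tolerance = 1e-10)
  # stats::aov / TukeyHSD as an independent library oracle
  fit <- stats::aov(y ~ grp)
  expect_equal(res$F, summary(fit)[[1]]$`F value`[1], tolerance = 1e-8)
  tk <- stats::TukeyHSD(fit)$grp
  ours <- res$tukey[order(res$tukey$comparison), ]
  expect_equal(sort(ours$p_adj), sort(unname(tk[, "p adj"])), tolerance = 1e-6)

  # identical group distributions -> F = 0
  same <- data.frame(date = g$date,
                     count = rep(rep(c(5, 7, 9), length.out = 13), 3))
  res0 <- lunar_anova(g, same)
  expect_lt(res0$F, 1e-10)

  flat <- data.frame(date = g$date, count = 5)
  expect_error(lunar_anova(g, flat), "zero within-group variance")
})

test_that("water pairing averages a centred window of daily activity", {
  daily <- data.frame(date = seq(as.Date("2013-04-01"), by = 1, length.out = 30),
                      total = 1:30)
  water <- data.frame(date = as.Date(c("2013-04-05", "2013-04-10")), cm = c(40, 30))
  pw <- pair_water_activity(water, daily)
  expect_equal(pw$activity, c(5, 10))  # centred 5-day means of 3..7 and 8..12
})

test_that("hatch date estimator finds an injected step", {
  dates <- seq(as.Date("2013-05-01"), by = 1, length.out = 60)
  lam <- ifelse(dates >= as.Date("2013-05-30"), 700, 400)
  withr::with_seed(3, {
    daily <- data.frame(date = dates, total = rpois(60, lam))
  })
  est <- estimate_hatch_date(daily)
  expect_lte(abs(as.numeric(est - as.Date("2013-05-30"))), 2)
})
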