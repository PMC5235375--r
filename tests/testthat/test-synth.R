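test_that("call waveform honours peak level, duration, and harmonic structure", {
  # peak: -20 dBFS -> amplitude 0.1
  w <- make_call_waveform(call_spec(n_notes = 1L, note_dur_s = 0.15,
                                    peak_dbfs = -20), 48000)
  expect_equal(max(abs(w$samples)), 0.1, tolerance = 1e-12)
  expect_equal(clip_duration(w), 0.15)

  # duration arithmetic: 3 notes x 0.1 s + 2 gaps x 0.3 s = 0.9 s
  w3 <- make_call_waveform(call_spec(n_notes = 3L, note_dur_s = 0.1,
                                     gap_s = 0.3, peak_dbfs = -20), 48000)
  expect_equal(clip_duration(w3), 0.9)

  # harmonic stack: FFT peaks at k * 1300 Hz, k = 1..6
  wl <- make_call_waveform(call_spec(n_notes = 1L, note_dur_s = 0.5,
                                     f0_hz = 1300, n_harmonics = 6L,
                                     peak_dbfs = -10), 48000)
  pk <- fft_peaks(wl, n = 6, merge_hz = 200)
  expect_equal(pk, 1300 * (1:6), tolerance = 0.01)

  # harmonics above Nyquist are dropped, not aliased
  whi <- make_call_waveform(call_spec(n_notes = 1L, note_dur_s = 0.2,
                                      f0_hz = 5000, n_harmonics = 6L,
                                      peak_dbfs = -10), 24000)
  expect_lt(band_power(whi, 0, 4000) / band_power(whi, 4500, 11500), 1e-6)

  expect_error(make_call_waveform(call_spec(peak_dbfs = 0), 48000), NA)
  expect_error(call_spec(peak_dbfs = 3), "peak_dbfs")
  expect_error(call_spec(note_dur_s = 0.01), ">= 0.05")
})

test_that("rendered scenes carry exact annotations and are reproducible", {
  calls <- c(
    lapply(c(1, 3, 5, 7, 9), function(o)
      call_spec(onset_s = o, peak_dbfs = -25, label = "target")),
    lapply(c(2, 4.5, 6.5), function(o)
      call_spec(onset_s = o, peak_dbfs = -30, label = "nontarget",
                f0_hz = 3000)))
  spec <- scene_spec(12, sample_rate_hz = 24000, calls = calls, seed = 42)
  sc <- render_scene(spec)
  expect_equal(nrow(sc$annotations), 8)
  expect_equal(sum(sc$annotations$label == "target"), 5)
  expect_true(all(diff(sc$annotations$start_s) >= 0))

  # bit-identical on re-render
  sc2 <- render_scene(spec)
  expect_identical(sc$clip$samples, sc2$clip$samples)
  expect_identical(sc$annotations, sc2$annotations)

  # empty scene -> empty annotation list
  sc0 <- render_scene(scene_spec(2, sample_rate_hz = 24000, seed = 1))
  expect_equal(nrow(sc0$annotations), 0)

  # annotated intervals hold more energy than the adjacent background
  a <- sc$annotations[sc$annotations$label == "target", ][1, ]
  fs <- sc$clip$rate_hz
  seg <- sc$clip$samples[round(a$start_s * fs):round(a$end_s * fs)]
  bgseg <- sc$clip$samples[round(11 * fs):round(11.9 * fs)]
  expect_gt(mean(seg^2), 2 * mean(bgseg^2))

  # a scene engineered to clip raises
  loud <- scene_spec(2, sample_rate_hz = 24000, broadband_level_dbfs = 0,
                     seed = 1)
  expect_error(render_scene(loud), "clips")
})

test_that("rendered target peaks match the requested dBFS within 0.1 dB", {
  # quiet background so the call dominates the peak measurement
  for (pk in c(-10, -20, -35)) {
    sp <- scene_spec(4, sample_rate_hz = 24000, broadband_level_dbfs = -80,
                     wind_band_level_dbfs = -80, insect_band_level_dbfs = -80,
                     calls = list(call_spec(onset_s = 1, peak_dbfs = pk)),
                     seed = 5)
    sc <- render_scene(sp)
    fs <- sc$clip$rate_hz
    seg <- sc$clip$samples[round(1 * fs):round(1.6 * fs)]
    expect_equal(dbfs(max(abs(seg))), pk, tolerance = 0.1)
  }
})

test_that("season simulator obeys its trivial contracts", {
  rates0 <- c(flood_low = 0, territory = 0, laying_dip = 0,
              incubation_ramp = 0, tending_plateau = 0, decay = 0,
              post_breeding = 0)
  s0 <- simulate_season(season_spec(phase_mean_rates = rates0, seed = 2))
  expect_true(all(s0$true_count == 0))

  s1 <- simulate_season(season_spec(seed = 9))
  s2 <- simulate_season(season_spec(seed = 9))
  expect_identical(s1, s2)
  expect_equal(sort(unique(s1$quarter_hour_index)), 0:95)

  # round trip through CSV
  p <- withr::local_tempfile(fileext = ".csv")
  write_season_csv(s1, p)
  expect_equal(read_season_csv(p), s1)
})

test_that("simulated phase means recover the injected intensities (3 SE)", {
  spec <- season_spec(seed = 314)
  season <- simulate_season(spec)
  daily <- aggregate(true_count ~ date, season, sum)
  expct <- season_expected_daily(spec)
  m <- merge(daily, expct, by = "date")
  for (ph in unique(m$phase)) {
    sel <- m$phase == ph
    n <- sum(sel)
    mu <- mean(m$expected_true[sel])
    se <- sqrt(mu / n)   # Poisson SE of the mean daily count
    expect_lt(abs(mean(m$true_count[sel]) - mu), 3 * se + 1e-9)
  }
})

test_that("the hatch step lifts the plateau by the configured fraction", {
  spec <- season_spec(hatch_step_fraction = 0.64)
  # derived rate: 467 * 1.64 = 766 events/day (to integer precision)
  expect_equal(unname(spec$phase_mean_rates["hatch_step"]), 765.88)
  expect_equal(round(spec$phase_mean_rates[["hatch_step"]]), 766)
})

test_that("the day/night split matches the diel profile mass within MC error", {
  spec <- season_spec(seed = 55)
  season <- simulate_season(spec)
  # analytic expected night counts per day (profile night mass x rate x
  # lunar multiplier), via the package's own intensity pieces
  dates <- sort(unique(season$date))
  sun <- sun_times(spec$solar, dates)
  base <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  sr <- as.numeric(sun$sunrise - base, units = "hours")
  ss <- as.numeric(sun$sunset - base, units = "hours")
  rate <- season_daily_rate(spec, dates)
  phases <- season_phase_of(spec, dates)
  moon <- is_moonlit(dates)
  tc <- (0:95) / 4 + 0.125
  exp_night <- vapply(seq_along(dates), function(i) {
    w <- quero:::diel_weights(spec$diel_profile[[phases[i]]], sr[i], ss[i])
    night <- !(tc >= sr[i] - 1 & tc <= ss[i] + 0.75)
    mult <- if (moon[i]) spec$lunar_night_multiplier else 1
    rate[i] * sum(w[night]) * mult
  }, numeric(1))
  got_night <- sum(season$true_count[season$night_flag])
  expect_lt(abs(got_night - sum(exp_night)), 3 * sqrt(sum(exp_night)))
  # and the total over quarter-hours is the day total by construction
  expect_equal(sum(season$true_count),
               sum(aggregate(true_count ~ date, season, sum)$true_count))
})
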