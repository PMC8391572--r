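test_that("template spectra calibrate exactly and carry the right tilt", {
  for (lvl in c(55, 68, 83)) {
    a <- aircraft_spectrum(lvl)
    r <- road_spectrum(lvl)
    expect_equal(a_weighted_level(a), lvl, tolerance = 0.01)
    expect_equal(a_weighted_level(r), lvl, tolerance = 0.01)
  }
  a <- aircraft_spectrum(68)
  r <- road_spectrum(65)
  # aircraft: high-frequency character
  expect_gt(a$level_db[a$freq_hz == 4000], a$level_db[a$freq_hz == 125])
  # road: broadband (within 15 dB across 100 Hz-5 kHz), low-frequency tilt
  mid <- r$level_db[r$freq_hz >= 100 & r$freq_hz <= 5000]
  expect_lte(diff(range(mid)), 15)
  expect_gte(r$level_db[r$freq_hz == 125], r$level_db[r$freq_hz == 8000])
  # determinism
  expect_identical(aircraft_spectrum(68), aircraft_spectrum(68))
  expect_error(aircraft_spectrum(120))
})

test_that("flyover waveforms are calibrated, reproducible and peak mid-file", {
  fly <- flyover_waveform(70, duration = 5, fs = 12000, seed = 9)
  expect_equal(a_weighted_level(fly), 70, tolerance = 0.1)
  fly2 <- flyover_waveform(70, duration = 5, fs = 12000, seed = 9)
  expect_identical(fly$left, fly2$left)
  expect_identical(fly$right, fly2$right)
  # loudness maximum falls in the middle third of the file
  tr <- time_varying_loudness(fly, cst)
  peak <- which.max(tr$short_term) / length(tr$short_term)
  expect_gt(peak, 1 / 3)
  expect_lt(peak, 2 / 3)
  expect_error(flyover_waveform(70, duration = 2), "duration")
})

test_that("the jury design enumerates all 85 conditions", {
  d <- jury_design()
  expect_equal(nrow(d), 85)
  expect_equal(sum(d$type == "combined"), 25)
  expect_equal(sum(d$type == "aircraft_alone"), 5)
  expect_equal(sum(d$type == "road_alone"), 5)
  expect_equal(sum(d$type == "aircraft_with_road"), 25)
  expect_equal(sum(d$type == "road_with_aircraft"), 25)
  expect_setequal(unique(stats::na.omit(d$aircraft_db)), c(63, 68, 73, 78, 83))
  expect_setequal(unique(stats::na.omit(d$road_db)), c(55, 60, 65, 70, 75))
})

test_that("simulated ratings respect the scale and the noise model", {
  x <- seq(0, 60, 5)
  r0 <- simulate_ratings(x, n_subjects = 5, noise_sd = 0, seed = 1)
  # noiseless subjects are identical
  expect_true(all(apply(r0, 2, function(col) length(unique(col)) == 1)))
  r <- simulate_ratings(x, n_subjects = 200, noise_sd = 3, seed = 2)
  expect_true(all(r >= 0 & r <= 10))
  expect_true(all(r == round(r)))
})

test_that("the simulated jury links conditions to model ratings", {
  jury <- simulate_jury(n_subjects = 3, noise_sd = 0.5, seed = 5,
                        constants = cst)
  expect_equal(nrow(jury), 85 * 3)
  expect_true(all(jury$rating >= 0 & jury$rating <= 10))
  jury2 <- simulate_jury(n_subjects = 3, noise_sd = 0.5, seed = 5,
                         constants = cst)
  expect_identical(jury$rating, jury2$rating)
  # masked conditions are rated below the matching single-source condition
  agg <- stats::aggregate(loudness ~ type + aircraft_db, data = jury,
                          FUN = mean)
  single <- agg[agg$type == "aircraft_alone" & agg$aircraft_db == 73, "loudness"]
  masked <- agg[agg$type == "aircraft_with_road" & agg$aircraft_db == 73,
                "loudness"]
  expect_true(all(masked < single))
})

test_that("binned survey simulation tracks the generating %HA curve", {
  bins <- simulate_survey_bins(n_per_bin = 2000, seed = 3)
  expect_equal(nrow(bins), 9)
  # each bin within a 3-sigma binomial interval of the generating value
  se <- sqrt(bins$p_true * (100 - bins$p_true) / bins$n)
  expect_true(all(abs(bins$pct_ha - bins$p_true) < 3.5 * se))
})

test_that("the toy exposure grid has the line-source geometry", {
  g <- receiver_grid(nx = 20, ny = 16, road_level = 72, air_level = 78,
                     road_decay = 4)
  expect_equal(g$cellsize, 10)
  expect_equal(dim(g$road), c(16, 20))
  # maximum road level on the road axis row
  axis_row <- which.max(g$road[, 1])
  expect_equal(g$road[axis_row, 1], max(g$road))
  # the grid is built from the configured distance-decay law, which loses
  # exactly decay_db per doubling of distance beyond the reference distance
  y <- (seq_len(16) - 0.5) * 10
  d <- abs(y - 0.25 * 16 * 10)
  expect_equal(g$road[, 3], distance_attenuation(72, d, 25, 4),
               tolerance = 1e-12)
  expect_equal(distance_attenuation(72, 50, 25, 4) -
                 distance_attenuation(72, 100, 25, 4), 4, tolerance = 1e-12)
})

test_that("survey simulation is seeded and labels exposure groups", {
  g <- receiver_grid(nx = 8, ny = 8)
  s1 <- simulate_survey(g, n_subjects = 40, seed = 21, constants = cst)
  s2 <- simulate_survey(g, n_subjects = 40, seed = 21, constants = cst)
  expect_identical(s1, s2)
  expect_true(all(s1$loud_total >= s1$loud_aircraft |
                    s1$loud_total >= s1$loud_road))
  expect_true(all(levels(s1$group) == c("less than 50 dBA", "50-60 dBA",
                                        "60-70 dBA", "over 70 dBA")))
  expect_equal(s1$aircraft_indoor_db, s1$aircraft_db - 15)
  expect_equal(s1$road_indoor_db, s1$road_db - 15.8)
})
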