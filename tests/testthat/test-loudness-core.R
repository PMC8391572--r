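test_that("excitation patterns honour silence, monotonicity and rejection", {
  silent <- third_octave_spectrum(c(500, 1000), c(-Inf, -Inf))
  e0 <- excitation_from_spectrum(silent, constants = cst)
  expect_true(all(e0$excitation == 0))

  e10 <- excitation_from_spectrum(tone_spec(10), constants = cst)
  e0db <- excitation_from_spectrum(tone_spec(0), constants = cst)
  ch <- which.min(abs(cst$freq - 1000))
  expect_gt(e10$excitation[ch], e0db$excitation[ch])

  # raising any band level never decreases excitation anywhere
  lo <- excitation_from_spectrum(flat_spec(50), constants = cst)
  hi <- excitation_from_spectrum(flat_spec(60), constants = cst)
  expect_true(all(hi$excitation >= lo$excitation))

  expect_error(excitation_from_spectrum(tone_spec(125), constants = cst),
               "120 dB")
})

test_that("specific loudness implements the compressive transform", {
  # zero excitation maps to zero loudness density
  ez <- excitation_from_spectrum(third_octave_spectrum(1000, -Inf),
                                 constants = cst)
  expect_true(all(specific_loudness(ez, cst)$n_prime == 0))

  # mid-level channel equals the direct scalar evaluation of the formula
  e <- structure(list(cam = cst$cam,
                      excitation = rep(0, length(cst$cam)),
                      cam_step = cst$cam_step), class = "excitation_pattern")
  ch <- which.min(abs(cst$freq - 1000))
  e$excitation[ch] <- 1e7
  n <- specific_loudness(e, cst)$n_prime[ch]
  direct <- cst$C * ((1e7 * cst$G[ch] + cst$A[ch])^cst$alpha[ch] -
                       cst$A[ch]^cst$alpha[ch])
  expect_equal(n, direct, tolerance = 1e-12)

  # doubling excitation well above threshold scales by about 2^alpha
  e2 <- e
  e2$excitation[ch] <- 2e7
  ratio <- specific_loudness(e2, cst)$n_prime[ch] / n
  expect_equal(ratio, 2^cst$alpha[ch], tolerance = 0.02)

  # grid mismatch rejected
  other <- loudness_constants(cam_min = 2, cam_max = 38)
  expect_error(specific_loudness(e, other), "grid")
})

test_that("loudness calibration anchors hold", {
  expect_equal(loudness_stationary(tone_spec(40), constants = cst), 1,
               tolerance = 0.05)
  l40 <- loudness_stationary(tone_spec(40), constants = cst)
  l50 <- loudness_stationary(tone_spec(50), constants = cst)
  l60 <- loudness_stationary(tone_spec(60), constants = cst)
  expect_equal(l50 / l40, 2, tolerance = 0.1)
  expect_equal(l60 / l50, 2, tolerance = 0.1)
})

test_that("partial loudness reduces to the unmasked pattern without a masker", {
  et <- excitation_from_spectrum(calibrate_level(aircraft_template(), 70),
                                 constants = cst)
  ez <- excitation_from_spectrum(
    third_octave_spectrum(1000, -Inf), constants = cst)
  p <- partial_specific_loudness(et, ez, cst)
  s <- specific_loudness(et, cst)
  expect_identical(p$n_prime, s$n_prime)
})

test_that("masking monotonicity: partial loudness falls as background rises", {
  et <- excitation_from_spectrum(calibrate_level(aircraft_template(), 70),
                                 constants = cst)
  bg_levels <- seq(30, 87, length.out = 20)
  vals <- vapply(bg_levels, function(b) {
    eb <- excitation_from_spectrum(calibrate_level(road_template(), b),
                                   constants = cst)
    integrate_loudness(partial_specific_loudness(et, eb, cst))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # and never exceeds the unmasked loudness
  expect_true(all(vals <= integrate_loudness(specific_loudness(et, cst))))
})

test_that("loudness additivity holds in the strong-target limit", {
  # matched broadband shapes, 60 dB apart: the target is far above its masked
  # threshold in every channel that carries loudness
  es <- excitation_from_spectrum(flat_spec(85), constants = cst)
  eb <- excitation_from_spectrum(flat_spec(25), constants = cst)
  ps <- partial_specific_loudness(es, eb, cst)
  pb <- specific_loudness(eb, cst, role = "background")
  tot <- specific_loudness(annoymap:::add_excitation(es, eb), cst)

  ethrn <- cst$K * eb$excitation + cst$E_THRQ
  cond <- es$excitation >= 1000 * ethrn &
    tot$n_prime > 0.01 * max(tot$n_prime)
  expect_gt(sum(cond), 100)
  relerr <- abs(ps$n_prime[cond] + pb$n_prime[cond] - tot$n_prime[cond]) /
    tot$n_prime[cond]
  expect_lt(max(relerr), 0.05)
  # and for the integrated loudness
  int_err <- abs(integrate_loudness(ps) + integrate_loudness(pb) -
                   integrate_loudness(tot)) / integrate_loudness(tot)
  expect_lt(int_err, 0.05)
})

test_that("integration over the Cam scale is linear and nonnegative", {
  ea <- excitation_from_spectrum(flat_spec(60), constants = cst)
  eb <- excitation_from_spectrum(tone_spec(70), constants = cst)
  sa <- specific_loudness(ea, cst)
  sb <- specific_loudness(eb, cst)
  ssum <- sa
  ssum$n_prime <- sa$n_prime + sb$n_prime
  expect_equal(integrate_loudness(ssum),
               integrate_loudness(sa) + integrate_loudness(sb),
               tolerance = 1e-12)
  zero <- sa
  zero$n_prime <- rep(0, length(sa$n_prime))
  expect_identical(integrate_loudness(zero), 0)
})

test_that("binaural inhibition matches the closed-form factors", {
  s <- specific_loudness(excitation_from_spectrum(tone_spec(60),
                                                  constants = cst), cst)
  z <- s
  z$n_prime <- rep(0, length(s$n_prime))

  # silent contralateral ear: factor 2 / 2^P = 2^(1 - 1.598) in every channel
  mono <- binaural_inhibition(s, z, cst)
  act <- s$n_prime > 0
  expect_equal(mono$left$n_prime[act] / s$n_prime[act],
               rep(2^(1.598 - 1), sum(act)), tolerance = 1e-6)
  expect_true(all(mono$right$n_prime == 0))

  # identical ears: factor 2 / (1 + sech(1))^1.598 of about 0.900
  dio <- binaural_inhibition(s, s, cst)
  f_expect <- 2 / (1 + 1 / cosh(1))^1.598
  expect_equal(f_expect, 0.900, tolerance = 1e-3)
  expect_equal(dio$left$n_prime[act] / s$n_prime[act],
               rep(1 / f_expect, sum(act)), tolerance = 1e-6)

  # ear-swap symmetry is exact
  s2 <- specific_loudness(excitation_from_spectrum(tone_spec(50),
                                                   constants = cst), cst)
  ab <- binaural_inhibition(s, s2, cst)
  ba <- binaural_inhibition(s2, s, cst)
  expect_identical(ab$left$n_prime, ba$right$n_prime)
  expect_identical(ab$right$n_prime, ba$left$n_prime)

  expect_error(binaural_inhibition(z, {
    neg <- s
    neg$n_prime[1] <- -1
    neg
  }, cst), "non-negative")
})

test_that("diotic loudness is about 1.5 times monaural", {
  for (lvl in c(40, 60, 80)) {
    dio <- loudness_stationary(tone_spec(lvl), ears = "diotic",
                               constants = cst)
    mono <- loudness_stationary(tone_spec(lvl), ears = "monaural",
                                constants = cst)
    expect_equal(dio / mono, 1.5, tolerance = 0.1)
  }
})
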