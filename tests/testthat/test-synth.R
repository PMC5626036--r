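test_that("a generated beat is deterministic with the R peak at its argmax", {
  b1 <- generate_beat(360, beat_shape_params())
  b2 <- generate_beat(360, beat_shape_params())
  expect_identical(b1$samples, b2$samples)
  expect_equal(which.max(b1$samples), b1$r_index)
  expect_length(b1$samples, 360)

  zero <- beat_shape_params(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_identical(generate_beat(360, zero)$samples, numeric(360))
})

test_that("beat generation validates its parameters", {
  expect_error(generate_beat(-1), "fs")
  expect_error(generate_beat(200, beat_shape_params(hr = 60)), "271")
  expect_error(beat_shape_params(width_ms = c(P = 25, Q = 10, R = -1,
                                              S = 10, T = 60)), "widths")
  expect_error(
    beat_shape_params(amplitude = c(P = 0.12, Q = -0.1, R = 0.2,
                                    S = -0.15, T = 0.30)),
    "dominate")
})

test_that("records concatenate beats with exact R ground truth and seed determinism", {
  g <- quiet_record(n_beats = 5)
  expect_length(g$r_peaks, 5)
  expect_true(all(diff(g$r_peaks) == 360))
  # zero noise: record equals the clean reference exactly
  expect_identical(g$record$samples, g$clean)
  # every true R is the local maximum of the clean signal near it
  for (r in g$r_peaks) {
    win <- max(1, r - 5):min(length(g$clean), r + 5)
    expect_lte(abs(win[which.max(g$clean[win])] - r), 2)
  }

  a <- generate_record(360, 4, noise = noise_params(sd = 0.05, seed = 9))
  b <- generate_record(360, 4, noise = noise_params(sd = 0.05, seed = 9))
  c <- generate_record(360, 4, noise = noise_params(sd = 0.05, seed = 10))
  expect_identical(a$record$samples, b$record$samples)
  expect_false(identical(a$record$samples, c$record$samples))
})

test_that("baseline wander shows up as the dominant low-frequency peak", {
  g <- generate_record(360, 20, noise = noise_params(sd = 0, wander_amp = 0.3,
                                                     wander_freq = 0.2))
  sp <- stats::spec.pgram(stats::ts(g$record$samples, frequency = 360),
                          plot = FALSE, taper = 0)
  low <- sp$freq < 1
  peak <- sp$freq[low][which.max(sp$spec[low])]
  expect_equal(peak, 0.2, tolerance = 0.05)
})

test_that("amplitude jitter is seeded and off by default", {
  j <- generate_record(360, 6, noise = noise_params(sd = 0, wander_amp = 0,
                                                    amp_jitter_sd = 0.1,
                                                    seed = 3))
  j2 <- generate_record(360, 6, noise = noise_params(sd = 0, wander_amp = 0,
                                                     amp_jitter_sd = 0.1,
                                                     seed = 3))
  expect_identical(j$record$samples, j2$record$samples)
  amp1 <- max(j$clean[1:360])
  amp4 <- max(j$clean[1081:1440])
  expect_false(isTRUE(all.equal(amp1, amp4)))
})
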