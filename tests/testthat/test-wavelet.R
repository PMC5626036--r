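test_that("smoothing preserves constants and the additive details vanish", {
  x <- rep(3.7, 128)
  d <- atrous_decompose(x, 4)
  expect_equal(d$S, x, tolerance = 1e-12)
  for (w in d$W) expect_equal(max(abs(w)), 0, tolerance = 1e-12)
})

test_that("level-1 analytic detail equals direct convolution of the high-pass filter", {
  n <- 33
  x <- numeric(n); x[17] <- 1 # unit impulse
  fp <- filter_pair()
  d <- atrous_decompose(x, 1, fp, variant = "analytic")
  # oracle: W_1(m) = sum_k g_k x(m - k), mirror boundary irrelevant mid-signal
  expected <- numeric(n)
  for (m in 5:(n - 5)) {
    expected[m] <- sum(fp$g * x[m - fp$g_taps])
  }
  expect_equal(d$W[[1]][5:(n - 5)], expected[5:(n - 5)], tolerance = 1e-14)
})

test_that("additive decomposition reconstructs any signal exactly", {
  set.seed(4)
  for (n in c(64, 257)) {
    x <- stats::rnorm(n)
    for (J in c(1, 3, 5)) {
      d <- atrous_decompose(x, J)
      expect_equal(d$S + Reduce(`+`, d$W), x, tolerance = 1e-12)
    }
  }
})

test_that("the transform is linear and shift-covariant in the interior", {
  set.seed(5)
  x <- stats::rnorm(256); y <- stats::rnorm(256)
  for (variant in c("additive", "analytic")) {
    dx <- atrous_decompose(x, 3, variant = variant)
    dy <- atrous_decompose(y, 3, variant = variant)
    dz <- atrous_decompose(2 * x - 3 * y, 3, variant = variant)
    expect_equal(dz$W[[3]], 2 * dx$W[[3]] - 3 * dy$W[[3]], tolerance = 1e-10)
    expect_equal(dz$S, 2 * dx$S - 3 * dy$S, tolerance = 1e-10)
  }
  # circular shift: interior samples of the shifted decomposition match
  s <- 8L
  xs <- c(x[(s + 1):256], x[1:s])
  d0 <- atrous_decompose(x, 3)
  d1 <- atrous_decompose(xs, 3)
  interior <- 60:180
  expect_equal(d1$W[[3]][interior], d0$W[[3]][interior + s], tolerance = 1e-10)
})

test_that("decomposition refuses signals shorter than the dilated support", {
  expect_error(atrous_decompose(stats::rnorm(20), J = 5), "shorter")
})

test_that("baseline removal cancels drift-band tones and helps a wandering record", {
  expect_identical(remove_baseline(ecg_record(numeric(2000), 360))$samples,
                   numeric(2000))
  t <- (0:7199) / 360
  for (f in c(0.15, 0.2, 0.3)) {
    s <- sin(2 * pi * f * t)
    out <- remove_baseline(ecg_record(s, 360))
    expect_lt(sum(out$samples^2) / sum(s^2), 0.15)
  }
  # the derived bound from the band interior
  s <- sin(2 * pi * 0.2 * t)
  out <- remove_baseline(ecg_record(s, 360))
  expect_lt(sum(out$samples^2) / sum(s^2), 0.10)

  g <- generate_record(360, 10, noise = noise_params(sd = 0, wander_amp = 0.2,
                                                     wander_freq = 0.2))
  cleaned <- remove_baseline(g$record)
  expect_lt(prd(g$clean, cleaned$samples), prd(g$clean, g$record$samples))
  expect_error(remove_baseline(ecg_record(stats::rnorm(100), fs = 1)), "too low")
})

test_that("denoising keeps the cardiac scales and reduces white-noise distortion", {
  expect_identical(denoise(ecg_record(numeric(400), 360))$samples, numeric(400))
  g <- generate_record(360, 10, noise = noise_params(sd = 0.05, wander_amp = 0))
  dn <- denoise(g$record)
  expect_lt(prd(g$clean, dn$samples), prd(g$clean, g$record$samples))
  # keeping every scale reproduces the input (telescoping identity)
  set.seed(6)
  x <- stats::rnorm(400)
  all_kept <- denoise(ecg_record(x, 360), keep = 1:5, J = 5)
  expect_equal(all_kept$samples, x, tolerance = 1e-6)
  # the default keep-set equals input minus the discarded fine scales
  dec <- atrous_decompose(x, 5)
  expect_equal(denoise(ecg_record(x, 360))$samples,
               x - dec$W[[1]] - dec$W[[2]], tolerance = 1e-10)
})

test_that("the filter pair is validated", {
  expect_error(filter_pair(h = c(1, 1) / 3, h_taps = c(0L, 1L)), "sum to 1")
  expect_error(filter_pair(h = c(0.5, 0.5), h_taps = 0L), "equal lengths")
})
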