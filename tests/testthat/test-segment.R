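test_that("the default scheme cuts a 270-sample window, the cluster scheme 251", {
  s270 <- segmentation_scheme()
  expect_equal(s270$beat_length, 270L)
  rec <- ecg_record(seq_len(2000), 360)
  bm <- segment_beats(rec, 1000L, s270)
  expect_equal(ncol(bm$beats), 270)
  # window is [R - 105, R + 165): sample values are their own indices here
  expect_equal(bm$beats[1, 1], 895)
  expect_equal(bm$beats[1, 270], 1164)
  expect_equal(bm$beats[1, 106], 1000) # R at position pre + 1

  s251 <- segmentation_scheme(pre = 90, post = 161, target = 70)
  expect_equal(s251$beat_length, 251L)
})

test_that("boundary beats are skipped and counted", {
  rec <- ecg_record(stats::rnorm(1000), 360)
  bm <- segment_beats(rec, c(50L, 500L, 990L))
  expect_equal(nrow(bm$beats), 1)
  expect_equal(bm$skipped, 2)
  expect_equal(nrow(bm$beats) + bm$skipped, 3)
  expect_warning(segment_beats(rec, 10L), "no beat")
})

test_that("downsampling keeps exactly 70 samples with the central block intact", {
  sch <- segmentation_scheme()
  idx <- downsample_indices(sch)
  expect_length(idx, 70)
  expect_true(all((106 - 7):(106 + 7) %in% idx)) # R-centered 15 samples
  beat <- sin(seq_len(270) / 9)
  down <- downsample_beat(beat, sch)
  expect_length(down, 70)
  expect_identical(down, beat[idx])
  # central samples appear unchanged at their mapped positions
  central <- (106 - 7):(106 + 7)
  expect_identical(down[match(central, idx)], beat[central])
  expect_identical(downsample_beat(rep(2.5, 270), sch), rep(2.5, 70))
  expect_error(downsample_beat(numeric(100), sch), "270")
})

test_that("the stride-6 variant retains 15 + ceiling(255/6) samples", {
  sch <- segmentation_scheme(method = "stride", stride = 6)
  expect_length(downsample_indices(sch), 15 + ceiling(255 / 6))
})

test_that("downsampling commutes with scaling and permutes as a gather", {
  sch <- segmentation_scheme()
  beat <- stats::rnorm(270)
  expect_equal(downsample_beat(3 * beat + 1, sch),
               3 * downsample_beat(beat, sch) + 1)
})

test_that("upsampling inverts downsampling on the retained samples", {
  sch <- segmentation_scheme()
  idx <- downsample_indices(sch)
  expect_identical(upsample_beat(rep(1.5, 70), sch), rep(1.5, 270))
  beat <- generate_beat(360, beat_shape_params())
  win <- (beat$r_index - 105):(beat$r_index + 164)
  smooth <- beat$samples[win]
  round <- upsample_beat(downsample_beat(smooth, sch), sch)
  expect_identical(round[idx], smooth[idx]) # exact fixed points
  expect_lt(prd(smooth, round), 0.05)
  expect_error(upsample_beat(numeric(30), sch), "retains")
})

test_that("per-beat normalization maps to [0,1] and inverts exactly", {
  set.seed(7)
  m <- matrix(stats::rnorm(300, sd = 3), 10, 30)
  m[4, ] <- 2 # constant beat
  nb <- normalize_beats(m)
  expect_true(all(nb$beats >= 0 & nb$beats <= 1))
  expect_true(all(nb$beats[4, ] == 0.5))
  back <- denormalize_beats(nb$beats, nb$mins, nb$maxs)
  expect_equal(back, m, tolerance = 1e-12)
})

test_that("scheme parameters are validated", {
  expect_error(segmentation_scheme(central_width = 14), "odd")
  expect_error(segmentation_scheme(target = 5), "central_width")
})
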