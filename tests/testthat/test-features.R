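# Feature pipeline: segmentation, sections, band decomposition, differential
# entropy, grid assembly, 4D stacking, baseline subtraction.

test_that("segmentation yields floor(duration/T) contiguous segments", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(2 * 200 * 180), 2), 200)
  segs <- segment_signal(rec, T = 3)
  expect_length(segs, 60)
  expect_true(all(vapply(segs, ncol, 0L) == 600))
  # exact fit -> one segment; remainder discarded
  expect_length(segment_signal(eeg_recording(matrix(rnorm(600), 1), 200), 3), 1)
  expect_length(segment_signal(eeg_recording(matrix(rnorm(799), 1), 200), 3), 1)
  expect_error(segment_signal(eeg_recording(matrix(rnorm(580), 1), 200), 3),
               "too short")
  # concatenating the segments reproduces the used part of the signal
  expect_identical(do.call(cbind, segs), rec$samples[, 1:(60 * 600)])
})

test_that("sections are 2T half-second pieces whose concatenation is the segment", {
  set.seed(2)
  seg <- matrix(rnorm(3 * 600), 3)
  secs <- split_sections(seg, T = 3, fs = 200)
  expect_length(secs, 6)
  expect_true(all(vapply(secs, ncol, 0L) == 100))
  expect_identical(do.call(cbind, secs), seg)
  # T = 2.5 -> 5 sections
  seg5 <- matrix(rnorm(2 * 500), 2)
  expect_length(split_sections(seg5, T = 2.5, fs = 200), 5)
  expect_error(split_sections(seg, T = 3.3, fs = 200), "integer")
})

test_that("band decomposition isolates a 10 Hz tone into the alpha band", {
  fs <- 200
  tt <- (0:(fs / 2 - 1)) / fs
  tone <- sin(2 * pi * 10 * tt)
  out <- band_decompose(tone, fs = fs)
  ratios <- vapply(out, function(b) stats::var(b) / stats::var(tone), 0)
  expect_gte(ratios[["alpha"]], 0.90)
  expect_lte(ratios[["theta"]], 0.05)
  expect_lte(ratios[["beta"]], 0.05)
  expect_lte(ratios[["gamma"]], 0.05)
  # shapes preserved; zero in -> zero out
  expect_true(all(vapply(out, length, 0L) == length(tone)))
  zed <- band_decompose(rep(0, 100), fs = fs)
  expect_true(all(vapply(zed, function(b) max(abs(b)), 0) == 0))
  expect_length(zed, 4)
})

test_that("band edges at or above Nyquist are rejected with the band named", {
  bands <- default_bands()
  expect_error(band_decompose(rnorm(100), bands, fs = 100), "gamma")
})

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(3)
  expect_equal(differential_entropy(rnorm(1e4)), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.05)
  expect_equal(differential_entropy(rnorm(1e4, sd = 2)),
               0.5 * log(2 * pi * exp(1) * 4), tolerance = 0.05)
})

test_that("differential entropy obeys the scaling identity DE(cx) = DE(x) + log|c|", {
  set.seed(4)
  for (c_ in c(2, 0.5, 7.3)) {
    x <- rnorm(57)
    expect_equal(differential_entropy(c_ * x) - differential_entropy(x),
                 log(c_), tolerance = 1e-12)
  }
})

test_that("degenerate differential entropy inputs warn or error", {
  expect_warning(de <- differential_entropy(rep(1, 10)), "floor")
  expect_true(is.finite(de))
  expect_error(differential_entropy(1), "at least 2")
  expect_error(differential_entropy(c(1, NA, 3)), "finite")
})

test_that("grid assembly places electrodes and conserves the DE sum", {
  g <- default_grid_map("seed62")
  vals <- stats::setNames(runif(62, 1, 2), g$entries$electrode)
  map <- assemble_grid(vals, g)
  expect_equal(dim(map), c(9, 8))
  expect_equal(sum(map != 0), 62)
  expect_equal(sum(map), sum(vals))
  # empty and single-electrode cases
  expect_equal(assemble_grid(numeric(0), g), matrix(0, 9, 8))
  one <- assemble_grid(c(FPZ = 1.5), g)
  expect_equal(one[1, 1], 1.5)
  expect_equal(sum(one), 1.5)
  expect_error(assemble_grid(c(NOPE = 1), g), "NOPE")
})

test_that("4D feature tensor obeys the (floor(dur/T), 9, 8, 4, 2T) shape law", {
  prof <- small_profile()
  rec <- generate_recording(prof, 1, duration = 12, seed = 5)
  for (T in c(2, 2.5, 3, 3.5, 4)) {
    ft <- build_4d_features(rec, T = T, grid = small_grid())
    expect_equal(dim(ft$values), c(floor(12 / T), 9, 8, 4, 2 * T),
                 info = paste("T =", T))
  }
  expect_error(build_4d_features(rec, T = 3.3, grid = small_grid()), "integer")
})

test_that("feature building is deterministic and matches the per-section path", {
  prof <- small_profile()
  rec <- generate_recording(prof, 2, duration = 6, seed = 6)
  ft1 <- build_4d_features(rec, T = 3, grid = small_grid())
  ft2 <- build_4d_features(rec, T = 3, grid = small_grid())
  expect_identical(ft1$values, ft2$values)
  # cross-check one cell against the manual segment -> section -> band -> DE path
  g <- small_grid()
  seg <- segment_signal(rec, T = 3)[[2]]
  sec <- split_sections(seg, T = 3, fs = rec$sampling_rate)[[4]]
  banded <- band_decompose(sec, fs = rec$sampling_rate)
  ch <- 3  # F7 -> row 2, col 0
  de_manual <- differential_entropy(banded[["beta"]][ch, ])
  expect_equal(ft1$values[2, 3, 1, 3, 4], de_manual, tolerance = 1e-10)
})

test_that("unmapped channels are rejected with the electrode named", {
  rec <- eeg_recording(matrix(rnorm(2 * 1200), 2), 200,
                       channel_names = c("AF3", "XX9"))
  expect_error(build_4d_features(rec, T = 3, grid = small_grid()), "XX9")
})

test_that("baseline subtraction removes a constant per-cell offset", {
  prof <- small_profile()
  rec <- generate_recording(prof, 1, duration = 6, seed = 7)
  ft <- build_4d_features(rec, T = 3, grid = small_grid())
  # zero baseline map -> identity
  zero_map <- array(0, dim = c(9, 8, 4))
  expect_identical(subtract_baseline(ft, zero_map)$values, ft$values)
  # constant offset map is removed elementwise from every segment and section
  off <- array(runif(9 * 8 * 4), dim = c(9, 8, 4))
  adj <- subtract_baseline(ft, off)
  expect_equal(adj$values[2, , , , 3], ft$values[2, , , , 3] - off,
               tolerance = 1e-12)
  expect_error(subtract_baseline(ft, array(0, dim = c(9, 8, 3))), "dimensions")
})

test_that("a recording's own baseline is subtracted as its mean section DE", {
  prof <- small_profile()
  rec <- generate_recording(prof, 1, duration = 6, seed = 8)
  base <- generate_recording(prof, 1, duration = 3, seed = 9)
  rec_b <- eeg_recording(rec$samples, rec$sampling_rate, rec$channel_names,
                         baseline = base$samples)
  plain <- build_4d_features(rec_b, T = 3, grid = small_grid(),
                             use_baseline = FALSE)
  bmap <- baseline_de_map(rec_b, grid = small_grid())
  auto <- build_4d_features(rec_b, T = 3, grid = small_grid())
  expect_equal(auto$values, subtract_baseline(plain, bmap)$values,
               tolerance = 1e-12)
  # a baseline statistically identical to the trial nearly cancels the features
  rec_same <- eeg_recording(rec$samples, rec$sampling_rate, rec$channel_names,
                            baseline = rec$samples)
  adj <- build_4d_features(rec_same, T = 3, grid = small_grid())
  mapped <- adj$values[, 2:9, , , ][abs(adj$values[, 2:9, , , ]) > 0]
  expect_lt(mean(abs(mapped)), 0.2)
})

test_that("resampling preserves a band-limited signal", {
  fs <- 100
  tt <- (0:(fs * 4 - 1)) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 6 * tt)), fs)
  up <- resample_recording(rec, 200)
  expect_equal(ncol(up$samples), 800)
  tt2 <- (0:799) / 200
  mid <- 101:700  # away from filter edge effects
  expect_equal(up$samples[1, mid], sin(2 * pi * 10 * tt2)[mid], tolerance = 0.02)
})
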