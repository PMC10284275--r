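test_that("preprocessing removes powerline noise and preserves the passband", {
  fs <- 250
  tt <- seq_len(4 * fs) / fs
  line <- sin(2 * pi * 50 * tt)
  rec <- preprocess(signal_recording(cbind(line, line), fs))
  expect_lt(rms(rec$data[1, ]) / rms(line), 10^(-20 / 20))  # >= 20 dB down

  alpha <- sin(2 * pi * 10 * tt)
  rec2 <- preprocess(signal_recording(cbind(alpha, alpha), fs))
  expect_lt(abs(rms(rec2$data[1, ]) / rms(alpha) - 1), 0.05)

  zero <- preprocess(signal_recording(matrix(0, 2 * fs, 2), fs))
  expect_true(all(zero$data == 0))

  bad <- signal_recording(matrix(c(NA, rnorm(2 * fs * 2 - 1)), ncol = 2), fs)
  expect_error(preprocess(bad), "non-finite")
  expect_error(preprocess(signal_recording(matrix(rnorm(200), ncol = 2), 80)),
               "sampling rate too low")
})

test_that("band decomposition isolates sinusoids into their bands", {
  fs <- 250
  tt <- seq_len(3 * fs) / fs
  energy_by_band <- function(freq) {
    rec <- signal_recording(matrix(sin(2 * pi * freq * tt), ncol = 1), fs)
    banded <- band_decompose(rec)
    vapply(banded, function(m) sum(m^2), numeric(1))
  }
  e10 <- energy_by_band(10)
  expect_gt(e10[["alpha"]] / sum(e10), 0.95)
  e35 <- energy_by_band(35)
  expect_gt(e35[["gamma"]] / sum(e35), 0.95)

  zero <- band_decompose(signal_recording(matrix(0, fs, 1), fs))
  expect_true(all(vapply(zero, function(m) all(m == 0), logical(1))))

  expect_error(band_decompose(signal_recording(matrix(rnorm(fs), ncol = 1), fs),
                              bands = list(a = c(4, 10), b = c(8, 13))),
               "overlap")
  expect_error(eeg_bands(list(a = c(10, 4))), "low < high")
})

test_that("per-second power matches the closed form for sinusoids", {
  fs <- 250
  tt <- seq_len(1 * fs) / fs
  rec <- signal_recording(matrix(sin(2 * pi * 10 * tt), ncol = 1), fs)
  fm <- segment_power(band_decompose(rec), fs, "ch1")
  # sum of sin^2 over whole cycles = n/2 = 125
  expect_lt(abs(fm[1, "ch1_alpha"] - 125) / 125, 0.10)

  # one in-band sinusoid per band: each band's power near n * A^2 / 2
  amps <- c(theta = 1.5, alpha = 1, beta = 0.8, gamma = 0.6)
  freqs <- c(theta = 5.5, alpha = 10, beta = 20, gamma = 38)
  tt3 <- seq_len(3 * fs) / fs
  x <- rowSums(vapply(names(amps),
                      function(b) amps[[b]] * sin(2 * pi * freqs[[b]] * tt3),
                      numeric(length(tt3))))
  fm3 <- segment_power(band_decompose(signal_recording(matrix(x, ncol = 1), fs)),
                       fs, "ch1")
  for (b in names(amps)) {
    expected <- fs * amps[[b]]^2 / 2
    expect_lt(abs(fm3[2, paste0("ch1_", b)] - expected) / expected, 0.10)
  }
})

test_that("segmentation drops trailing partial seconds and orders channel-major", {
  fs <- 250
  x <- matrix(rnorm(32 * (3 * fs + 100)), nrow = 32)  # 3 s + partial
  rec <- eeg_recording("s", "v", x, paste0("c", 1:32), fs)
  fm <- eeg_features(rec)
  expect_identical(dim(unclass(fm)), c(3L, 128L))
  expect_true(all(fm >= 0))
  lab <- feature_labels(fm)
  expect_identical(lab$channel[1:4], rep("c1", 4))
  expect_identical(lab$band[1:8], rep(c("theta", "alpha", "beta", "gamma"), 2))
  expect_identical(colnames(fm)[1:2], c("c1_theta", "c1_alpha"))
  expect_error(segment_power(list(theta = x[, 1:100, drop = FALSE]), fs, paste0("c", 1:32)),
               "fewer than fs samples")
})

test_that("group averaging is the element-wise mean and validates labels", {
  fs <- 250
  mk <- function(seed) {
    set.seed(seed)
    eeg_features(eeg_recording("s", "v", matrix(rnorm(4 * 2 * fs), nrow = 4),
                               paste0("c", 1:4), fs))
  }
  a <- mk(1); b <- mk(2); c3 <- mk(3)
  expect_equal(group_average(list(a)), a)
  avg <- group_average(list(a, b))
  expect_equal(unclass(avg), (unclass(a) + unclass(b)) / 2,
               ignore_attr = TRUE)
  # permutation invariance
  expect_equal(group_average(list(a, b, c3)), group_average(list(c3, a, b)))
  bad <- a[, 1:8]
  expect_error(group_average(list(a, bad)), "differ in shape")
})

test_that("feature matrix and EEG delimited files round-trip", {
  fs <- 250
  set.seed(9)
  rec <- eeg_recording("sub7", "video2", matrix(rnorm(3 * 2 * fs), nrow = 3),
                       c("Fz", "Cz", "Pz"), fs)
  fm <- eeg_features(rec)
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, fpath)
  fm2 <- read_feature_matrix(fpath)
  expect_equal(unclass(fm2), unclass(fm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(feature_labels(fm2), feature_labels(fm))

  dpath <- withr::local_tempfile(fileext = ".csv")
  mpath <- withr::local_tempfile(fileext = ".json")
  write_eeg_delim(rec, dpath, mpath)
  rec2 <- read_eeg_delim(dpath, mpath)
  expect_equal(rec2$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rec2$channel_names, rec$channel_names)
  expect_identical(rec2$fs, rec$fs)
  expect_identical(rec2$participant_id, "sub7")
})
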