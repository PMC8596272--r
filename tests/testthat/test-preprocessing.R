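# Band-pass contract, epoch assembly, split halves, artifact flagging.

rms <- function(x) sqrt(mean(x^2))

test_that("passband and stopband behave as specified (FFT oracle)", {
  fs <- 250; t <- (0:4999) / fs
  s10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(s10, band_spec("alpha", 8, 13), fs)
  expect_lt(abs(rms(y10) / rms(s10) - 1), 0.05)
  expect_lt(abs(fft_amplitude(y10, 10, fs) / fft_amplitude(s10, 10, fs) - 1),
            0.05)
  s1 <- sin(2 * pi * 1 * t)
  y1 <- bandpass(s1, band_spec("alpha", 8, 13), fs)
  expect_lt(rms(y1) / rms(s1), 0.1)
  # one octave outside the band: >= 20 dB down
  s26 <- sin(2 * pi * 26 * t)
  expect_lt(rms(bandpass(s26, band_spec("alpha", 8, 13), fs)) / rms(s26), 0.1)
  expect_identical(bandpass(numeric(2000), band_spec("alpha", 8, 13), fs),
                   numeric(2000))
})

test_that("filtering is idempotent for in-band signals", {
  fs <- 250
  x <- gen_band_noise(0.5, c(9.5, 11.5), 6000, fs = fs, seed = 2L)
  y1 <- bandpass(x, band_spec("alpha", 8, 13), fs)
  y2 <- bandpass(y1, band_spec("alpha", 8, 13), fs)
  expect_lt(abs(rms(y2) - rms(y1)) / rms(y1), 0.02)
})

test_that("band and length validation", {
  expect_error(bandpass(rnorm(1000), c(10, 130), 250),
               class = "fe_param_error")
  expect_error(bandpass(rnorm(20), c(8, 13), 250), class = "fe_param_error")
  expect_error(band_spec("x", 5, 2), class = "fe_param_error")
  cb <- canonical_bands()
  expect_identical(names(cb), c("broadband", "slow", "alpha", "beta"))
  expect_identical(vapply(cb, function(b) c(b$low, b$high), numeric(2)),
                   matrix(c(2, 20, 2, 7, 8, 13, 14, 19), 2,
                          dimnames = list(NULL, names(cb))))
})

test_that("epoch assembly concatenates chronologically and exactly", {
  rec <- toy_recording()
  ep <- segment_by_state(rec, target_s = 60)
  expect_identical(vapply(ep, nrow, integer(1L)),
                   c(rest = 15000L, a = 15000L, b = 15000L))
  # state 'a' = its three 20 s intervals in order (onsets 90, 110, 130)
  idx <- c(90 * 250 + 1:5000, 110 * 250 + 1:5000, 130 * 250 + 1:5000)
  expect_identical(ep$a[, "C3"], rec$data[idx, "C3"])
  # rest = first 60 s of the 90 s interval
  expect_identical(ep$rest[, "C4"], rec$data[1:15000, "C4"])
  # schedule entry order is irrelevant
  rec2 <- rec
  rec2 <- set_schedule(rec2, rec$schedule[sample(nrow(rec$schedule)), ])
  ep2 <- segment_by_state(rec2, target_s = 60)
  expect_identical(ep2$a, ep$a)
})

test_that("insufficient material names the offending state", {
  rec <- toy_recording()
  err <- tryCatch(segment_by_state(rec, target_s = 70),
                  error = function(e) e)
  expect_s3_class(err, "fe_data_error")
  expect_match(conditionMessage(err), "'a'|'b'")
})

test_that("band-limited epochs are filtered before concatenation", {
  rec <- toy_recording()
  ep <- segment_by_state(rec, target_s = 60, band = canonical_bands()$alpha)
  # each 20 s piece equals the independently filtered interval's head
  piece <- bandpass(rec$data[90 * 250 + 1:5000, "C3"],
                    canonical_bands()$alpha, rec$fs)
  expect_equal(ep$a[1:5000, "C3"], piece, tolerance = 1e-12)
})

test_that("split_half partitions the epoch", {
  h <- split_half(1:15000)
  expect_identical(lengths(h), c(first = 7500L, second = 7500L))
  expect_identical(c(h$first, h$second), 1:15000)
  ho <- split_half(1:7)
  expect_identical(ho$first, 1:4)
  expect_identical(ho$second, 5:7)
})

test_that("artifact flags are maximal padded runs", {
  fs <- 250
  expect_identical(nrow(flag_artifacts(rnorm(1000, sd = 10), 200, fs)), 0L)
  x <- rnorm(5000, sd = 10); x[1000] <- 500
  fl <- flag_artifacts(x, 200, fs)
  expect_identical(nrow(fl), 1L)
  expect_true(fl$start <= 1000 && fl$end >= 1000)
  expect_identical(fl$end - fl$start, 2L * as.integer(0.1 * fs))
  # degenerate threshold flags everything nonzero
  fl0 <- flag_artifacts(c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 0,
                        fs = 10)
  expect_identical(nrow(fl0), 1L)
  expect_error(flag_artifacts(c(1, Inf)), class = "fe_param_error")
})
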