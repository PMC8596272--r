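# Synthetic signal generators: determinism, exact covariance, dimension
# targets.

test_that("generators are pure functions of their parameters and seed", {
  expect_identical(gen_fbm(0.7, 500, seed = 3L), gen_fbm(0.7, 500, seed = 3L))
  expect_false(identical(gen_fbm(0.7, 500, seed = 3L),
                         gen_fbm(0.7, 500, seed = 4L)))
  expect_identical(gen_band_noise(0.6, c(2, 20), 1000, seed = 9L),
                   gen_band_noise(0.6, c(2, 20), 1000, seed = 9L))
  expect_identical(gen_weierstrass(1.5, 300), gen_weierstrass(1.5, 300))
  # the ambient RNG stream is not disturbed by seeded calls
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_fbm(0.5, 100, seed = 77L)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("fGn has the exact fractional autocovariance", {
  # empirical covariance of many short draws vs the analytic fGn covariance
  n <- 48L; H <- 0.7
  draws <- vapply(1:1500, function(i) gen_fgn(H, n, seed = i),
                  numeric(n))
  emp <- stats::cov(t(draws))
  h <- 1:(n - 1)
  acv <- c(1, 0.5 * ((h + 1)^(2 * H) - 2 * h^(2 * H) + (h - 1)^(2 * H)))
  expect_lt(max(abs(emp - stats::toeplitz(acv))), 0.12)   # ~4x MC se
  expect_lt(mean(abs(emp - stats::toeplitz(acv))), 0.03)
})

test_that("fGn increments: zero lag-1 correlation at H = 0.5, zero mean", {
  r1 <- vapply(1:20, function(i) {
    x <- gen_fgn(0.5, 10000, seed = 100L + i)
    stats::cor(x[-1], x[-length(x)])
  }, numeric(1))
  expect_lt(max(abs(r1)), 0.05)
  for (H in c(0.2, 0.5, 0.8)) {
    n <- 20000L
    x <- gen_fgn(H, n, seed = 5L)
    # under long-range dependence sd(mean) scales as n^(H-1), not n^(-1/2)
    expect_lt(abs(mean(x)), 4 * n^(H - 1))
  }
})

test_that("fBm self-similarity: Var(X_t) grows like t^(2H)", {
  H <- 0.8; n <- 2^14
  t_idx <- round(seq(32, n, length.out = 12L))
  V <- matrix(0, 20L, length(t_idx))
  for (i in 1:20) V[i, ] <- gen_fbm(H, n, seed = 300L + i)[t_idx]^2
  slope <- stats::coef(stats::lm(log(colMeans(V)) ~ log(t_idx)))[[2L]]
  expect_lt(abs(slope - 2 * H), 0.2)
})

test_that("Weierstrass curve recovers its nominal dimension", {
  d <- higuchi_fd(gen_weierstrass(1.5, 15000), warn_range = FALSE)$fd
  expect_lt(abs(d - 1.5), 0.15)
  # single term is a pure cosine: a smooth curve with dimension 1
  d1 <- higuchi_fd(gen_weierstrass(1.5, 15000, n_terms = 1L),
                   warn_range = FALSE)$fd
  expect_lt(abs(d1 - 1), 0.1)
})

test_that("band noise respects its band and amplitude", {
  x <- gen_band_noise(0.5, c(8, 13), 5000, fs = 250, amplitude = 3,
                      seed = 21L)
  expect_lt(abs(stats::sd(x) - 3) / 3, 0.25)
  inband <- fft_amplitude(x, 10, 250)
  outband <- fft_amplitude(x, 40, 250)
  expect_gt(inband, 100 * max(outband, 1e-12))
})

test_that("generator parameter validation", {
  expect_error(gen_fbm(1.2, 100), class = "fe_param_error")
  expect_error(gen_fbm(0.5, 1), class = "fe_param_error")
  expect_error(gen_weierstrass(2.4, 100), class = "fe_param_error")
  expect_error(gen_band_noise(0.5, c(100, 130), 500, fs = 250),
               class = "fe_param_error")
  expect_error(fractal_signal_spec("fbm", 100, hurst = 0),
               class = "fe_param_error")
})

test_that("fractal_signal_spec dispatches all kinds", {
  expect_identical(gen_signal(fractal_signal_spec("line", 5, amplitude = 2)),
                   2 * (1:5))
  expect_identical(gen_signal(fractal_signal_spec("constant", 4,
                                                  amplitude = 7)),
                   rep(7, 4))
  sp <- fractal_signal_spec("fbm", 200, hurst = 0.6, seed = 8L)
  expect_identical(gen_signal(sp), gen_fbm(0.6, 200, seed = 8L))
  sp2 <- fractal_signal_spec("weierstrass", 200, fractal_dim = 1.3)
  expect_identical(gen_signal(sp2), gen_weierstrass(1.3, 200))
})
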