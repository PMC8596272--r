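# Synthetic signal generators with analytically known fractal structure.
#
# Three families:
#   * gen_fbm()         - exact-covariance fractional Brownian motion
#                         (circulant embedding of the fGn autocovariance);
#                         fractal dimension D = 2 - H.
#   * gen_weierstrass() - deterministic Weierstrass-type curve with known
#                         box dimension D.
#   * gen_band_noise()  - stationary Gaussian noise whose power spectrum is
#                         a power law f^-(2H+1) restricted to a frequency
#                         band; the in-band exponent controls roughness.

#' Fractional Brownian motion by circulant embedding
#'
#' Generates an fBm path as the cumulative sum of fractional Gaussian noise
#' (fGn) with the stated Hurst exponent.  The fGn is sampled exactly (to
#' machine precision) by the Davies-Harte circulant-embedding method, so the
#' increments have unit variance and exactly the fGn autocovariance
#' \eqn{\gamma(h) = ((h+1)^{2H} - 2h^{2H} + |h-1|^{2H})/2}.
#' The theoretical fractal dimension of the path is \eqn{D = 2 - H}.
#'
#' @param hurst Hurst exponent, strictly in (0, 1).
#' @param n Number of samples, at least 2.
#' @param seed Optional integer seed; the same `(hurst, n, seed, amplitude)`
#'   reproduces the identical vector and the caller's RNG stream is left
#'   untouched.  With `seed = NULL` the ambient RNG stream is consumed.
#' @param amplitude Scale factor applied to the increments (microvolts when
#'   used to emulate EEG).
#' @return Numeric vector of length `n`.
#' @export
gen_fbm <- function(hurst, n, seed = NULL, amplitude = 1) {
  stopifnot_prob_open(hurst, "hurst")
  stopifnot_scalar_count(n, "n", min = 2L)
  amplitude * cumsum(gen_fgn(hurst, n, seed))
}

#' Fractional Gaussian noise (exact covariance)
#'
#' The increment process of [gen_fbm()]; exposed because stationary noise is
#' the natural building block for epoch-level tests.
#'
#' @inheritParams gen_fbm
#' @return Numeric vector of length `n` with unit marginal variance.
#' @export
gen_fgn <- function(hurst, n, seed = NULL) {
  stopifnot_prob_open(hurst, "hurst")
  stopifnot_scalar_count(n, "n", min = 2L)
  h <- seq_len(n)
  acv <- c(1, 0.5 * ((h + 1)^(2 * hurst) - 2 * h^(2 * hurst) +
                       (h - 1)^(2 * hurst)))
  m <- 2L * n
  lambda <- Re(stats::fft(c(acv[1:n], acv[n + 1L], acv[n:2])))
  if (any(lambda < -1e-8 * max(lambda))) {
    fe_stop("fe_param_error",
            "circulant embedding is not nonnegative definite for this input")
  }
  lambda[lambda < 0] <- 0
  z <- with_seed_opt(seed, stats::rnorm(m))
  a <- complex(length.out = m)
  a[1L] <- sqrt(lambda[1L] / m) * z[1L]
  a[n + 1L] <- sqrt(lambda[n + 1L] / m) * z[2L]
  k <- seq_len(n - 1L)
  ak <- sqrt(lambda[k + 1L] / (2 * m)) * complex(real = z[2L + k],
                                                 imaginary = z[n + 1L + k])
  a[1L + k] <- ak
  a[m + 1L - k] <- Conj(ak)
  Re(stats::fft(a))[1:n]
}

#' Weierstrass-type curve with known fractal dimension
#'
#' \eqn{W(t) = \sum_{j=0}^{m-1} b^{-jH} \cos(2\pi b^j t)} with
#' \eqn{H = 2 - D} and fixed base `b > 1`.  The curve's graph has box
#' dimension `fractal_dim`; the construction is deterministic (no seed).
#' By default the series is truncated once the component frequency exceeds
#' the Nyquist rate, since faster terms cannot be represented at `fs`.
#'
#' @param fractal_dim Target dimension, strictly in (1, 2).
#' @param n Number of samples.
#' @param fs Sampling rate in Hz; component frequencies are `b^j` Hz on the
#'   time grid `t = (0:(n-1))/fs`.
#' @param n_terms Number of cosine terms; default is the count of components
#'   at or below Nyquist (12 for `fs = 250`, `b = 1.5`).
#' @param b Frequency ratio between successive terms (`> 1`).
#' @param amplitude Scale factor.
#' @return Numeric vector of length `n`.
#' @export
gen_weierstrass <- function(fractal_dim, n, fs = 250, n_terms = NULL,
                            b = 1.5, amplitude = 1) {
  if (!is.numeric(fractal_dim) || length(fractal_dim) != 1L ||
      !is.finite(fractal_dim) || fractal_dim <= 1 || fractal_dim >= 2) {
    fe_stop("fe_param_error", "`fractal_dim` must lie strictly in (1, 2)")
  }
  stopifnot_scalar_count(n, "n", min = 2L)
  if (!is.numeric(b) || length(b) != 1L || b <= 1) {
    fe_stop("fe_param_error", "`b` must be > 1")
  }
  if (is.null(n_terms)) n_terms <- max(10L, floor(log(fs / 2, base = b)) + 1L)
  stopifnot_scalar_count(n_terms, "n_terms", min = 1L)
  hex <- 2 - fractal_dim
  t <- (0:(n - 1L)) / fs
  w <- numeric(n)
  for (j in 0:(n_terms - 1L)) {
    w <- w + b^(-j * hex) * cos(2 * pi * b^j * t)
  }
  amplitude * w
}

#' Band-limited power-law Gaussian noise
#'
#' Stationary Gaussian noise whose power spectral density is
#' \eqn{S(f) \propto f^{-(2H+1)}} for `f` inside `band` and zero outside,
#' synthesized in the frequency domain on the DFT grid.  Within its band
#' this mimics the spectral tilt of fractional noise: smaller `hurst` means
#' a flatter in-band spectrum and a rougher (higher-dimensional) signal.
#' Because the Higuchi dimension is amplitude-invariant, the band-filtered
#' complexity of such a signal is governed by `hurst` alone.
#'
#' @inheritParams gen_fbm
#' @param band Length-2 numeric `(low, high)` in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param amplitude Standard deviation of the output (microvolts).
#' @return Numeric vector of length `n`.
#' @export
gen_band_noise <- function(hurst, band, n, fs = 250, amplitude = 1,
                           seed = NULL) {
  stopifnot_prob_open(hurst, "hurst")
  stopifnot_scalar_count(n, "n", min = 8L)
  check_band_edges(band[1L], band[2L], fs)
  tpl <- spectral_template(n, fs,
                           sub_lo = band[1L], sub_hi = band[2L],
                           hurst_in = hurst, power = 1)
  # template power 1 => theoretical variance 1; amplitude sets the SD
  amplitude * drop(synth_block(n, templates = list(tpl), cols = 1L, seed = seed))
}

#' Declarative synthetic-signal specification
#'
#' Bundles the parameters of one synthetic signal so generation is a pure
#' function of the spec.  `kind` selects the generator: `"fbm"` (`hurst`),
#' `"weierstrass"` (`fractal_dim`, via \eqn{D = 2 - H}), `"band_noise"`
#' (`hurst` + `band`), `"line"` and `"constant"` (degenerate references).
#'
#' @param kind One of `"fbm"`, `"weierstrass"`, `"band_noise"`, `"line"`,
#'   `"constant"`.
#' @param length Sample count.
#' @param fs Sampling rate in Hz.
#' @param amplitude Scale factor (microvolts).
#' @param hurst,fractal_dim,band,seed,n_terms Generator-specific parameters;
#'   see the individual generators.
#' @return Object of class `fractal_signal_spec`.
#' @seealso [gen_signal()]
#' @export
fractal_signal_spec <- function(kind, length, fs = 250, amplitude = 1,
                                hurst = NULL, fractal_dim = NULL, band = NULL,
                                seed = NULL, n_terms = NULL) {
  kind <- match.arg(kind, c("fbm", "weierstrass", "band_noise", "line",
                            "constant"))
  stopifnot_scalar_count(length, "length", min = 2L)
  if (kind %in% c("fbm", "band_noise")) stopifnot_prob_open(hurst, "hurst")
  if (kind == "weierstrass" &&
      (is.null(fractal_dim) || fractal_dim <= 1 || fractal_dim >= 2)) {
    fe_stop("fe_param_error", "`fractal_dim` must lie strictly in (1, 2)")
  }
  if (kind == "band_noise") check_band_edges(band[1L], band[2L], fs)
  structure(list(kind = kind, length = as.integer(length), fs = fs,
                 amplitude = amplitude, hurst = hurst,
                 fractal_dim = fractal_dim, band = band, seed = seed,
                 n_terms = n_terms),
            class = "fractal_signal_spec")
}

#' Generate the signal described by a [fractal_signal_spec()]
#'
#' @param spec A `fractal_signal_spec`.
#' @return Numeric vector of length `spec$length`.
#' @export
gen_signal <- function(spec) {
  if (!inherits(spec, "fractal_signal_spec")) {
    fe_stop("fe_param_error", "`spec` must be a fractal_signal_spec")
  }
  switch(spec$kind,
    fbm = gen_fbm(spec$hurst, spec$length, seed = spec$seed,
                  amplitude = spec$amplitude),
    weierstrass = gen_weierstrass(spec$fractal_dim, spec$length, fs = spec$fs,
                                  n_terms = spec$n_terms,
                                  amplitude = spec$amplitude),
    band_noise = gen_band_noise(spec$hurst, spec$band, spec$length,
                                fs = spec$fs, amplitude = spec$amplitude,
                                seed = spec$seed),
    line = spec$amplitude * seq_len(spec$length),
    constant = rep(spec$amplitude, spec$length)
  )
}

check_band_edges <- function(low, high, fs) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high) ||
      low <= 0 || high <= low || high >= fs / 2) {
    fe_stop("fe_param_error",
            sprintf("band edges must satisfy 0 < low < high < fs/2 = %g", fs / 2))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Frequency-domain synthesis kernel.
#
# A template describes the amplitude spectrum of one signal class on the DFT
# grid of length n: positive-frequency bin indices `bins` (DFT index j,
# frequency j*fs/n) and coefficient scales `a` such that a synthesized signal
# x_t = 2 Re sum_j a_j (xi_j + i eta_j) e^{2 pi i j t / n} has variance
# sum_j 4 a_j^2 (xi, eta iid standard normal).

# Amplitude template for one power-law sub-band, optionally weighted so the
# band's total power matches `power`.
spectral_template <- function(n, fs, sub_lo, sub_hi, hurst_in, power) {
  j <- seq_len(floor((n - 1) / 2))
  f <- j * fs / n
  keep <- f >= sub_lo & f < sub_hi
  if (!any(keep)) {
    fe_stop("fe_param_error",
            sprintf("band [%g, %g) Hz contains no DFT bin at n = %d, fs = %g",
                    sub_lo, sub_hi, n, fs))
  }
  j <- j[keep]; f <- f[keep]
  shape <- f^(-(2 * hurst_in + 1))
  a2 <- shape / sum(shape) * power / 4
  list(bins = j, a = sqrt(a2))
}

# Integral of f^-(2H+1) over [lo, hi): relative power carried by a sub-band
# under a broadband power-law tilt with Hurst exponent H.
powerlaw_band_power <- function(lo, hi, hurst) {
  (lo^(-2 * hurst) - hi^(-2 * hurst)) / (2 * hurst)
}

# Synthesize `cols[i]` independent real signals from templates[[i]], all of
# length n, via one batched inverse FFT.  Two real signals are packed per
# complex column (real/imaginary parts), halving the transform work.
# Output variance equals sum(4 a^2) per template; callers rescale.
synth_block <- function(n, templates, cols, seed = NULL) {
  stopifnot(length(templates) == length(cols))
  total <- sum(cols)
  tpl_of_col <- rep(seq_along(templates), times = cols)
  nb <- vapply(templates, function(t) length(t$bins), integer(1L))
  z <- with_seed_opt(seed, stats::rnorm(2L * sum(nb[tpl_of_col])))
  np <- ceiling(total / 2)
  spec <- matrix(0 + 0i, n, np)
  pos <- 0L
  coefs <- vector("list", total)
  for (cc in seq_len(total)) {
    t <- templates[[tpl_of_col[cc]]]
    m <- length(t$bins)
    coefs[[cc]] <- t$a * complex(real = z[pos + seq_len(m)],
                                 imaginary = z[pos + m + seq_len(m)])
    pos <- pos + 2L * m
  }
  for (p in seq_len(np)) {
    c1 <- coefs[[2L * p - 1L]]
    b1 <- templates[[tpl_of_col[2L * p - 1L]]]$bins
    if (2L * p <= total) {
      c2 <- coefs[[2L * p]]
      b2 <- templates[[tpl_of_col[2L * p]]]$bins
    } else {
      c2 <- complex(0); b2 <- integer(0)
    }
    # accumulate the two packed spectra: top rows get c, bottom rows Conj(c)
    spec[b1 + 1L, p] <- spec[b1 + 1L, p] + c1
    spec[n + 1L - b1, p] <- spec[n + 1L - b1, p] + Conj(c1)
    if (length(b2)) {
      spec[b2 + 1L, p] <- spec[b2 + 1L, p] + 1i * c2
      spec[n + 1L - b2, p] <- spec[n + 1L - b2, p] + 1i * Conj(c2)
    }
  }
  y <- stats::mvfft(spec, inverse = TRUE)
  out <- matrix(0, n, total)
  for (cc in seq_len(total)) {
    p <- ceiling(cc / 2)
    out[, cc] <- if (cc %% 2L == 1L) Re(y[, p]) else Im(y[, p])
  }
  out
}
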