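# Independent oracles and small fixtures used across the suite.

# Naive double-loop Higuchi curve lengths, written directly from the
# defining formula (1-based indices, no vectorization); the production
# kernel must agree to 1e-10.
oracle_curve_lengths <- function(x, k_max) {
  n <- length(x)
  L <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      M <- floor((n - m) / k)
      s <- 0
      for (i in seq_len(M)) {
        s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      }
      Lm[m] <- (1 / k) * s * (n - 1) / (M * k)
    }
    L[k] <- mean(Lm)
  }
  L
}

oracle_hfd <- function(x, k_max = 8L) {
  L <- oracle_curve_lengths(x, k_max)
  stats::coef(stats::lm(log(L) ~ log(1 / seq_len(k_max))))[[2L]]
}

# Brute-force Wilks' lambda for a one-way layout: explicit SSCP matrices and
# determinant ratio, plus the eigenvalue route det identity.
oracle_wilks <- function(Y, group) {
  group <- factor(group)
  grand <- colMeans(Y)
  p <- ncol(Y)
  E <- matrix(0, p, p); H <- matrix(0, p, p)
  for (lev in levels(group)) {
    Yg <- Y[group == lev, , drop = FALSE]
    mg <- colMeans(Yg)
    E <- E + t(Yg - rep(1, nrow(Yg)) %*% t(mg)) %*%
      (Yg - rep(1, nrow(Yg)) %*% t(mg))
    H <- H + nrow(Yg) * (mg - grand) %*% t(mg - grand)
  }
  list(det_ratio = det(E) / det(E + H),
       eigen = prod(1 / (1 + Re(eigen(solve(E) %*% H)$values))))
}

# Amplitude of the frequency component nearest `freq` via the FFT.
fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  bin <- round(freq * n / fs) + 1L
  sp[bin]
}

# Reduced cohort design: full protocol structure but shorter stimulus
# streams, for fast structural tests (not used by the acceptance criteria).
small_design <- function(n = c(control = 1, mild_dai = 1, severe_dai = 1),
                         effects = "default", seed = 11L, ...) {
  cohort_design(n_subjects = n, effects = effects, repetitions = 6L,
                rest_duration_s = 60, gap_s = 0.5, seed = seed, ...)
}

# Hand-built recording: known content per state so epoch assembly is
# verifiable sample by sample.
toy_recording <- function(fs = 250) {
  states <- c("rest", "a", "b")
  sch <- data.frame(
    state = c("rest", rep(c("a", "b"), each = 3L)),
    onset = c(0, 90, 110, 130, 150, 170, 190),
    duration = c(90, rep(20, 6L))
  )
  n <- 210 * fs
  set.seed(42)
  data <- matrix(rnorm(n * 2L), n, 2L)
  eeg_recording(data, fs, c("C3", "C4"), schedule = sch)
}
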