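# Band-pass filtering and epoch assembly.
#
# Filter: 4th-order Butterworth band-pass applied forward-backward
# (zero-phase), implemented as a cascade of second-order sections with
# steady-state initial conditions and odd reflection padding.  Zero-phase
# filtering preserves waveform shape, which matters because the Higuchi
# dimension is computed from raw amplitude differences.

#' Frequency band specification
#'
#' @param name Band label.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(name, low, high) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    fe_stop("fe_param_error", "`name` must be a non-empty string")
  }
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low) {
    fe_stop("fe_param_error", "band edges must satisfy 0 < low < high")
  }
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' The canonical analysis bands
#'
#' Broadband 2-20 Hz plus the three clinical sub-bands analysed by the
#' pipeline: slow-wave 2-7 Hz, alpha 8-13 Hz, beta 14-19 Hz.
#'
#' @return Named list of [band_spec()] objects.
#' @export
canonical_bands <- function() {
  list(broadband = band_spec("broadband", 2, 20),
       slow      = band_spec("slow", 2, 7),
       alpha     = band_spec("alpha", 8, 13),
       beta      = band_spec("beta", 14, 19))
}

# Butterworth band-pass as second-order sections (matrix ns x 6:
# b0 b1 b2 1 a1 a2).  Analog prototype poles -> analog band transform ->
# bilinear transform; n zeros at z = +1 and n at z = -1; unit gain at the
# (warped) band centre.
butter_bandpass_sos <- function(low, high, fs, order = 4L) {
  check_band_edges(low, high, fs)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * order)))
  pb <- proto * bw
  disc <- sqrt(pb^2 - 4 * w0^2)
  s_poles <- c((pb + disc) / 2, (pb - disc) / 2)
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  # pair each pole with its complex conjugate
  up <- z_poles[Im(z_poles) > 1e-12]
  re <- sort(Re(z_poles[abs(Im(z_poles)) <= 1e-12]))
  ns <- order
  sos <- matrix(0, ns, 6L)
  sec <- 1L
  for (p in up) {
    sos[sec, ] <- c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
    sec <- sec + 1L
  }
  while (length(re) >= 2L) {
    p1 <- re[1L]; p2 <- re[2L]; re <- re[-(1:2)]
    sos[sec, ] <- c(1, 0, -1, 1, -(p1 + p2), p1 * p2)
    sec <- sec + 1L
  }
  stopifnot(sec == ns + 1L)
  # normalize to unit gain at the warped centre frequency
  f0 <- atan(w0 / fs2) * fs / pi
  z0 <- exp(2i * pi * f0 / fs)
  h <- prod(vapply(seq_len(ns), function(s) {
    num <- sos[s, 1L] * z0^2 + sos[s, 2L] * z0 + sos[s, 3L]
    den <- z0^2 + sos[s, 5L] * z0 + sos[s, 6L]
    Mod(num / den)
  }, numeric(1L)))
  sos[, 1:3] <- sos[, 1:3] * (1 / h)^(1 / ns)
  sos
}

# Steady-state (unit step) internal state per section, plus the cumulative
# DC gains needed to scale the state for the actual boundary value.
sosfilt_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2L)
  gain <- 1
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    g <- sum(b) / sum(a)
    zi[s, 1L] <- gain * (g - b[1L])
    zi[s, 2L] <- gain * (b[3L] - a[3L] * g)
    gain <- gain * g
  }
  zi
}

# Zero-phase filtering: odd extension, forward pass, backward pass, trim.
# Columns of a matrix are filtered independently; padlen >= n is rejected
# upstream.
sosfiltfilt <- function(x, sos, padlen, zi = sosfilt_zi(sos)) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  y <- .sosfiltfilt_mat_cpp(x, sos, zi, as.integer(padlen))
  if (vec) drop(y) else y
}

#' Zero-phase band-pass filter
#'
#' Filters `x` with a 4th-order Butterworth band-pass applied
#' forward-backward, so the output has zero phase distortion and squared
#' magnitude response.  Passband gain at the band centre is within a few
#' percent of unity; attenuation one octave outside the band exceeds 20 dB.
#'
#' @param x Numeric vector (or samples x channels matrix).
#' @param band A [band_spec()] or numeric `c(low, high)` in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, band, fs, order = 4L) {
  if (inherits(band, "band_spec")) band <- c(band$low, band$high)
  sos <- butter_bandpass_sos(band[1L], band[2L], fs, order = order)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  padlen <- filter_padlen(fs, band[1L], order)
  if (n <= max(padlen, 3L * (2L * order + 1L))) {
    fe_stop("fe_param_error",
            sprintf("input too short to filter: %d samples (need > %d)",
                    n, max(padlen, 3L * (2L * order + 1L))))
  }
  y <- sosfiltfilt(x, sos, padlen)
  if (is.matrix(x)) dimnames(y) <- dimnames(x)
  y
}

# Reflection pad long enough for edge transients of the low band edge.
filter_padlen <- function(fs, low, order) {
  max(3L * (2L * order + 1L), as.integer(round(fs / low)))
}

#' Assemble per-state epochs of fixed duration
#'
#' For every state in the recording's schedule, concatenates that state's
#' scheduled intervals in chronological order and truncates to exactly
#' `target_s` seconds (the chronologically first material is used).  When a
#' band is given, each contributing interval is band-pass filtered *before*
#' concatenation, so filter transients from interval boundaries never enter
#' the epoch interior.
#'
#' @param rec An [eeg_recording()] with a schedule.
#' @param target_s Epoch duration in seconds (default 60).
#' @param band Optional [band_spec()]; `NULL` keeps the raw signal.
#' @param channels Channel labels to include (default: all).
#' @return An `epoch_set`: named list mapping state to a
#'   `(target_s * fs) x channels` matrix, with `fs`, `band`, and
#'   `provenance` attributes.
#' @export
segment_by_state <- function(rec, target_s = 60, band = NULL,
                             channels = NULL) {
  if (!inherits(rec, "eeg_recording") || is.null(rec$schedule)) {
    fe_stop("fe_param_error", "`rec` must be an eeg_recording with a schedule")
  }
  channels <- channels %||% rec$channel_labels
  ch_idx <- match(channels, rec$channel_labels)
  if (anyNA(ch_idx)) {
    fe_stop("fe_param_error", "unknown channel label requested")
  }
  fs <- rec$fs
  target_n <- as.integer(round(target_s * fs))
  sch <- rec$schedule[order(rec$schedule$onset), , drop = FALSE]
  states <- unique(sch$state)
  sos <- NULL; padlen <- NULL; zi <- NULL
  if (!is.null(band)) {
    if (!inherits(band, "band_spec")) band <- band_spec("band", band[1L], band[2L])
    sos <- butter_bandpass_sos(band$low, band$high, fs)
    padlen <- filter_padlen(fs, band$low, 4L)
    zi <- sosfilt_zi(sos)
  }
  out <- vector("list", length(states))
  names(out) <- states
  provenance <- vector("list", length(states))
  names(provenance) <- states
  for (st in states) {
    rows <- sch[sch$state == st, , drop = FALSE]
    starts <- as.integer(round(rows$onset * fs)) + 1L
    lens <- as.integer(round(rows$duration * fs))
    avail <- sum(lens)
    if (avail < target_n) {
      fe_stop("fe_data_error",
              sprintf("insufficient material for state '%s': %.1f s < %.1f s",
                      st, avail / fs, target_s))
    }
    need <- target_n
    epoch <- matrix(NA_real_, target_n, length(channels))
    used <- numeric(0)
    for (i in seq_along(starts)) {
      if (need <= 0L) break
      seg <- rec$data[starts[i]:(starts[i] + lens[i] - 1L), ch_idx,
                      drop = FALSE]
      if (!is.null(sos)) {
        if (nrow(seg) <= padlen) {
          fe_stop("fe_data_error",
                  sprintf("interval of state '%s' too short to filter (%d samples)",
                          st, nrow(seg)))
        }
        seg <- sosfiltfilt(seg, sos, padlen, zi = zi)
      }
      take <- min(nrow(seg), need)
      epoch[(target_n - need) + seq_len(take), ] <- seg[seq_len(take), ]
      used <- c(used, take / fs)
      need <- need - take
    }
    colnames(epoch) <- channels
    out[[st]] <- epoch
    provenance[[st]] <- data.frame(
      onset = rows$onset[seq_along(used)],
      duration = rows$duration[seq_along(used)],
      used_s = used
    )
  }
  structure(out, class = "epoch_set", fs = fs,
            band = if (is.null(band)) NA_character_ else band$name,
            target_s = target_s, provenance = provenance)
}

#' Split an epoch into two consecutive halves
#'
#' Used for the split-half stability control: the statistic of interest is
#' computed on two consecutive halves (e.g. 30 s each of a 60 s epoch) to
#' rule out drift or fatigue effects.  For odd lengths the first half
#' receives the extra sample (documented behaviour, not an error).
#'
#' @param x Numeric vector.
#' @return List with elements `first` and `second`; concatenating them
#'   reproduces `x`.
#' @export
split_half <- function(x) {
  n <- length(x)
  if (n < 2L) fe_stop("fe_param_error", "need at least 2 samples to split")
  cut <- ceiling(n / 2)
  list(first = x[seq_len(cut)], second = x[(cut + 1L):n])
}

#' Flag high-amplitude intervals
#'
#' Minimal amplitude-threshold artifact screen: maximal runs where
#' `|x| > threshold_uv`, padded by 0.1 s on both sides and merged.  The
#' result is informational - the pipeline warns but never excises samples,
#' so epoch lengths stay exact.
#'
#' @param x Numeric vector in microvolts.
#' @param threshold_uv Absolute amplitude threshold (default 200).
#' @param fs Sampling rate in Hz (for the 0.1 s padding).
#' @return Data frame with columns `start`, `end` (sample indices of the
#'   flagged intervals); zero rows when nothing exceeds the threshold.
#' @export
flag_artifacts <- function(x, threshold_uv = 200, fs = 250) {
  if (any(!is.finite(x))) {
    fe_stop("fe_param_error", "`x` must contain only finite samples")
  }
  bad <- abs(x) > threshold_uv
  if (!any(bad)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  pad <- as.integer(round(0.1 * fs))
  s <- pmax(1L, starts[keep] - pad)
  e <- pmin(length(x), ends[keep] + pad)
  # merge overlapping padded runs
  ms <- s[1L]; me <- e[1L]; out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= me + 1L) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
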