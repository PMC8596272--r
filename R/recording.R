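# Recording container, stimulus schedule and the lateralized 10-20 montage.

#' Standard 10-20 channel labels used by the pipeline
#'
#' The 19 scalp electrodes of the international 10-20 layout, in the
#' conventional anterior-to-posterior order.  The three midline electrodes
#' (`Fz`, `Cz`, `Pz`) are recorded but excluded from the lateralized
#' analysis.
#'
#' @return Character vector of 19 channel labels.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Homologous left/right electrode pairs
#'
#' The 16 lateral channels grouped into 8 left/right pairs, ordered
#' anterior to posterior.  The pair index is the "locus" used in the
#' lateralized group analysis.
#'
#' @return Data frame with columns `locus`, `left`, `right`.
#' @export
montage_pairs <- function() {
  data.frame(
    locus = 1:8,
    left  = c("Fp1", "F7", "F3", "T3", "C3", "T5", "P3", "O1"),
    right = c("Fp2", "F8", "F4", "T4", "C4", "T6", "P4", "O2"),
    stringsAsFactors = FALSE
  )
}

#' Stimulus schedule constructor
#'
#' A schedule is a set of labelled half-open intervals
#' `[onset, onset + duration)` in seconds from recording start.  Intervals
#' must not overlap; gaps between intervals are permitted (and are never
#' analysed).
#'
#' @param state Character vector of state labels (e.g. `"rest"`, `"laughter"`).
#' @param onset Numeric vector of onsets in seconds, `>= 0`.
#' @param duration Numeric vector of durations in seconds, `> 0`.
#' @return A `data.frame` of class `stim_schedule`, sorted by onset.
#' @export
stim_schedule <- function(state, onset, duration) {
  if (length(state) != length(onset) || length(onset) != length(duration)) {
    fe_stop("fe_validation_error", "schedule columns must have equal length")
  }
  if (length(state) == 0L) {
    fe_stop("fe_validation_error", "schedule must contain at least one entry")
  }
  onset <- as.numeric(onset); duration <- as.numeric(duration)
  if (any(!is.finite(onset)) || any(!is.finite(duration)) ||
      any(onset < 0) || any(duration <= 0)) {
    fe_stop("fe_validation_error",
            "schedule onsets must be >= 0 and durations > 0")
  }
  ord <- order(onset)
  sch <- data.frame(state = as.character(state)[ord], onset = onset[ord],
                    duration = duration[ord], stringsAsFactors = FALSE)
  ends <- sch$onset + sch$duration
  if (nrow(sch) > 1L && any(sch$onset[-1L] < ends[-nrow(sch)] - 1e-9)) {
    fe_stop("fe_validation_error", "schedule intervals overlap")
  }
  class(sch) <- c("stim_schedule", "data.frame")
  sch
}

#' Multichannel EEG recording container
#'
#' @param data Numeric matrix, samples in rows, channels in columns
#'   (microvolts).  A plain numeric vector is treated as one channel.
#' @param fs Sampling rate in Hz (250 in the study design this package
#'   emulates).
#' @param channel_labels Character vector of unique channel labels, one per
#'   column of `data`.
#' @param schedule Optional [stim_schedule()]; every interval must fall
#'   inside the recording.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, schedule = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data) || nrow(data) < 1L) {
    fe_stop("fe_validation_error", "`data` must be a numeric samples x channels matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    fe_stop("fe_validation_error", "`fs` must be a positive sampling rate in Hz")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(data)) {
    fe_stop("fe_validation_error", "one label per channel is required")
  }
  if (anyDuplicated(channel_labels)) {
    fe_stop("fe_validation_error", "channel labels must be unique")
  }
  if (!identical(colnames(data), channel_labels)) {
    colnames(data) <- channel_labels    # skipped when pre-named: avoids a copy
  }
  rec <- structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         schedule = NULL),
    class = "eeg_recording"
  )
  if (!is.null(schedule)) rec <- set_schedule(rec, schedule)
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (!is.null(x$schedule)) {
    cat(sprintf("  schedule: %d intervals, states: %s\n", nrow(x$schedule),
                paste(unique(x$schedule$state), collapse = ", ")))
  }
  invisible(x)
}

#' Attach a stimulus schedule to a recording
#'
#' @param rec An [eeg_recording()].
#' @param schedule A [stim_schedule()] or data frame with columns
#'   `state`, `onset`, `duration`.
#' @return The recording with the validated schedule attached.
#' @export
set_schedule <- function(rec, schedule) {
  if (!inherits(rec, "eeg_recording")) {
    fe_stop("fe_param_error", "`rec` must be an eeg_recording")
  }
  if (!inherits(schedule, "stim_schedule")) {
    schedule <- stim_schedule(schedule$state, schedule$onset, schedule$duration)
  }
  dur <- nrow(rec$data) / rec$fs
  if (any(schedule$onset + schedule$duration > dur + 1e-9)) {
    fe_stop("fe_validation_error",
            "schedule interval extends beyond the end of the recording")
  }
  rec$schedule <- schedule
  rec
}

#' Lateralized montage view of a recording
#'
#' Maps each of the 16 lateral 10-20 channels to its hemisphere and locus
#' (homologous pair index 1-8, anterior to posterior).  Midline channels
#' (`Fz`, `Cz`, `Pz`) are excluded by design; any other extra channels
#' (e.g. oculogram leads) are ignored.
#'
#' @param rec An [eeg_recording()] or a character vector of channel labels.
#' @return Data frame with columns `channel`, `hemisphere` (`"left"` or
#'   `"right"`) and `locus` (integer 1-8), one row per lateral channel
#'   present, in pair order.
#' @export
montage_views <- function(rec) {
  labels <- if (inherits(rec, "eeg_recording")) rec$channel_labels
            else as.character(rec)
  pairs <- montage_pairs()
  map <- data.frame(
    channel = c(rbind(pairs$left, pairs$right)),
    hemisphere = rep(c("left", "right"), times = nrow(pairs)),
    locus = rep(pairs$locus, each = 2L),
    stringsAsFactors = FALSE
  )
  missing <- setdiff(map$channel, labels)
  if (length(missing)) {
    fe_stop("fe_validation_error",
            sprintf("lateral channel(s) missing from recording: %s",
                    paste(missing, collapse = ", ")))
  }
  map
}
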