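# EDF (European Data Format) reading and writing, plus a documented
# plain-text matrix dialect as a transparent fallback.
#
# Writing: plain EDF, one 1 s data record per second, 16-bit samples with a
# symmetric physical range covering the data; the final record is
# zero-padded when the recording is not a whole number of seconds.
# Reading: honors the per-signal physical/digital scaling in the header.
# An "EDF Annotations" signal (EDF+), if present, is skipped as a data
# channel; schedules travel in a tab-separated sidecar file.

#' Path of the schedule sidecar for a recording file
#'
#' @param path Recording file path.
#' @return `<path without extension>_schedule.tsv`.
#' @export
schedule_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_schedule.tsv")
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write a recording to disk
#'
#' EDF output for `.edf` paths, the plain-text dialect for anything else
#' (first line `#fs <TAB> <Hz>`, second line tab-separated channel labels,
#' then one row of microvolt samples per time point).  The stimulus
#' schedule, when present, is written to the [schedule_path()] sidecar.
#'
#' @param rec An [eeg_recording()] with finite samples.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) {
    fe_stop("fe_validation_error", "`rec` must be an eeg_recording")
  }
  if (nrow(rec$data) == 0L || ncol(rec$data) == 0L) {
    fe_stop("fe_validation_error", "refusing to write an empty recording")
  }
  if (any(!is.finite(rec$data))) {
    fe_stop("fe_validation_error", "recording contains non-finite samples")
  }
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    atomic_write(path, function(tmp) write_edf_impl(rec, tmp))
  } else {
    atomic_write(path, function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines(sprintf("#fs\t%.10g", rec$fs), con)
      writeLines(paste(rec$channel_labels, collapse = "\t"), con)
      utils::write.table(format(rec$data, trim = TRUE, digits = 8), con,
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    })
  }
  if (!is.null(rec$schedule)) {
    write_tsv_atomic(as.data.frame(unclass(rec$schedule)), schedule_path(path))
  }
  invisible(path)
}

write_edf_impl <- function(rec, path) {
  data <- rec$data
  fs <- rec$fs
  nch <- ncol(data)
  spr <- as.integer(round(fs))            # samples per 1 s record
  if (abs(spr - fs) > 1e-9) {
    fe_stop("fe_validation_error", "EDF writer requires an integer sampling rate")
  }
  n <- nrow(data)
  n_rec <- as.integer(ceiling(n / spr))
  pmax_ <- max(max(abs(data)), 1e-6) * 1.0001
  pmin_ <- -pmax_
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8L)
  wr("synthetic subject", 80L)
  wr("fractalEEG recording", 80L)
  wr("01.01.20", 8L); wr("00.00.00", 8L)
  wr(256L * (1L + nch), 8L)
  wr("", 44L)
  wr(n_rec, 8L)
  wr("1", 8L)
  wr(nch, 4L)
  for (lab in rec$channel_labels) wr(lab, 16L)
  for (i in seq_len(nch)) wr("EEG electrode", 80L)
  for (i in seq_len(nch)) wr("uV", 8L)
  for (i in seq_len(nch)) wr(formatC(pmin_, format = "g", digits = 6), 8L)
  for (i in seq_len(nch)) wr(formatC(pmax_, format = "g", digits = 6), 8L)
  for (i in seq_len(nch)) wr(dmin, 8L)
  for (i in seq_len(nch)) wr(dmax, 8L)
  for (i in seq_len(nch)) wr("", 80L)
  for (i in seq_len(nch)) wr(spr, 8L)
  for (i in seq_len(nch)) wr("", 32L)
  # digital conversion; pad the tail of the last record with physical zero
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  to_dig <- function(x) as.integer(round((x - pmin_) * scale) + dmin)
  pad <- n_rec * spr - n
  if (pad > 0L) data <- rbind(data, matrix(0, pad, nch))
  for (r in seq_len(n_rec)) {
    rows <- (r - 1L) * spr + seq_len(spr)
    writeBin(as.vector(to_dig(data[rows, , drop = FALSE])), con, size = 2L,
             endian = "little")
  }
}

#' Read a recording from disk
#'
#' Reads EDF (or the plain-text dialect) and attaches the schedule from
#' `schedule_path(path)` or an explicit sidecar.  EDF signals are returned
#' in physical units (microvolts) using the header scaling; an EDF+
#' annotations signal is skipped.
#'
#' @param path Recording file (`.edf` or text dialect).
#' @param schedule_path_ Optional explicit schedule sidecar path; by default
#'   the conventional sidecar is used when it exists.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, schedule_path_ = NULL) {
  if (!file.exists(path)) {
    fe_stop("fe_format_error", sprintf("no such file: '%s'", path))
  }
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf_impl(path)
  } else {
    read_text_impl(path)
  }
  sp <- schedule_path_ %||% schedule_path(path)
  if (file.exists(sp)) {
    sch <- read_tsv_plain(sp)
    rec <- set_schedule(rec, sch)
  }
  rec
}

read_text_impl <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#fs\t", first)) {
    fe_stop("fe_format_error",
            "text recording must start with a '#fs<TAB><Hz>' line")
  }
  fs <- as.numeric(sub("^#fs\t", "", first))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           check.names = FALSE)
  eeg_recording(as.matrix(tab), fs, colnames(tab))
}

read_edf_impl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    out <- readChar(con, width, useBytes = TRUE)
    if (length(out) == 0L || nchar(out, type = "bytes") < width) {
      fe_stop("fe_format_error", "truncated EDF header")
    }
    trimws(out)
  }
  rd(8L)                       # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(rd(8L))
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  nch <- as.integer(rd(4L))
  if (is.na(nch) || nch < 1L || is.na(n_rec) || is.na(rec_dur) ||
      rec_dur <= 0) {
    fe_stop("fe_format_error", "unparseable EDF header")
  }
  labels <- vapply(seq_len(nch), function(i) rd(16L), "")
  vapply(seq_len(nch), function(i) rd(80L), "")   # transducer
  vapply(seq_len(nch), function(i) rd(8L), "")    # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8L), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8L), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8L), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8L), ""))
  vapply(seq_len(nch), function(i) rd(80L), "")   # prefilter
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8L), ""))
  vapply(seq_len(nch), function(i) rd(32L), "")   # reserved
  if (any(is.na(spr)) || any(spr < 1L) || any(is.na(pmin_)) ||
      any(is.na(pmax_)) || any(dmax <= dmin)) {
    fe_stop("fe_format_error", "unparseable EDF signal headers")
  }
  expected <- header_bytes + 2 * n_rec * sum(spr)
  if (sz < expected) {
    fe_stop("fe_format_error",
            sprintf("truncated EDF: %d bytes, header promises %d", sz, expected))
  }
  keep <- labels != "EDF Annotations"
  if (length(unique(spr[keep])) != 1L) {
    fe_stop("fe_format_error",
            "EDF signals with differing sampling rates are not supported")
  }
  data <- matrix(0, n_rec * spr[keep][1L], sum(keep))
  for (r in seq_len(n_rec)) {
    col_out <- 0L
    for (ch in seq_len(nch)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      if (keep[ch]) {
        col_out <- col_out + 1L
        phys <- (raw - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
          (dmax[ch] - dmin[ch]) + pmin_[ch]
        data[(r - 1L) * spr[ch] + seq_len(spr[ch]), col_out] <- phys
      }
    }
  }
  eeg_recording(data, spr[keep][1L] / rec_dur, labels[keep])
}
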