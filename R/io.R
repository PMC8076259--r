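#' Construct a two-channel recording
#'
#' @param eeg,emg Numeric sample vectors of equal length.
#' @param fs Sampling rate in Hz.
#' @param start_zt Zeitgeber hour of the first sample (0 = lights on).
#' @param schedule A [light_dark_schedule()].
#' @return Object of class `recording`.
#' @export
recording <- function(eeg, emg, fs, start_zt = 0,
                      schedule = light_dark_schedule()) {
  if (length(eeg) != length(emg)) stop("eeg and emg must have equal length")
  if (length(eeg) == 0L) stop("recording must be non-empty")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  structure(
    list(eeg = as.numeric(eeg), emg = as.numeric(emg), fs = fs,
         start_zt = start_zt, schedule = schedule),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d samples @ %g Hz (%.2f h), start ZT %g\n",
              length(x$eeg), x$fs, length(x$eeg) / x$fs / 3600, x$start_zt))
  invisible(x)
}

#' Read a recording from disk
#'
#' @param path Input file.
#' @param format `"csv"` (columns `time_s,eeg,emg`) or `"edf"`.
#' @param fs Sampling rate; for CSV inferred from the time column when `NULL`.
#' @param start_zt Zeitgeber hour of the first sample.
#' @param schedule A [light_dark_schedule()].
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf"), fs = NULL,
                           start_zt = 0, schedule = light_dark_schedule()) {
  format <- match.arg(format)
  switch(format,
    csv = read_recording_csv(path, fs = fs, start_zt = start_zt,
                             schedule = schedule),
    edf = read_recording_edf(path, start_zt = start_zt, schedule = schedule)
  )
}

#' Write a recording as CSV
#' @param rec A [recording()].
#' @param path Output file; columns `time_s,eeg,emg`.
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(
    time_s = (seq_along(rec$eeg) - 1) / rec$fs,
    eeg = rec$eeg, emg = rec$emg
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs Sampling rate; inferred from the `time_s` column when `NULL`.
#' @param start_zt,schedule Session alignment, as in [recording()].
#' @export
read_recording_csv <- function(path, fs = NULL, start_zt = 0,
                               schedule = light_dark_schedule()) {
  df <- utils::read.csv(path)
  for (ch in c("eeg", "emg")) {
    if (!ch %in% names(df)) stop("missing channel: ", ch)
  }
  if (is.null(fs)) {
    if (!"time_s" %in% names(df) || nrow(df) < 2) {
      stop("cannot infer fs: provide fs or a time_s column")
    }
    fs <- 1 / stats::median(diff(df$time_s))
    fs <- round(fs, 6)
  }
  recording(df$eeg, df$emg, fs = fs, start_zt = start_zt, schedule = schedule)
}

# --- minimal EDF (16-bit, continuous) reader/writer ---------------------
# Covers the subset needed here: equal-rate channels, one data record per
# second, physical scaling from per-channel min/max. No annotations.

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording as EDF
#'
#' Minimal EDF writer: two 16-bit channels labelled EEG and EMG, 1 s data
#' records. The signal is truncated to a whole number of seconds. Values are
#' scaled into the int16 range from the per-channel physical min/max, so the
#' roundtrip is exact to about 1/65536 of the channel range.
#'
#' @param rec A [recording()].
#' @param path Output file.
#' @export
write_recording_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n_rec <- length(rec$eeg) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  chans <- list(EEG = rec$eeg[1:(n_rec * fs)], EMG = rec$emg[1:(n_rec * fs)])
  ns <- length(chans)

  phys_min <- vapply(chans, min, 0)
  phys_max <- vapply(chans, max, 0)
  span <- ifelse(phys_max > phys_min, phys_max - phys_min, 1)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + ns * 256, 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(ns, 4)
  )
  sig <- paste0(
    paste0(vapply(names(chans), pad, "", width = 16), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad("au", 8), ns), collapse = ""),
    paste0(vapply(sprintf("%.6g", phys_min), pad, "", width = 8), collapse = ""),
    paste0(vapply(sprintf("%.6g", phys_max), pad, "", width = 8), collapse = ""),
    paste0(rep(pad(-32768, 8), ns), collapse = ""),
    paste0(rep(pad(32767, 8), ns), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad(fs, 8), ns), collapse = ""),
    paste0(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  dig <- lapply(seq_along(chans), function(i) {
    as.integer(round((chans[[i]] - phys_min[i]) / span[i] * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_along(chans)) {
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @param start_zt,schedule Session alignment, as in [recording()].
#' @export
read_recording_edf <- function(path, start_zt = 0,
                               schedule = light_dark_schedule()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(ns) || ns < 1) stop("unreadable EDF header")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (f in c(80, 8)) for (i in seq_len(ns)) rd(f)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nspr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  out <- lapply(seq_len(ns), function(i) numeric(n_rec * nspr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = nspr[i], size = 2, endian = "little",
                   signed = TRUE)
      g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      out[[i]][((r - 1) * nspr[i] + 1):(r * nspr[i])] <-
        phys_min[i] + (d - dig_min[i]) * g
    }
  }
  names(out) <- toupper(labels)
  for (ch in c("EEG", "EMG")) {
    if (!ch %in% names(out)) stop("missing channel: ", ch)
  }
  fs <- nspr[match("EEG", toupper(labels))] / rec_dur
  recording(out[["EEG"]], out[["EMG"]], fs = fs, start_zt = start_zt,
            schedule = schedule)
}

# --- filtering / decimation / epoching ----------------------------------

#' Emulate the acquisition hardware's band-pass filters
#'
#' Zero-phase 4th-order Butterworth high-pass + low-pass cascades:
#' EEG 0.1-100 Hz, EMG 1-100 Hz. Signal length is preserved.
#'
#' @param rec A [recording()] with `fs > 200` Hz.
#' @return Filtered [recording()].
#' @export
hardware_bandpass <- function(rec) {
  if (rec$fs <= 200) stop("fs must exceed 200 Hz (2x the 100 Hz band edge)")
  nyq <- rec$fs / 2
  lp <- signal::butter(4, 100 / nyq, type = "low")
  hp_eeg <- signal::butter(4, 0.1 / nyq, type = "high")
  hp_emg <- signal::butter(4, 1 / nyq, type = "high")
  rec$eeg <- signal::filtfilt(lp, signal::filtfilt(hp_eeg, rec$eeg))
  rec$emg <- signal::filtfilt(lp, signal::filtfilt(hp_emg, rec$emg))
  rec
}

#' Downsample a recording
#'
#' Applies a zero-phase 8th-order Butterworth anti-alias low-pass at 0.8x
#' the target Nyquist, then keeps every `fs/target_fs`-th sample.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate; must divide `fs` exactly.
#' @return A [recording()] at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("fs must be an integer multiple of target_fs")
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  aa <- signal::butter(8, 0.8 * (target_fs / 2) / (rec$fs / 2), type = "low")
  keep <- seq(1, length(rec$eeg), by = q)
  rec$eeg <- signal::filtfilt(aa, rec$eeg)[keep]
  rec$emg <- signal::filtfilt(aa, rec$emg)[keep]
  rec$fs <- target_fs
  rec
}

#' Cut a signal into non-overlapping scoring epochs
#'
#' Epochs are contiguous from sample 1; a trailing partial epoch is
#' discarded. Concatenating the rows reproduces the retained signal prefix.
#'
#' @param x A numeric vector or a [recording()].
#' @param fs Sampling rate in Hz (taken from the recording if given one).
#' @param epoch_len Epoch length in seconds.
#' @param channel For recordings, `"eeg"` or `"emg"`.
#' @return Object of class `epoched_signal`: a matrix (epochs x samples)
#'   with attributes `fs` and `epoch_len`.
#' @export
epoch_signal <- function(x, fs = NULL, epoch_len = 4,
                         channel = c("eeg", "emg")) {
  if (inherits(x, "recording")) {
    channel <- match.arg(channel)
    fs <- x$fs
    x <- x[[channel]]
  }
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (epoch_len <= 0) stop("epoch_len must be > 0")
  spe <- epoch_len * fs
  if (abs(spe - round(spe)) > 1e-9) stop("epoch_len * fs must be an integer")
  spe <- as.integer(round(spe))
  n_ep <- length(x) %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch")
  m <- matrix(x[1:(n_ep * spe)], nrow = n_ep, ncol = spe, byrow = TRUE)
  structure(m, fs = fs, epoch_len = epoch_len, class = "epoched_signal")
}

#' @export
print.epoched_signal <- function(x, ...) {
  cat(sprintf("epoched signal: %d epochs x %d samples (%g s @ %g Hz)\n",
              nrow(x), ncol(x), attr(x, "epoch_len"), attr(x, "fs")))
  invisible(x)
}
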