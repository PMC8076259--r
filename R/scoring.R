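#' Per-epoch scoring features
#'
#' Computes the two features the stand-in scorer uses: epoch EMG RMS and
#' the EEG theta/delta power ratio (theta 6-9 Hz, delta 1-5 Hz, raw
#' periodogram power).
#'
#' @param eeg_epochs,emg_epochs `epoched_signal` objects with equal epoch
#'   counts.
#' @return data.frame: `emg_rms`, `delta`, `theta`, `ratio`.
#' @export
epoch_features <- function(eeg_epochs, emg_epochs) {
  if (nrow(eeg_epochs) != nrow(emg_epochs)) {
    stop("EEG and EMG must have equal epoch counts")
  }
  if (nrow(eeg_epochs) == 0L) stop("empty input")
  emg_rms <- sqrt(rowMeans(emg_epochs^2))
  psd <- periodogram_rows(eeg_epochs, attr(eeg_epochs, "fs"))
  delta <- band_power(psd, c(1, 5))
  theta <- band_power(psd, c(6, 9))
  if (any(!is.finite(emg_rms)) || any(!is.finite(delta + theta))) {
    stop("non-finite features")
  }
  data.frame(emg_rms = emg_rms, delta = delta, theta = theta,
             ratio = theta / pmax(delta, .Machine$double.xmin))
}

# Adaptive WAKE/sleep cut on the EMG RMS: 2-means on the log scale,
# threshold at the midpoint of the cluster centres. Robust to the WAKE
# fraction, unlike a fixed quantile.
adaptive_emg_threshold <- function(emg_rms) {
  lx <- log(pmax(emg_rms, .Machine$double.xmin))
  if (length(unique(lx)) < 2) return(max(emg_rms) * 2) # constant EMG: nothing is WAKE
  km <- stats::kmeans(lx, centers = range(lx))
  exp(mean(km$centers))
}

#' Score epochs into WAKE/NREMS/REMS
#'
#' Transparent two-feature threshold classifier (a documented stand-in for
#' semi-automated scoring software): an epoch is WAKE when its EMG RMS
#' exceeds the muscle-tone threshold; remaining (sleep) epochs are REMS when
#' the EEG theta/delta ratio exceeds `ratio_threshold`, else NREMS.
#'
#' @param eeg_epochs,emg_epochs `epoched_signal` objects, equal epoch count.
#' @param emg_threshold `"adaptive"` (2-means split of log EMG RMS, the
#'   default), a single number (absolute RMS cut), or
#'   `list(quantile = q)` for a fixed-quantile cut.
#' @param ratio_threshold REMS cut on theta/delta (default 1).
#' @param start_zt,schedule Alignment metadata for the output hypnogram.
#' @return A [hypnogram()].
#' @export
score_epochs <- function(eeg_epochs, emg_epochs, emg_threshold = "adaptive",
                         ratio_threshold = 1, start_zt = 0,
                         schedule = light_dark_schedule()) {
  feats <- epoch_features(eeg_epochs, emg_epochs)
  thr <- if (identical(emg_threshold, "adaptive")) {
    adaptive_emg_threshold(feats$emg_rms)
  } else if (is.list(emg_threshold) && !is.null(emg_threshold$quantile)) {
    stats::quantile(feats$emg_rms, emg_threshold$quantile, names = FALSE)
  } else if (is.numeric(emg_threshold) && length(emg_threshold) == 1L) {
    emg_threshold
  } else {
    stop("emg_threshold must be \"adaptive\", a number, or list(quantile=)")
  }
  states <- ifelse(feats$emg_rms > thr, "WAKE",
                   ifelse(feats$ratio > ratio_threshold, "REMS", "NREMS"))
  hypnogram(states, epoch_len = attr(eeg_epochs, "epoch_len"),
            start_zt = start_zt, schedule = schedule)
}

#' Consolidate short bouts (rescoring rule)
#'
#' Re-scores a hypnogram so that every resulting bout lasts at least
#' `min_bout_epochs` epochs (default 3 epochs = 12 s). Scanning left to
#' right, a run shorter than the floor is absorbed into the preceding run's
#' state (a sub-minimum run at the very start merges into the following
#' run), repeating to fixpoint. Only epochs belonging to sub-minimum runs
#' are ever altered, and the operation is idempotent.
#'
#' @param h A [hypnogram()].
#' @param min_bout_epochs Minimum run length in epochs (>= 1).
#' @return A [hypnogram()] whose every bout has length >= `min_bout_epochs`.
#' @export
smooth_bouts <- function(h, min_bout_epochs = 3) {
  if (min_bout_epochs < 1) stop("min_bout_epochs must be >= 1")
  if (n_epochs(h) < min_bout_epochs) {
    stop("hypnogram shorter than min_bout_epochs")
  }
  states <- h$states
  repeat {
    r <- rle(states)
    short <- which(r$lengths < min_bout_epochs)
    if (length(short) == 0L) break
    i <- short[1]
    r$values[i] <- if (i == 1L) r$values[i + 1L] else r$values[i - 1L]
    states <- inverse.rle(r)
  }
  h$states <- states
  h
}
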