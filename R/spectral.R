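#' Frequency band scheme
#'
#' Band edges used throughout the analysis: delta 1.0-5.0 Hz, theta
#' 6.0-9.0 Hz, alpha 10.0-15.0 Hz, eta 16.0-22.75 Hz. Edges are inclusive
#' at both ends and sit on the 0.25 Hz grid; the inter-band gaps are left
#' unassigned deliberately.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
band_scheme <- function() {
  list(delta = c(1, 5), theta = c(6, 9), alpha = c(10, 15),
       eta = c(16, 22.75))
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# One-sided density-scaled periodogram of the rows of a matrix.
# Returns epochs x bins matrix; attr "freqs" holds the bin centres.
periodogram_rows <- function(m, fs, window = hamming_window(ncol(m))) {
  n <- ncol(m)
  nb <- n %/% 2 + 1
  W <- matrix(window, nrow = nrow(m), ncol = n, byrow = TRUE)
  X <- t(apply(m * W, 1, function(row) {
    p <- Mod(stats::fft(row))^2 / (fs * sum(window^2))
    ps <- p[1:nb]
    if (n %% 2 == 0) ps[2:(nb - 1)] <- 2 * ps[2:(nb - 1)]
    else ps[2:nb] <- 2 * ps[2:nb]
    ps
  }))
  if (nrow(m) == 1L) X <- matrix(X, nrow = 1)
  structure(X, freqs = (0:(nb - 1)) * fs / n)
}

#' Zero-phase high-pass filter applied per epoch
#'
#' Removes movement-associated low-frequency artifacts before PSD
#' computation. The epoch mean (the DC component) is subtracted exactly
#' first — on 4 s epochs the IIR filter's edge transients make DC rejection
#' by the filter alone unreliable — then a zero-phase 2nd-order Butterworth
#' high-pass (default cutoff 1 Hz) removes the remaining drift.
#'
#' @param epochs An `epoched_signal` from [epoch_signal()].
#' @param cutoff High-pass cutoff in Hz; must be below Nyquist.
#' @return Filtered `epoched_signal` of the same shape.
#' @export
highpass_epochs <- function(epochs, cutoff = 1) {
  fs <- attr(epochs, "fs")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  hp <- signal::butter(2, cutoff / (fs / 2), type = "high")
  out <- t(apply(epochs, 1, function(row) {
    signal::filtfilt(hp, row - mean(row))
  }))
  structure(out, fs = fs, epoch_len = attr(epochs, "epoch_len"),
            class = "epoched_signal")
}

#' Per-epoch power spectral density on the 0.25 Hz grid
#'
#' Welch PSD at 0.25 Hz resolution for non-overlapping 4 s epochs: at that
#' resolution each 4 s epoch is a single Hamming-windowed segment, so the
#' estimate reduces to one windowed periodogram per epoch (density scaling,
#' one-sided). The grid runs from 0 Hz to Nyquist in 0.25 Hz steps.
#'
#' @param epochs An `epoched_signal`; `epoch_len` must be 4 s so that the
#'   grid spacing is exactly 0.25 Hz.
#' @return Matrix (epochs x frequency bins) of raw PSD with attribute
#'   `freqs`.
#' @export
epoch_psd <- function(epochs) {
  fs <- attr(epochs, "fs")
  epoch_len <- attr(epochs, "epoch_len")
  if (abs(fs / ncol(epochs) - 0.25) > 1e-9) {
    stop("epoch length incompatible with the 0.25 Hz grid (need 4 s epochs)")
  }
  periodogram_rows(epochs, fs)
}

#' Normalize per-epoch PSD to relative power
#'
#' Divides each frequency bin by the epoch's total power so every epoch's
#' relative spectrum sums to exactly 1. All-zero epochs cannot be
#' normalized; they are set to NA and flagged in the `excluded` attribute.
#'
#' @param raw Matrix from [epoch_psd()] (epochs x bins, attr `freqs`).
#' @return Matrix of the same shape; rows sum to 1. Attribute `excluded`
#'   marks all-zero input epochs.
#' @export
normalize_psd <- function(raw) {
  tot <- rowSums(raw)
  excluded <- !is.finite(tot) | tot <= 0
  out <- raw / tot
  out[excluded, ] <- NA_real_
  structure(out, freqs = attr(raw, "freqs"), excluded = excluded)
}

#' Median/IQR relative power per state and phase
#'
#' Aggregates epoch spectra over all epochs of a given vigilance state
#' within a phase; reported on the 1-22.75 Hz range the analysis uses.
#'
#' @param spectra Matrix from [normalize_psd()], epoch-aligned with `hyp`.
#' @param hyp The [hypnogram()] the epochs were scored with.
#' @param phase `"light"`, `"dark"`, or `"both"`.
#' @param f_lo,f_hi Reported frequency range (inclusive).
#' @return Long data.frame: `state`, `freq`, `median`, `q25`, `q75`,
#'   `n_epochs`. States absent from the phase yield no rows and a warning.
#' @export
state_psd_summary <- function(spectra, hyp, phase = c("light", "dark", "both"),
                              f_lo = 1, f_hi = 22.75) {
  phase <- match.arg(phase)
  if (nrow(spectra) != n_epochs(hyp)) {
    stop("spectra and hypnogram must be epoch-aligned")
  }
  freqs <- attr(spectra, "freqs")
  sel_f <- which(freqs >= f_lo - 1e-9 & freqs <= f_hi + 1e-9)
  in_phase <- if (phase == "both") rep(TRUE, n_epochs(hyp))
              else epoch_phase(hyp) == phase
  ok_row <- !apply(is.na(spectra), 1, any)
  out <- list()
  for (st in vigilance_states()) {
    rows <- which(hyp$states == st & in_phase & ok_row)
    if (length(rows) == 0L) {
      warning("state ", st, " absent in ", phase, " phase; empty summary")
      next
    }
    sub <- spectra[rows, sel_f, drop = FALSE]
    qs <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE)
    out[[st]] <- data.frame(
      state = st, freq = freqs[sel_f],
      median = qs[2, ], q25 = qs[1, ], q75 = qs[3, ],
      n_epochs = length(rows)
    )
  }
  if (length(out) == 0L) {
    return(data.frame(state = character(0), freq = numeric(0),
                      median = numeric(0), q25 = numeric(0),
                      q75 = numeric(0), n_epochs = integer(0)))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Band power from relative spectra
#'
#' Sums relative power over all grid bins whose frequency lies within the
#' band, both edges inclusive.
#'
#' @param spectra Matrix with attribute `freqs` (e.g. from
#'   [normalize_psd()]).
#' @param band `c(lo, hi)` in Hz or a name from [band_scheme()].
#' @return Numeric vector, one value per epoch (row).
#' @export
band_power <- function(spectra, band) {
  if (is.character(band)) band <- band_scheme()[[band]]
  freqs <- attr(spectra, "freqs")
  if (band[1] < min(freqs) - 1e-9 || band[2] > max(freqs) + 1e-9) {
    stop("band lies outside the frequency grid")
  }
  sel <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  rowSums(spectra[, sel, drop = FALSE])
}

#' High-frequency (eta band) quality-control flags
#'
#' Flags animals whose median NREMS eta-band relative power falls below a
#' fraction of the cohort median, mirroring the exclusion of animals with
#' unspecific high-frequency PSD attenuation. Flags affect only spectral
#' aggregation; flagged animals stay in architecture and spindle analyses.
#'
#' @param eta_power Named numeric vector: per-animal median NREMS eta-band
#'   relative power.
#' @param threshold Flag when below `threshold` x cohort median.
#' @return Named logical vector, `TRUE` = excluded from spectral pooling.
#' @export
eta_qc <- function(eta_power, threshold = 0.5) {
  if (length(eta_power) < 3) {
    warning("fewer than 3 animals: eta QC skipped, no animal flagged")
    return(stats::setNames(rep(FALSE, length(eta_power)), names(eta_power)))
  }
  eta_power < threshold * stats::median(eta_power)
}
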