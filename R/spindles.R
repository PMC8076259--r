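#' Spindle detection parameters
#'
#' Defaults follow a validated mouse spindle-detection paradigm: sigma
#' band-pass 10-15 Hz with stopbands at 3 and 22 Hz and 24 dB/octave
#' attenuation, 750 ms RMS smoothing window, cubing of the RMS trace,
#' lower/upper thresholds at 1.0x / 2.5x the mean cubed RMS, duration
#' bounds 0.5-10 s and a 0.1 s inter-spindle interval.
#'
#' @param passband,stopband `c(lo, hi)` in Hz.
#' @param atten_db Required stopband attenuation in dB (zero-phase total).
#' @param rms_window_s RMS smoothing window in seconds.
#' @param lower_mult,upper_mult Threshold multiples of the mean cubed RMS.
#' @param min_dur_s,max_dur_s Event duration bounds in seconds.
#' @param min_isi_s Minimum inter-spindle interval; closer events merge.
#' @param baseline Envelope-mean scope: `"nrems"` (default) or `"all"`.
#' @return List of class `spindle_params`.
#' @export
spindle_params <- function(passband = c(10, 15), stopband = c(3, 22),
                           atten_db = 24, rms_window_s = 0.75,
                           lower_mult = 1, upper_mult = 2.5,
                           min_dur_s = 0.5, max_dur_s = 10,
                           min_isi_s = 0.1,
                           baseline = c("nrems", "all")) {
  stopifnot(min_dur_s > 0, min_dur_s < max_dur_s, lower_mult < upper_mult,
            stopband[1] < passband[1], passband[2] < stopband[2])
  structure(list(passband = passband, stopband = stopband,
                 atten_db = atten_db, rms_window_s = rms_window_s,
                 lower_mult = lower_mult, upper_mult = upper_mult,
                 min_dur_s = min_dur_s, max_dur_s = max_dur_s,
                 min_isi_s = min_isi_s, baseline = match.arg(baseline)),
            class = "spindle_params")
}

# |H(f)| of a designed digital filter at frequencies f (Hz)
filter_gain <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w)
  num <- vapply(seq_along(w), function(i) sum(flt$b * z[i]^(0:(length(flt$b) - 1))), 0i)
  den <- vapply(seq_along(w), function(i) sum(flt$a * z[i]^(0:(length(flt$a) - 1))), 0i)
  Mod(num / den)
}

#' Sigma band-pass filter for spindle detection
#'
#' Zero-phase Butterworth band-pass over the sigma (10-15 Hz) range. The
#' section order is the minimum whose zero-phase (forward-backward) response
#' attenuates both stopband edges by at least `atten_db`; with the default
#' 24 dB requirement this yields a 4th-order band-pass, consistent with a
#' 24 dB/octave roll-off.
#'
#' @param eeg Numeric sample vector.
#' @param fs Sampling rate in Hz (> 2x the upper stopband edge).
#' @param params A [spindle_params()].
#' @return Filtered vector of equal length.
#' @export
sigma_filter <- function(eeg, fs, params = spindle_params()) {
  if (fs <= 2 * params$stopband[2]) {
    stop("fs must exceed twice the upper stopband edge")
  }
  nyq <- fs / 2
  flt <- NULL
  for (ord in 1:12) {
    cand <- signal::butter(ord, params$passband / nyq, type = "pass")
    g <- filter_gain(cand, params$stopband, fs)
    atten <- -20 * log10(pmax(g, 1e-300)) * 2 # filtfilt doubles attenuation
    if (all(atten >= params$atten_db)) { flt <- cand; break }
  }
  if (is.null(flt)) stop("unmeetable filter design specification")
  signal::filtfilt(flt, eeg)
}

#' Cubed moving-RMS envelope
#'
#' Centered moving RMS over a 750 ms window (truncated at the recording
#' edges), then cubed elementwise to sharpen the separation between spindle
#' bursts and background.
#'
#' @param x Filtered signal vector.
#' @param fs Sampling rate in Hz.
#' @param window_s RMS window length in seconds.
#' @return Non-negative envelope vector of equal length.
#' @export
cubed_rms_envelope <- function(x, fs, window_s = 0.75) {
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  if (w <= 0 || w > n) stop("window must be positive and no longer than the signal")
  half <- w %/% 2
  cs <- cumsum(c(0, x^2))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + (w - half - 1L))
  ms <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  sqrt(ms)^3
}

#' Two-threshold spindle detection on the cubed RMS envelope
#'
#' Baseline = mean cubed RMS over NREMS samples (or the whole recording,
#' per `params$baseline`). Candidate events are maximal runs above the
#' lower threshold that contain at least one sample above the upper
#' threshold; candidates separated by less than the inter-spindle interval
#' are merged; events outside the duration bounds, or starting outside an
#' NREMS epoch, are discarded.
#'
#' @param envelope Vector from [cubed_rms_envelope()], time-aligned with
#'   `hyp` (sample 1 = first epoch's first sample).
#' @param hyp The [hypnogram()] providing NREMS context.
#' @param fs Sampling rate of `envelope` in Hz.
#' @param params A [spindle_params()].
#' @return data.frame of events: `start_s`, `end_s`, `duration_s`, `peak`
#'   (max cubed RMS), `phase`. Zero rows (with a warning) when the
#'   hypnogram contains no NREMS.
#' @export
detect_spindles <- function(envelope, hyp, fs, params = spindle_params()) {
  spe <- as.integer(round(hyp$epoch_len * fs))
  n <- min(length(envelope), n_epochs(hyp) * spe)
  envelope <- envelope[1:n]
  state_per_sample <- rep(hyp$states, each = spe)[1:n]
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), peak = numeric(0),
                      phase = character(0))
  is_nrems <- state_per_sample == "NREMS"
  if (!any(is_nrems)) {
    warning("no NREMS in hypnogram; no spindles detected")
    return(empty)
  }
  base <- if (params$baseline == "nrems") mean(envelope[is_nrems])
          else mean(envelope)
  lower <- params$lower_mult * base
  upper <- params$upper_mult * base

  r <- rle(envelope > lower)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (length(cand) == 0L) return(empty)
  s <- starts[cand]; e <- ends[cand]
  # keep candidates containing a supra-upper sample
  keep <- vapply(seq_along(s), function(i) max(envelope[s[i]:e[i]]) > upper,
                 TRUE)
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0L) return(empty)
  # merge events whose gap is below the inter-spindle interval
  min_gap <- params$min_isi_s * fs
  ms <- s[1]; me <- e[1]; out_s <- c(); out_e <- c()
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] - me - 1L < min_gap) {
        me <- e[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  dur <- (out_e - out_s + 1L) / fs
  ok <- dur >= params$min_dur_s & dur <= params$max_dur_s &
    is_nrems[out_s]
  out_s <- out_s[ok]; out_e <- out_e[ok]
  if (length(out_s) == 0L) return(empty)
  start_s <- (out_s - 1L) / fs
  zt_h <- hyp$start_zt + start_s / 3600
  data.frame(
    start_s = start_s,
    end_s = out_e / fs,
    duration_s = (out_e - out_s + 1L) / fs,
    peak = vapply(seq_along(out_s),
                  function(i) max(envelope[out_s[i]:out_e[i]]), 0),
    phase = zt_phase(zt_h, hyp$schedule),
    stringsAsFactors = FALSE
  )
}

#' Detect spindles directly from a recording
#'
#' Convenience wrapper: sigma-filters the EEG, builds the cubed RMS
#' envelope, and runs the two-threshold detector.
#'
#' @param rec A [recording()].
#' @param hyp The epoch-aligned [hypnogram()].
#' @param params A [spindle_params()].
#' @return As [detect_spindles()].
#' @export
detect_spindles_recording <- function(rec, hyp, params = spindle_params()) {
  filt <- sigma_filter(rec$eeg, rec$fs, params)
  env <- cubed_rms_envelope(filt, rec$fs, params$rms_window_s)
  detect_spindles(env, hyp, rec$fs, params)
}

#' Spindle statistics per phase and 2 h bin
#'
#' @param events data.frame from [detect_spindles()].
#' @param hyp The [hypnogram()] used for detection.
#' @return List with `per_phase` (phase, amount, nrems_min, density per
#'   NREMS minute, mean_duration_s) and `binned` (2 h bin counts). Phases
#'   without NREMS get `density = NA` (flagged undefined); phases without
#'   events get `mean_duration_s = NA`.
#' @export
spindle_stats <- function(events, hyp) {
  ph <- epoch_phase(hyp)
  per_phase <- do.call(rbind, lapply(c("light", "dark"), function(p) {
    nrems_min <- sum(hyp$states == "NREMS" & ph == p) * hyp$epoch_len / 60
    ev <- events[events$phase == p, , drop = FALSE]
    data.frame(
      phase = p,
      amount = nrow(ev),
      nrems_min = nrems_min,
      density = if (nrems_min > 0) nrow(ev) / nrems_min else NA_real_,
      mean_duration_s = if (nrow(ev) > 0) mean(ev$duration_s) else NA_real_
    )
  }))
  bins <- zt_bins(hyp$schedule)
  ev_zt <- hyp$start_zt + events$start_s / 3600
  bin_of <- findInterval(ev_zt, bins$start_zt)
  binned <- cbind(bins, count = vapply(bins$bin, function(b)
    sum(bin_of == b), 0L))
  list(per_phase = per_phase, binned = binned)
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one onset matching within a tolerance; used to validate
#' the detector against the generator's injected events.
#'
#' @param detected,truth data.frames with a `start_s` column.
#' @param tol_s Onset tolerance in seconds.
#' @return List: `recall`, `precision`, `n_matched`.
#' @export
match_events <- function(detected, truth, tol_s = 0.25) {
  used <- rep(FALSE, nrow(detected))
  n_match <- 0L
  for (t0 in truth$start_s) {
    d <- abs(detected$start_s - t0)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_s) {
      used[which.min(d)] <- TRUE
      n_match <- n_match + 1L
    }
  }
  list(
    recall = if (nrow(truth) > 0) n_match / nrow(truth) else NA_real_,
    precision = if (nrow(detected) > 0) n_match / nrow(detected) else NA_real_,
    n_matched = n_match
  )
}
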