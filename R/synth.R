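# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic hypnogram
#'
#' Simulates the bout process of a [strain_profile()]: a semi-Markov chain
#' over WAKE/NREMS/REMS with geometric dwell times at epoch resolution
#' (exit probability per epoch = epoch_len / mean bout duration) and
#' phase-dependent parameters. A bout running into the light/dark boundary
#' is truncated there and the state's dwell is re-drawn under the new
#' phase's parameters (memorylessness makes this equivalent to per-epoch
#' simulation). Direct WAKE->REMS transitions never occur. When the
#' hypnogram starts at lights-on (ZT0), the initial state is WAKE with its
#' first dwell mean set to the profile's sleep-latency offset.
#'
#' @param profile A [strain_profile()].
#' @param duration_s Total duration in seconds; must be a positive multiple
#'   of `epoch_len`.
#' @param epoch_len Epoch length in seconds (default 4).
#' @param schedule A [light_dark_schedule()].
#' @param seed Integer RNG seed; identical inputs give identical output.
#' @param start_zt Zeitgeber hour of the first epoch.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(profile, duration_s, epoch_len = 4,
                               schedule = light_dark_schedule(), seed = 1,
                               start_zt = 0) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- duration_s / epoch_len
  if (abs(n - round(n)) > 1e-9) stop("duration must be a multiple of epoch_len")
  n <- as.integer(round(n))
  for (ph in c("light", "dark")) {
    if (any(profile[[ph]]$mean_bout_s[vigilance_states()] <= epoch_len)) {
      stop("all mean bout durations must exceed one epoch length")
    }
  }
  route <- list(
    light = routing_probs(profile$light$prob, profile$light$mean_bout_s),
    dark = routing_probs(profile$dark$prob, profile$dark$mean_bout_s)
  )

  epochs_per_h <- 3600 / epoch_len
  boundary_epoch <- (schedule$light_h - start_zt) * epochs_per_h # last light epoch index
  phase_of <- function(e) if (e <= boundary_epoch) "light" else "dark"
  # epochs remaining in the current phase counting from epoch e
  left_in_phase <- function(e) {
    if (e <= boundary_epoch) as.integer(ceiling(boundary_epoch - e + 1)) else n - e + 1L
  }

  with_seed(seed, {
    states <- character(n)
    ph1 <- phase_of(1)
    act1 <- route[[ph1]]$active
    if (length(act1) == 1L) {
      state <- act1
    } else if (start_zt == 0 && profile$latency_offset_min > 0 &&
               "WAKE" %in% act1) {
      state <- "WAKE"
    } else {
      p <- profile[[ph1]]$prob[act1]
      state <- sample(act1, 1, prob = p / sum(p))
    }
    e <- 1L
    first_bout <- TRUE
    while (e <= n) {
      ph <- phase_of(e)
      r <- route[[ph]]
      if (first_bout && state == "WAKE" && start_zt == 0 &&
          profile$latency_offset_min > 0) {
        # the lights-on WAKE bout models consolidated sleep-onset latency:
        # a narrow gamma dwell (CV ~ 0.32) around the profile offset rather
        # than the memoryless within-phase dwell
        mean_ep <- profile$latency_offset_min * 60 / epoch_len
        dwell <- max(1L, as.integer(round(stats::rgamma(1, shape = 10,
                                                        rate = 10 / mean_ep))))
      } else {
        mean_s <- profile[[ph]]$mean_bout_s[[state]]
        p_exit <- min(1, epoch_len / mean_s)
        dwell <- 1L + stats::rgeom(1, p_exit)
      }
      avail <- left_in_phase(e)
      k <- min(dwell, avail, n - e + 1L)
      states[e:(e + k - 1L)] <- state
      e <- e + k
      first_bout <- FALSE
      if (e > n) break
      if (dwell > avail) next # truncated at phase boundary: same state, new phase
      # transition according to the phase in which the bout ended
      if (length(r$active) == 1L) {
        # single active state: dwell irrelevant, stay
        next
      } else if (length(r$active) == 2L) {
        state <- setdiff(r$active, state)
      } else {
        state <- switch(state,
          WAKE = "NREMS",
          NREMS = if (stats::runif(1) < r$a) "WAKE" else "REMS",
          REMS = if (stats::runif(1) < r$b) "NREMS" else "WAKE"
        )
      }
    }
    hypnogram(states, epoch_len = epoch_len, start_zt = start_zt,
              schedule = schedule)
  })
}

#' Generate a synthetic EEG/EMG recording with ground truth
#'
#' Synthesizes a two-channel recording that follows a hypnogram: the EEG is
#' a state-weighted sum of unit-RMS band-limited noise components (delta
#' 1-4.5 Hz, theta 6-9 Hz, sigma 10-15 Hz, broadband white) plus a
#' narrowband ~8 Hz component during REMS, and the EMG is white noise with
#' state-dependent amplitude (WAKE > NREMS >= REMS). Sleep spindles are
#' injected into NREMS as Hann-windowed 11 Hz bursts at the profile's rate,
#' with peak sinusoid RMS equal to `spindle_amp_mult` times the NREMS
#' sigma-band background RMS; every injected event is recorded in the
#' returned ground truth. Amplitude units are arbitrary.
#'
#' @param truth_base A [hypnogram()] the recording should follow.
#' @param profile A [strain_profile()].
#' @param fs Sampling rate in Hz (>= 250 recommended; must exceed twice the
#'   highest synthesized band edge).
#' @param seed Integer RNG seed.
#' @param spindle_amp_mult Spindle burst amplitude as a multiple of the
#'   NREMS sigma-band background RMS (default 5).
#' @return A list with elements `recording` (a [recording()]) and `truth`
#'   (list: `hypnogram`, `spindle_events` data.frame with `start_s`/`end_s`,
#'   `profile`, `seed`).
#' @export
generate_recording <- function(truth_base, profile, fs = 250, seed = 1,
                               spindle_amp_mult = 5) {
  h <- truth_base
  if (fs <= 2 * 15) stop("fs must exceed twice the highest synthesized band edge")
  spe <- h$epoch_len * fs
  if (abs(spe - round(spe)) > 1e-9) stop("epoch_len * fs must be an integer")
  spe <- as.integer(round(spe))
  n <- n_epochs(h) * spe
  nyq <- fs / 2

  with_seed(seed, {
    unit_rms <- function(x) x / stats::sd(x)
    band_noise <- function(lo, hi) {
      flt <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
      unit_rms(signal::filtfilt(flt, stats::rnorm(n)))
    }
    comp <- list(
      delta = band_noise(1, 4.5),
      theta = band_noise(6, 9),
      sigma = band_noise(10, 15),
      broad = unit_rms(stats::rnorm(n)),
      rems_peak = band_noise(7.5, 8.5)
    )
    state_per_sample <- rep(h$states, each = spe)
    eeg <- numeric(n)
    for (st in vigilance_states()) {
      idx <- state_per_sample == st
      if (!any(idx)) next
      w <- profile$spectral[[st]]
      eeg[idx] <- w[["delta"]] * comp$delta[idx] +
        w[["theta"]] * comp$theta[idx] +
        w[["sigma"]] * comp$sigma[idx] +
        w[["broad"]] * comp$broad[idx] +
        w[["rems_peak"]] * comp$rems_peak[idx]
    }

    # spindle injection: homogeneous Poisson process within each NREMS run.
    # The burst is a Hann-windowed 11 Hz sinusoid. The ground-truth event
    # interval is the support where the burst's instantaneous RMS exceeds
    # the NREMS sigma-band background RMS (the oscillation is annotatable
    # only while it stands out of background, i.e. SNR > 1); the drawn
    # duration refers to that interval and the full Hann window is widened
    # accordingly. Requires bursts clearly above background.
    events <- list()
    if (profile$spindle_rate > 0) {
      if (spindle_amp_mult <= 2) {
        stop("spindle_amp_mult must exceed 2 (bursts must rise above background)")
      }
      sigma_bg_rms <- profile$spectral$NREMS[["sigma"]]
      amp <- spindle_amp_mult * sigma_bg_rms * sqrt(2) # peak sinusoid amplitude
      # hann(tau) * amp / sqrt(2) > sigma_bg_rms  <=>  hann > 1/mult
      taper_frac <- acos(1 - 2 / spindle_amp_mult) / (2 * pi)
      core_frac <- 1 - 2 * taper_frac
      r <- rle(h$states)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1L
      for (i in seq_along(r$values)) {
        if (r$values[i] != "NREMS") next
        run_t0 <- (run_start[i] - 1L) * h$epoch_len
        run_t1 <- run_end[i] * h$epoch_len
        k <- stats::rpois(1, profile$spindle_rate * (run_t1 - run_t0) / 60)
        if (k == 0) next
        starts <- sort(stats::runif(k, run_t0, run_t1))
        last_end <- -Inf
        for (s0 in starts) {
          dur <- min(10, max(0.5, stats::rnorm(1, profile$spindle_dur_s, 0.3)))
          D <- dur / core_frac # full Hann window length
          if (s0 < last_end + 0.3) next        # keep injected events separated
          if (s0 + D > run_t1) next            # must fit inside the NREMS run
          i0 <- floor(s0 * fs) + 1L
          i1 <- min(n, i0 + as.integer(round(D * fs)) - 1L)
          m <- i1 - i0 + 1L
          tt <- (0:(m - 1L)) / fs
          hann <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1L)) / (m - 1L))
          eeg[i0:i1] <- eeg[i0:i1] + amp * hann * sin(2 * pi * 11 * tt)
          events[[length(events) + 1L]] <- c(
            start_s = (i0 - 1L) / fs + taper_frac * D,
            end_s = (i0 - 1L) / fs + (1 - taper_frac) * D
          )
          last_end <- s0 + D
        }
      }
    }
    ev <- if (length(events)) {
      as.data.frame(do.call(rbind, events))
    } else {
      data.frame(start_s = numeric(0), end_s = numeric(0))
    }

    emg_flt <- signal::butter(2, c(1, min(100, 0.9 * nyq)) / nyq, type = "pass")
    emg <- unit_rms(signal::filtfilt(emg_flt, stats::rnorm(n))) *
      profile$emg_amp[state_per_sample]

    rec <- recording(eeg = eeg, emg = as.numeric(emg), fs = fs,
                     start_zt = h$start_zt, schedule = h$schedule)
    list(
      recording = rec,
      truth = list(hypnogram = h, spindle_events = ev, profile = profile,
                   seed = seed)
    )
  })
}
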