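#' Strain profile for the synthetic generator
#'
#' Bundles everything the generator needs to emulate one mouse strain:
#' per-phase stationary state probabilities and mean bout durations for the
#' semi-Markov bout process, per-state spectral shaping weights and EMG
#' amplitudes, spindle rate and duration, and a sleep-latency offset (the
#' dwell mean of the initial WAKE bout at lights-on).
#'
#' The bout process excludes direct WAKE->REMS transitions, so the embedded
#' bout chain has two free routing probabilities per phase which are solved
#' from the requested stationary distribution. Not every (probability, mean
#' duration) combination is reachable under that constraint; infeasible
#' requests error at construction.
#'
#' @param name Profile label.
#' @param light,dark Lists with elements `prob` (named numeric, WAKE/NREMS/
#'   REMS stationary probabilities summing to 1) and `mean_bout_s` (named
#'   numeric, mean bout durations in seconds).
#' @param spectral Named list (WAKE/NREMS/REMS) of band weights: `delta`,
#'   `theta`, `sigma`, `broad`, `rems_peak` (amplitude of the narrowband
#'   ~8 Hz REMS component). Arbitrary units.
#' @param emg_amp Named numeric, EMG noise amplitude per state; must rank
#'   WAKE > NREMS >= REMS.
#' @param spindle_rate Spindle events per NREMS minute (>= 0).
#' @param spindle_dur_s Mean spindle duration in seconds, within [0.5, 10].
#' @param latency_offset_min Dwell mean (minutes) of the initial WAKE bout
#'   when a hypnogram starts at lights-on; drives sleep-onset latency.
#' @return Object of class `strain_profile`.
#' @export
strain_profile <- function(name, light, dark,
                           spectral = default_spectral_weights(),
                           emg_amp = c(WAKE = 1, NREMS = 0.25, REMS = 0.12),
                           spindle_rate = 5,
                           spindle_dur_s = 1.8,
                           latency_offset_min = 8) {
  for (ph in list(light, dark)) {
    stopifnot(is.list(ph), all(c("prob", "mean_bout_s") %in% names(ph)))
    p <- ph$prob[vigilance_states()]
    if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("stationary probabilities must be non-negative and sum to 1")
    }
    m <- ph$mean_bout_s[vigilance_states()]
    if (any(is.na(m)) || any(m <= 0)) stop("mean bout durations must be > 0")
  }
  if (spindle_rate < 0) stop("spindle_rate must be >= 0")
  if (spindle_dur_s < 0.5 || spindle_dur_s > 10) {
    stop("spindle_dur_s must lie within [0.5, 10] s")
  }
  if (!(emg_amp[["WAKE"]] > emg_amp[["NREMS"]] &&
        emg_amp[["NREMS"]] >= emg_amp[["REMS"]])) {
    stop("EMG amplitudes must rank WAKE > NREMS >= REMS")
  }
  prof <- structure(
    list(name = name, light = light, dark = dark, spectral = spectral,
         emg_amp = emg_amp, spindle_rate = spindle_rate,
         spindle_dur_s = spindle_dur_s,
         latency_offset_min = latency_offset_min),
    class = "strain_profile"
  )
  # fail early if the requested stationary distribution is unreachable
  routing_probs(light$prob, light$mean_bout_s)
  routing_probs(dark$prob, dark$mean_bout_s)
  prof
}

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf("strain profile '%s'\n", x$name))
  for (ph in c("light", "dark")) {
    p <- x[[ph]]$prob[vigilance_states()]
    cat(sprintf("  %s: WAKE %.2f NREMS %.2f REMS %.2f\n", ph,
                p[1], p[2], p[3]))
  }
  cat(sprintf("  spindles: %.1f/NREMS-min, mean %.2f s\n",
              x$spindle_rate, x$spindle_dur_s))
  invisible(x)
}

# Default per-state spectral shaping (BL6-like). Units arbitrary; weights
# multiply unit-RMS band-limited noise components.
#' Default spectral shaping weights for the generator
#' @return Named list of per-state band weights.
#' @export
default_spectral_weights <- function() {
  list(
    WAKE  = c(delta = 0.30, theta = 0.50, sigma = 0.20, broad = 1.00, rems_peak = 0),
    NREMS = c(delta = 1.60, theta = 0.45, sigma = 0.35, broad = 0.35, rems_peak = 0),
    REMS  = c(delta = 0.25, theta = 0.50, sigma = 0.20, broad = 0.30, rems_peak = 1.30)
  )
}

# Solve the embedded bout-chain routing probabilities for one phase.
# With WAKE->REMS transitions excluded the chain is
#   WAKE -> NREMS (always); NREMS -> WAKE (a) / REMS (1-a);
#   REMS -> NREMS (b) / WAKE (1-b)
# and the embedded stationary distribution nu_i is proportional to
# prob_i / mean_bout_i (bout *rates*). Solving the balance equations gives
#   a = 1 - nu_R/nu_N,  b = (nu_N - nu_W)/nu_R.
# Degenerate cases (one or two active states) are handled explicitly.
routing_probs <- function(prob, mean_bout_s) {
  p <- prob[vigilance_states()]
  m <- mean_bout_s[vigilance_states()]
  active <- vigilance_states()[p > 0]
  if (length(active) == 1L) {
    return(list(active = active, a = NA_real_, b = NA_real_))
  }
  if (length(active) == 2L) {
    if (setequal(active, c("WAKE", "REMS"))) {
      stop("WAKE<->REMS only is infeasible: WAKE->REMS transitions are excluded")
    }
    # strict alternation between the two active states: stationary fractions
    # are fixed by the dwell means and must agree with the requested probs
    implied <- m[active] / sum(m[active])
    if (max(abs(implied - p[active] / sum(p[active]))) > 1e-6) {
      stop("with two active states the stationary probabilities are fixed ",
           "by the mean bout durations; requested values are inconsistent")
    }
    return(list(active = active, a = 1, b = 1))
  }
  nu <- p / m
  nu <- nu / sum(nu)
  a <- 1 - nu[["REMS"]] / nu[["NREMS"]]
  b <- (nu[["NREMS"]] - nu[["WAKE"]]) / nu[["REMS"]]
  tol <- 1e-9
  if (a < -tol || a > 1 + tol || b < -tol || b > 1 + tol) {
    stop("requested stationary distribution is infeasible under the ",
         "no-WAKE->REMS constraint (need bout rates with ",
         "rate(NREMS) >= rate(WAKE) >= rate(NREMS) - rate(REMS))")
  }
  list(active = vigilance_states(), a = min(max(a, 0), 1),
       b = min(max(b, 0), 1))
}

#' Built-in strain presets
#'
#' Two presets parameterized from the published group medians of a
#' S1 (129S1/SvImJ) versus BL6 (C57BL/6) baseline-sleep comparison:
#' stationary state probabilities from the 12 h / 11 h state percentages,
#' mean bout durations from the per-phase median bout lengths, spindle
#' densities and durations from the NREMS spindle statistics. The S1-like
#' preset has the weaker diurnal rhythm (more dark-phase sleep, more
#' fragmentation), lower NREMS delta / higher theta weight, a lower REMS
#' 8 Hz peak, a longer sleep-latency offset, and longer spindles.
#'
#' @param name `"S1-like"` or `"BL6-like"`.
#' @return A [strain_profile()].
#' @export
strain_preset <- function(name = c("S1-like", "BL6-like")) {
  name <- match.arg(name)
  norm <- function(x) x / sum(x)
  if (name == "S1-like") {
    spectral <- default_spectral_weights()
    spectral$NREMS[c("delta", "theta", "sigma", "broad")] <-
      c(1.15, 0.70, 0.45, 0.40)
    spectral$REMS[c("theta", "sigma", "broad", "rems_peak")] <-
      c(0.60, 0.30, 0.35, 1.00)
    strain_profile(
      name = "S1-like",
      light = list(
        prob = norm(c(WAKE = 35.90, NREMS = 59.88, REMS = 5.49)),
        mean_bout_s = 60 * c(WAKE = 3.464, NREMS = 4.050, REMS = 0.620)
      ),
      dark = list(
        prob = norm(c(WAKE = 53.11, NREMS = 43.08, REMS = 3.80)),
        mean_bout_s = 60 * c(WAKE = 6.411, NREMS = 3.440, REMS = 0.597)
      ),
      spectral = spectral,
      spindle_rate = 5.5,
      spindle_dur_s = 1.97,
      latency_offset_min = 13
    )
  } else {
    strain_profile(
      name = "BL6-like",
      light = list(
        prob = norm(c(WAKE = 33.92, NREMS = 63.28, REMS = 4.18)),
        mean_bout_s = 60 * c(WAKE = 4.113, NREMS = 3.875, REMS = 0.493)
      ),
      dark = list(
        prob = norm(c(WAKE = 85.13, NREMS = 14.29, REMS = 0.70)),
        mean_bout_s = 60 * c(WAKE = 16.89, NREMS = 2.695, REMS = 0.442)
      ),
      spectral = default_spectral_weights(),
      spindle_rate = 5.9,
      spindle_dur_s = 1.77,
      latency_offset_min = 2
    )
  }
}
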