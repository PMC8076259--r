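#' Extract bouts (run-length encoding of a hypnogram)
#'
#' @param h A [hypnogram()].
#' @return data.frame: `state`, `start_epoch` (1-based), `n_epochs`,
#'   `start_zt_s` (bout onset in ZT seconds), `duration_s`, `phase` (phase
#'   of the bout's first epoch). Bouts tile the hypnogram exactly.
#' @export
extract_bouts <- function(h) {
  r <- rle(h$states)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  start_zt_s <- (h$start_zt * 3600) + (start - 1L) * h$epoch_len
  data.frame(
    state = r$values,
    start_epoch = start,
    n_epochs = r$lengths,
    start_zt_s = start_zt_s,
    duration_s = r$lengths * h$epoch_len,
    phase = zt_phase(start_zt_s / 3600, h$schedule),
    stringsAsFactors = FALSE
  )
}

#' State percentages per circadian bin
#'
#' Percent of epochs spent in each vigilance state, per 2 h bin or per
#' phase (light/dark). Each bin is normalized by its own epoch count, so a
#' partial trailing bin is handled naturally; the three percentages sum to
#' 100 in every non-empty bin.
#'
#' @param h A [hypnogram()].
#' @param bins `"2h"` or `"phase"`.
#' @return data.frame with `bin` (or `phase`), `start_zt`, `end_zt`,
#'   `n_epochs`, and columns `WAKE`, `NREMS`, `REMS`.
#' @export
state_percentages <- function(h, bins = c("phase", "2h")) {
  bins <- match.arg(bins)
  zt <- epoch_zt(h)
  if (bins == "phase") {
    tab <- data.frame(
      phase = c("light", "dark"),
      start_zt = c(0, h$schedule$light_h),
      end_zt = c(h$schedule$light_h, h$schedule$session_h)
    )
    grp <- epoch_phase(h)
    key <- tab$phase
  } else {
    tab <- zt_bins(h$schedule)
    grp <- findInterval(zt, tab$start_zt)
    key <- tab$bin
  }
  pct <- matrix(NA_real_, nrow = nrow(tab), ncol = 3,
                dimnames = list(NULL, vigilance_states()))
  n_in <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    idx <- grp == key[i]
    n_in[i] <- sum(idx)
    if (n_in[i] == 0L) next
    tb <- table(factor(h$states[idx], levels = vigilance_states()))
    pct[i, ] <- 100 * as.numeric(tb) / n_in[i]
  }
  cbind(tab, n_epochs = n_in, as.data.frame(pct))
}

#' Transition counts and percentages within a phase
#'
#' Counts transitions over bout boundaries; a transition belongs to the
#' phase in which its second bout starts. Percentages are of the phase
#' total, keyed W/N, N/W, N/R, R/N, R/W, W/R.
#'
#' @param h A [hypnogram()].
#' @param phase `"light"` or `"dark"`.
#' @return List: `total`, `counts` (named integer), `percentages` (named
#'   numeric; empty when `total` is 0).
#' @export
transition_summary <- function(h, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  b <- extract_bouts(h)
  keys <- c("W/N", "N/W", "N/R", "R/N", "R/W", "W/R")
  counts <- stats::setNames(integer(length(keys)), keys)
  if (nrow(b) >= 2) {
    abbr <- c(WAKE = "W", NREMS = "N", REMS = "R")
    from <- b$state[-nrow(b)]
    to <- b$state[-1]
    in_phase <- b$phase[-1] == phase
    pair <- paste0(abbr[from], "/", abbr[to])[in_phase]
    tb <- table(factor(pair, levels = keys))
    counts[] <- as.integer(tb)
  }
  total <- sum(counts)
  percentages <- if (total > 0) 100 * counts / total else
    stats::setNames(numeric(0), character(0))
  list(total = total, counts = counts, percentages = percentages)
}

#' Sleep latency (mean onset of the first k qualifying bouts)
#'
#' Latency to NREMS or REMS measured as the mean elapsed time from
#' `from_zt` to the onsets of the first `k` bouts of the state lasting at
#' least `min_bout_s` (12 s = 3 epochs by default).
#'
#' @param h A [hypnogram()].
#' @param state `"NREMS"` or `"REMS"`.
#' @param k Number of qualifying bouts to average over (default 5).
#' @param from_zt Reference Zeitgeber hour (default 0 = lights-on).
#' @param min_bout_s Minimum qualifying bout duration in seconds.
#' @return Object of class `latency_result`: list with `state`, `k`,
#'   `onsets_min`, `latency_min` (NA with `insufficient = TRUE` when fewer
#'   than `k` qualifying bouts exist).
#' @export
sleep_latency <- function(h, state = c("NREMS", "REMS"), k = 5, from_zt = 0,
                          min_bout_s = 12) {
  state <- match.arg(state)
  b <- extract_bouts(h)
  b <- b[b$state == state & b$duration_s >= min_bout_s &
           b$start_zt_s >= from_zt * 3600 - 1e-9, , drop = FALSE]
  onsets <- (b$start_zt_s - from_zt * 3600) / 60
  if (nrow(b) < k) {
    return(structure(list(state = state, k = k, onsets_min = onsets,
                          latency_min = NA_real_, insufficient = TRUE),
                     class = "latency_result"))
  }
  onsets <- onsets[seq_len(k)]
  structure(list(state = state, k = k, onsets_min = onsets,
                 latency_min = mean(onsets), insufficient = FALSE),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  if (x$insufficient) {
    cat(sprintf("%s latency: insufficient bouts (%d found, %d required)\n",
                x$state, length(x$onsets_min), x$k))
  } else {
    cat(sprintf("%s latency: %.2f min (mean of first %d bout onsets)\n",
                x$state, x$latency_min, x$k))
  }
  invisible(x)
}

#' REMS latency after dark onset
#'
#' Minutes from dark onset (ZT = light hours) to the onset of the first
#' `k`-th qualifying REMS bout in the dark period (k = 1 by default).
#'
#' @param h A [hypnogram()].
#' @param k Bout count (1 = first REMS bout).
#' @param min_bout_s Minimum qualifying bout duration in seconds.
#' @return A `latency_result` (see [sleep_latency()]); `latency_min` is the
#'   mean onset of the first `k` dark REMS bouts.
#' @export
rems_latency_dark <- function(h, k = 1, min_bout_s = 12) {
  sleep_latency(h, "REMS", k = k, from_zt = h$schedule$light_h,
                min_bout_s = min_bout_s)
}

#' Diurnal change in state percentages
#'
#' Dark-phase minus light-phase percentage per state; the three changes sum
#' to zero because each phase's percentages sum to 100.
#'
#' @param pct Output of `state_percentages(h, bins = "phase")`.
#' @return Named numeric vector (WAKE, NREMS, REMS).
#' @export
diurnal_change <- function(pct) {
  stopifnot(all(c("light", "dark") %in% pct$phase))
  st <- vigilance_states()
  dark <- unlist(pct[pct$phase == "dark", st])
  light <- unlist(pct[pct$phase == "light", st])
  dark - light
}
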