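#' Vigilance-state labels
#'
#' The three vigilance states scored in rodent polysomnography.
#' @return Character vector `c("WAKE", "NREMS", "REMS")`.
#' @export
vigilance_states <- function() c("WAKE", "NREMS", "REMS")

#' Construct a hypnogram
#'
#' A hypnogram is a sequence of vigilance states, one per fixed-length
#' scoring epoch (4 s by default), aligned to Zeitgeber time.
#'
#' @param states Character vector of states, each one of
#'   `"WAKE"`, `"NREMS"`, `"REMS"`.
#' @param epoch_len Epoch length in seconds.
#' @param start_zt Zeitgeber hour of the first epoch (0 = lights on).
#' @param schedule A [light_dark_schedule()].
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_len = 4, start_zt = 0,
                      schedule = light_dark_schedule()) {
  states <- as.character(states)
  if (length(states) == 0L) stop("hypnogram must be non-empty")
  bad <- setdiff(unique(states), vigilance_states())
  if (length(bad) > 0L) {
    stop("unknown state token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(vigilance_states(), collapse = ", "))
  }
  if (!is.numeric(epoch_len) || epoch_len <= 0) stop("epoch_len must be > 0")
  span_h <- start_zt + length(states) * epoch_len / 3600
  if (span_h > schedule$session_h + 1e-9) {
    stop("hypnogram extends past the end of the recording session")
  }
  structure(
    list(states = states, epoch_len = epoch_len, start_zt = start_zt,
         schedule = schedule),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = vigilance_states()))
  cat(sprintf("hypnogram: %d epochs x %g s, start ZT %g\n",
              length(x$states), x$epoch_len, x$start_zt))
  cat(sprintf("  WAKE %.1f%%  NREMS %.1f%%  REMS %.1f%%\n",
              100 * tab[["WAKE"]] / length(x$states),
              100 * tab[["NREMS"]] / length(x$states),
              100 * tab[["REMS"]] / length(x$states)))
  invisible(x)
}

#' Number of epochs in a hypnogram
#' @param h A [hypnogram()].
#' @export
n_epochs <- function(h) length(h$states)

#' Zeitgeber hour of each epoch start
#' @param h A [hypnogram()].
#' @return Numeric vector of ZT hours, one per epoch.
#' @export
epoch_zt <- function(h) {
  h$start_zt + (seq_along(h$states) - 1) * h$epoch_len / 3600
}

#' Phase of each epoch
#' @param h A [hypnogram()].
#' @return Character vector, `"light"`/`"dark"`, one per epoch.
#' @export
epoch_phase <- function(h) zt_phase(epoch_zt(h), h$schedule)

#' Write a hypnogram to CSV
#'
#' Columns: `epoch_index` (1-based), `zt_seconds` (epoch start in ZT
#' seconds), `state`. The roundtrip with [read_hypnogram()] is lossless.
#'
#' @param h A [hypnogram()].
#' @param path Output file path.
#' @export
write_hypnogram <- function(h, path) {
  df <- data.frame(
    epoch_index = seq_along(h$states),
    zt_seconds = round(epoch_zt(h) * 3600, 6),
    state = h$states
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' @param path File written by [write_hypnogram()] (or with the same layout).
#' @param schedule A [light_dark_schedule()].
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, schedule = light_dark_schedule()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "zt_seconds", "state")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)))) {
    stop("non-contiguous epoch indices in hypnogram CSV")
  }
  if (nrow(df) >= 2) {
    steps <- diff(df$zt_seconds)
    if (max(abs(steps - steps[1])) > 1e-6) {
      stop("non-uniform epoch spacing in hypnogram CSV")
    }
    epoch_len <- steps[1]
  } else {
    epoch_len <- 4
  }
  hypnogram(df$state, epoch_len = epoch_len,
            start_zt = df$zt_seconds[1] / 3600, schedule = schedule)
}
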