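#' Simulate a two-strain synthetic cohort of hypnograms
#'
#' One hypnogram per animal, seeds derived deterministically from the
#' cohort seed.
#'
#' @param n_s1,n_bl6 Animals per strain.
#' @param duration_h Recording duration in hours.
#' @param epoch_len Epoch length in seconds.
#' @param seed Cohort seed.
#' @param schedule A [light_dark_schedule()].
#' @param profiles Named list with elements `S1` and `BL6`
#'   ([strain_profile()]s); defaults to the built-in presets.
#' @return data.frame-free list: `animals` (data.frame id/strain/seed) and
#'   `hypnograms` (list, one per animal).
#' @export
synth_cohort <- function(n_s1 = 8, n_bl6 = 7, duration_h = 23, epoch_len = 4,
                         seed = 1, schedule = light_dark_schedule(),
                         profiles = list(S1 = strain_preset("S1-like"),
                                         BL6 = strain_preset("BL6-like"))) {
  animals <- data.frame(
    id = sprintf("%s_%02d", rep(c("S1", "BL6"), c(n_s1, n_bl6)),
                 c(seq_len(n_s1), seq_len(n_bl6))),
    strain = rep(c("S1", "BL6"), c(n_s1, n_bl6)),
    seed = (seed * 1000L + seq_len(n_s1 + n_bl6)) %% .Machine$integer.max,
    stringsAsFactors = FALSE
  )
  hyps <- lapply(seq_len(nrow(animals)), function(i) {
    generate_hypnogram(profiles[[animals$strain[i]]],
                       duration_s = duration_h * 3600,
                       epoch_len = epoch_len, schedule = schedule,
                       seed = animals$seed[i])
  })
  list(animals = animals, hypnograms = hyps)
}

#' Per-animal sleep-architecture metrics
#'
#' Computes, for one hypnogram, the architecture metrics compared between
#' groups: per-phase state percentages, transition totals, bout numbers and
#' mean bout durations per state, NREMS/REMS sleep latency (light period)
#' and first-REMS latency after dark onset.
#'
#' @param h A [hypnogram()].
#' @return One-row data.frame of named metrics
#'   (`<metric>_<phase>` columns).
#' @export
architecture_metrics <- function(h) {
  pct <- state_percentages(h, bins = "phase")
  b <- extract_bouts(h)
  out <- list()
  for (p in c("light", "dark")) {
    row <- pct[pct$phase == p, ]
    for (st in vigilance_states()) {
      out[[paste0(tolower(st), "_pct_", p)]] <- row[[st]]
    }
    out[[paste0("transitions_", p)]] <- transition_summary(h, p)$total
    bp <- b[b$phase == p, , drop = FALSE]
    for (st in vigilance_states()) {
      bs <- bp[bp$state == st, , drop = FALSE]
      out[[paste0(tolower(st), "_bouts_", p)]] <- nrow(bs)
      out[[paste0(tolower(st), "_bout_dur_min_", p)]] <-
        if (nrow(bs) > 0) mean(bs$duration_s) / 60 else NA_real_
    }
  }
  out$nrems_latency_min <- sleep_latency(h, "NREMS")$latency_min
  out$rems_latency_min <- sleep_latency(h, "REMS")$latency_min
  out$rems_latency_dark_min <- rems_latency_dark(h)$latency_min
  dc <- diurnal_change(pct)
  for (st in vigilance_states()) {
    out[[paste0("diurnal_change_", tolower(st))]] <- unname(dc[st])
  }
  as.data.frame(out)
}

#' Architecture metric table for a cohort
#'
#' @param cohort Output of [synth_cohort()] (or a compatible list of
#'   hypnograms with an `animals` table).
#' @return data.frame: one row per animal (id, strain, metrics).
#' @export
cohort_metrics <- function(cohort) {
  rows <- lapply(seq_along(cohort$hypnograms), function(i) {
    cbind(cohort$animals[i, c("id", "strain")],
          architecture_metrics(cohort$hypnograms[[i]]))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Strain-contrast direction recovery over cohort replicates
#'
#' Repeats the synthetic cohort experiment and records, per replicate,
#' whether the cohort-median group contrast has the published dark-period
#' direction: S1 higher NREMS and REMS percentage, more transitions, more
#' NREMS and REMS bouts, shorter WAKE bouts; plus longer light-period NREMS
#' latency and (optionally, from short dark-phase recordings run through
#' the full spindle detector) a higher dark spindle amount.
#'
#' @param n_reps Number of cohort replicates.
#' @param seed Base seed; replicate r uses cohort seed `seed + r`.
#' @param n_s1,n_bl6 Animals per strain.
#' @param duration_h Hypnogram duration (hours).
#' @param spindles Include the spindle-amount contrast?
#' @param spindle_min Minutes of dark-phase recording synthesized per animal
#'   for the spindle contrast.
#' @return data.frame of logicals, one row per replicate, one column per
#'   contrast.
#' @export
direction_recovery <- function(n_reps = 100, seed = 1, n_s1 = 8, n_bl6 = 7,
                               duration_h = 23, spindles = TRUE,
                               spindle_min = 15) {
  profiles <- list(S1 = strain_preset("S1-like"), BL6 = strain_preset("BL6-like"))
  params <- spindle_params()
  one_rep <- function(r) {
    co <- synth_cohort(n_s1, n_bl6, duration_h = duration_h,
                       seed = seed + r, profiles = profiles)
    m <- cohort_metrics(co)
    med <- function(col, strain) stats::median(m[m$strain == strain, col],
                                               na.rm = TRUE)
    res <- c(
      dark_nrems_pct = med("nrems_pct_dark", "S1") > med("nrems_pct_dark", "BL6"),
      dark_rems_pct = med("rems_pct_dark", "S1") > med("rems_pct_dark", "BL6"),
      dark_transitions = med("transitions_dark", "S1") > med("transitions_dark", "BL6"),
      dark_nrems_bouts = med("nrems_bouts_dark", "S1") > med("nrems_bouts_dark", "BL6"),
      dark_rems_bouts = med("rems_bouts_dark", "S1") > med("rems_bouts_dark", "BL6"),
      dark_wake_bout_dur = med("wake_bout_dur_min_dark", "S1") <
        med("wake_bout_dur_min_dark", "BL6"),
      nrems_latency = med("nrems_latency_min", "S1") > med("nrems_latency_min", "BL6")
    )
    if (spindles) {
      amounts <- vapply(seq_len(nrow(co$animals)), function(i) {
        strain <- co$animals$strain[i]
        prof <- profiles[[strain]]
        hseed <- co$animals$seed[i] + 500L
        hyp <- generate_hypnogram(prof, duration_s = spindle_min * 60,
                                  epoch_len = 4, seed = hseed, start_zt = 12)
        gr <- generate_recording(hyp, prof, fs = 125, seed = hseed + 1L)
        # short dark segments can legitimately contain no NREMS at all
        # (especially BL6-like); that is a zero-spindle observation here
        suppressWarnings(
          nrow(detect_spindles_recording(gr$recording, hyp, params))
        )
      }, 0)
      s1 <- co$animals$strain == "S1"
      res <- c(res, dark_spindle_amount =
                 stats::median(amounts[s1]) > stats::median(amounts[!s1]))
    }
    res
  }
  out <- as.data.frame(do.call(rbind, lapply(seq_len(n_reps), one_rep)))
  out
}

#' Scoring validation against generator ground truth
#'
#' Generates short recordings from a profile, runs the full preprocessing +
#' scoring + bout-consolidation chain, and reports per-state percentage
#' errors and epoch-level agreement against the known hypnogram.
#'
#' @param n_seeds Number of independent recordings.
#' @param seed Base seed.
#' @param duration_min Minutes per recording.
#' @param profile A [strain_profile()].
#' @param fs Acquisition sampling rate (downsampled to 125 Hz for scoring).
#' @return data.frame per seed: `agreement_raw` (before smoothing),
#'   `agreement` (after), and absolute state-percentage errors
#'   `err_wake`, `err_nrems`, `err_rems`.
#' @export
scoring_validation <- function(n_seeds = 100, seed = 1, duration_min = 10,
                               profile = strain_preset("BL6-like"),
                               fs = 250) {
  one <- function(r) {
    # start mid light phase (stationary state mix) so all three states are
    # usually present in the short validation segment
    hyp <- generate_hypnogram(profile, duration_s = duration_min * 60,
                              epoch_len = 4, seed = seed + r, start_zt = 3)
    gr <- generate_recording(hyp, profile, fs = fs, seed = seed + r + 10000L)
    rec <- downsample(hardware_bandpass(gr$recording), 125)
    eeg_ep <- epoch_signal(rec, epoch_len = 4, channel = "eeg")
    emg_ep <- epoch_signal(rec, epoch_len = 4, channel = "emg")
    scored <- score_epochs(eeg_ep, emg_ep, schedule = hyp$schedule)
    smoothed <- smooth_bouts(scored)
    pct <- function(states) {
      100 * as.numeric(table(factor(states, levels = vigilance_states()))) /
        length(states)
    }
    err <- abs(pct(smoothed$states) - pct(hyp$states))
    data.frame(
      agreement_raw = mean(scored$states == hyp$states),
      agreement = mean(smoothed$states == hyp$states),
      err_wake = err[1], err_nrems = err[2], err_rems = err[3]
    )
  }
  do.call(rbind, lapply(seq_len(n_seeds), one))
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates generation, architecture metrics, group statistics and
#' (optionally) spindle detection for a synthetic two-strain cohort, and
#' writes all result tables as CSV under `out_dir`. Deterministic under a
#' fixed config.
#'
#' @param config List: `out_dir`; optional `n_s1`, `n_bl6`, `duration_h`,
#'   `seed`, `boot_reps`, `spindles` (logical), `spindle_min`.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(n_s1 = 8, n_bl6 = 7, duration_h = 23,
                                seed = 1, boot_reps = 2000, spindles = FALSE,
                                spindle_min = 15), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "hypnograms"), showWarnings = FALSE)

  co <- synth_cohort(cfg$n_s1, cfg$n_bl6, duration_h = cfg$duration_h,
                     seed = cfg$seed)
  for (i in seq_along(co$hypnograms)) {
    write_hypnogram(co$hypnograms[[i]],
                    file.path(cfg$out_dir, "hypnograms",
                              paste0(co$animals$id[i], ".csv")))
  }
  metrics <- cohort_metrics(co)
  utils::write.csv(metrics, file.path(cfg$out_dir, "architecture_metrics.csv"),
                   row.names = FALSE)

  # group comparisons, S1 = group A, BL6 = group B (AUC = P(BL6 > S1))
  num_cols <- setdiff(names(metrics), c("id", "strain"))
  comps <- do.call(rbind, lapply(num_cols, function(cl) {
    a <- metrics[metrics$strain == "S1", cl]
    b <- metrics[metrics$strain == "BL6", cl]
    if (any(is.na(a)) || any(is.na(b))) {
      return(NULL)
    }
    r <- compare_groups(a, b, reps = cfg$boot_reps, seed = cfg$seed)
    data.frame(metric = cl, median_s1 = r$median_a, median_bl6 = r$median_b,
               p = r$p, U = r$U, auc = r$auc, ci_lo = r$ci[1],
               ci_hi = r$ci[2])
  }))
  utils::write.csv(comps, file.path(cfg$out_dir, "group_comparisons.csv"),
                   row.names = FALSE)

  # 2 h time-course RM-ANOVA per state
  tc <- lapply(co$hypnograms, function(h) {
    state_percentages(h, bins = "2h")
  })
  anova_rows <- do.call(rbind, lapply(vigilance_states(), function(st) {
    mat <- do.call(rbind, lapply(tc, function(x) x[[st]]))
    g1 <- mat[co$animals$strain == "S1", , drop = FALSE]
    g2 <- mat[co$animals$strain == "BL6", , drop = FALSE]
    tab <- rm_anova_sidak(g1, g2)$table
    cbind(state = st, tab)
  }))
  utils::write.csv(anova_rows, file.path(cfg$out_dir, "rm_anova.csv"),
                   row.names = FALSE)

  if (isTRUE(cfg$spindles)) {
    profiles <- list(S1 = strain_preset("S1-like"),
                     BL6 = strain_preset("BL6-like"))
    sp <- do.call(rbind, lapply(seq_len(nrow(co$animals)), function(i) {
      prof <- profiles[[co$animals$strain[i]]]
      hseed <- co$animals$seed[i] + 500L
      hyp <- generate_hypnogram(prof, duration_s = cfg$spindle_min * 60,
                                epoch_len = 4, seed = hseed, start_zt = 12)
      gr <- generate_recording(hyp, prof, fs = 125, seed = hseed + 1L)
      ev <- suppressWarnings(detect_spindles_recording(gr$recording, hyp))
      st <- spindle_stats(ev, hyp)$per_phase
      cbind(id = co$animals$id[i], strain = co$animals$strain[i],
            st[st$phase == "dark", ])
    }))
    utils::write.csv(sp, file.path(cfg$out_dir, "spindle_stats_dark.csv"),
                     row.names = FALSE)
  }

  writeLines(c(
    sprintf("murisleep pipeline run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed=%d n_s1=%d n_bl6=%d duration_h=%g spindles=%s",
            cfg$seed, cfg$n_s1, cfg$n_bl6, cfg$duration_h, cfg$spindles)
  ), file.path(cfg$out_dir, "run_log.txt"))
  invisible(cfg$out_dir)
}
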