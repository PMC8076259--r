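# shared fixtures, built in code

random_hypnogram <- function(n, seed, epoch_len = 4, start_zt = 0) {
  set.seed(seed)
  hypnogram(sample(vigilance_states(), n, replace = TRUE),
            epoch_len = epoch_len, start_zt = start_zt)
}

# hypnogram from a run-length spec, e.g. runs_hyp(W = 10, N = 2, W = 10)
runs_hyp <- function(..., epoch_len = 4, start_zt = 0) {
  spec <- c(...)
  full <- c(W = "WAKE", N = "NREMS", R = "REMS")
  hypnogram(rep(full[names(spec)], spec), epoch_len = epoch_len,
            start_zt = start_zt)
}

# tie-free sample pair with a prescribed U statistic for groups (n_a, n_b):
# place the k = U 'b' wins as the largest values
samples_with_u <- function(U, n_a, n_b) {
  # a = 1..n_a; choose b so that exactly U pairs have b > a
  b <- numeric(n_b)
  full <- U %/% n_a     # b's that beat every a
  part <- U %% n_a      # one b beating `part` a's
  stopifnot(full <= n_b)
  k <- 1
  for (i in seq_len(full)) { b[k] <- n_a + i; k <- k + 1 }
  if (part > 0) { b[k] <- part + 0.5; k <- k + 1 } # beats a in {1..part}
  while (k <= n_b) { b[k] <- -k; k <- k + 1 }
  list(a = seq_len(n_a), b = b)
}

# independent mixed-design sums-of-squares oracle (balanced groups only)
rm_anova_oracle <- function(g1, g2) {
  stopifnot(nrow(g1) == nrow(g2))
  n <- nrow(g1); Tn <- ncol(g1)
  all <- rbind(g1, g2)
  grp <- rep(1:2, each = n)
  grand <- mean(all)
  gm <- c(mean(g1), mean(g2))
  tm <- colMeans(all)
  sm <- rowMeans(all)
  ss_strain <- Tn * n * sum((gm - grand)^2)
  ss_subj <- Tn * sum((sm - gm[grp])^2)
  ss_time <- 2 * n * sum((tm - grand)^2)
  cell <- rbind(colMeans(g1), colMeans(g2)) # group x time means
  ss_int <- n * sum((sweep(sweep(cell, 1, gm), 2, tm) + grand)^2)
  resid <- all - sm - cell[grp, ] + gm[grp]
  ss_err <- sum(resid^2)
  c(
    F_strain = (ss_strain / 1) / (ss_subj / (2 * n - 2)),
    F_time = (ss_time / (Tn - 1)) / (ss_err / ((2 * n - 2) * (Tn - 1))),
    F_int = (ss_int / (Tn - 1)) / (ss_err / ((2 * n - 2) * (Tn - 1)))
  )
}
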