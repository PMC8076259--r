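#' Exact two-tailed tail probability of the Mann-Whitney U statistic
#'
#' Computes p = 2 x P(U' <= U) under the tie-free null hypothesis by the
#' standard partition-counting recursion (the number of group labelings
#' yielding each U value), capped at 1. Half-integer U values arise only
#' under ties and are rejected here; use the permutation path of
#' [mannwhitney()] for tied data.
#'
#' @param U Observed U (the smaller of the two group U statistics).
#' @param n_a,n_b Group sizes.
#' @return Two-tailed p value.
#' @export
exact_u_tail <- function(U, n_a, n_b) {
  if (U < 0 || U > n_a * n_b) stop("U must lie in [0, n_a * n_b]")
  if (abs(U - round(U)) > 1e-9) {
    stop("non-integer U indicates ties; use the permutation path of mannwhitney()")
  }
  U <- as.integer(round(U))
  # counts[u + 1] = number of labelings with statistic u, built by adding
  # the n_a 'a' ranks one at a time: f(u; m, n_b) = f(u - n_b; m - 1, n_b)
  # accumulated via the bounded-part partition recurrence
  counts <- u_null_counts(n_a, n_b)
  p <- 2 * sum(counts[1:(U + 1)]) / sum(counts)
  min(p, 1)
}

# Null distribution of U for group sizes (m, n) as labeling counts, via the
# classic recurrence c(u; i, j) = c(u; i, j-1) + c(u-j; i-1, j) (condition on
# whether the largest pooled observation belongs to group A or B).
u_null_counts <- function(m, n) {
  maxu <- m * n
  C <- array(0, dim = c(m + 1, n + 1, maxu + 1))
  C[1, , 1] <- 1
  C[, 1, 1] <- 1
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      for (u in 0:(i * j)) {
        v <- C[i + 1, j, u + 1]
        if (u - j >= 0) v <- v + C[i, j + 1, u - j + 1]
        C[i + 1, j + 1, u + 1] <- v
      }
    }
  }
  C[m + 1, n + 1, ]
}

#' AUC effect size (common-language effect size)
#'
#' Probability that a random observation from group B exceeds one from
#' group A, ties counted half: `AUC = [#(b > a) + 0.5 #(b = a)] / (n_a n_b)`.
#'
#' @param a,b Numeric samples.
#' @return AUC in [0, 1].
#' @export
auc_effect <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  cmp <- outer(b, a, ">") + 0.5 * outer(b, a, "==")
  mean(cmp)
}

#' Reconstruct the AUC effect size from a U statistic
#'
#' Under the P(B > A) orientation, `AUC = 1 - U/(n_a n_b)` when the group-B
#' values tend to be larger (U counted from the smaller side), and
#' `U/(n_a n_b)` when group A tends larger.
#'
#' @param U Mann-Whitney U (the reported min-side statistic).
#' @param n_a,n_b Group sizes.
#' @param direction `"b_greater"` or `"a_greater"`: which group's values
#'   are the larger ones (e.g. by group medians).
#' @return AUC in [0, 1].
#' @export
auc_from_u <- function(U, n_a, n_b, direction = c("b_greater", "a_greater")) {
  direction <- match.arg(direction)
  if (direction == "b_greater") 1 - U / (n_a * n_b) else U / (n_a * n_b)
}

#' Mann-Whitney U test with AUC effect size
#'
#' U is the smaller of the two group statistics (mid-rank tie handling, so
#' half-integers can occur with ties). The exact two-tailed p is
#' 2 x min(lower tail, upper tail), capped at 1: tie-free samples with
#' `n_a + n_b <= 20` use the partition-count null of [exact_u_tail()];
#' tied samples use full enumeration of group labelings when feasible and
#' a seeded Monte-Carlo permutation fallback otherwise. Larger samples use
#' the normal approximation with tie correction.
#'
#' @param a,b Numeric samples (group A, group B).
#' @param method `"exact"` or `"approx"`.
#' @param seed RNG seed for the Monte-Carlo fallback.
#' @param mc_reps Monte-Carlo permutation count.
#' @return List of class `comparison_result`: `U`, `p`, `auc`
#'   (P(B > A)), `n_a`, `n_b`, `method`.
#' @export
mannwhitney <- function(a, b, method = c("exact", "approx"), seed = 1,
                        mc_reps = 20000) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled) # mid-ranks
  U_a <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  U_b <- n_a * n_b - U_a
  U <- min(U_a, U_b)
  ties <- any(duplicated(pooled))

  if (method == "exact" && n_a + n_b <= 20) {
    if (!ties) {
      p <- exact_u_tail(U, n_a, n_b)
    } else {
      n_lab <- choose(n_a + n_b, n_a)
      u_of <- function(idx) {
        sum(rk[idx]) - n_a * (n_a + 1) / 2
      }
      if (n_lab <= 2e5) {
        labs <- utils::combn(n_a + n_b, n_a)
        us <- apply(labs, 2, u_of)
      } else {
        us <- with_seed(seed, replicate(mc_reps, u_of(sample(n_a + n_b, n_a))))
      }
      # two-tailed on the (unfolded) permutation distribution of U_a
      p <- min(1, 2 * min(mean(us <= U_a + 1e-9), mean(us >= U_a - 1e-9)))
    }
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    n <- n_a + n_b
    sig2 <- n_a * n_b / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(z))
    }
  }

  structure(list(U = U, p = p, auc = auc_effect(a, b), n_a = n_a, n_b = n_b,
                 method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, p = %.4g (n = %d vs %d), AUC = %.3f",
              x$U, x$p, x$n_a, x$n_b, x$auc))
  if (!is.null(x$ci)) cat(sprintf(" [%.3f; %.3f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Bootstrap percentile confidence interval for the AUC effect size
#'
#' Resamples the two groups independently with replacement and returns the
#' percentile interval of the AUC over the resamples.
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @param reps Bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return `c(lo, hi)`.
#' @export
bootstrap_auc_ci <- function(a, b, reps = 10000, level = 0.95, seed = 1) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (reps < 100) warning("fewer than 100 bootstrap replicates")
  with_seed(seed, {
    aucs <- replicate(reps, auc_effect(
      a[sample.int(length(a), replace = TRUE)],
      b[sample.int(length(b), replace = TRUE)]
    ))
    unname(stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Full two-group comparison (U, exact p, AUC, bootstrap CI)
#'
#' @param a,b Numeric samples (group A, group B; the AUC is P(B > A)).
#' @param reps,seed Bootstrap settings, see [bootstrap_auc_ci()].
#' @return A `comparison_result` with `ci` and group medians attached.
#' @export
compare_groups <- function(a, b, reps = 10000, seed = 1) {
  res <- mannwhitney(a, b, seed = seed)
  res$ci <- bootstrap_auc_ci(a, b, reps = reps, seed = seed)
  res$median_a <- stats::median(a)
  res$median_b <- stats::median(b)
  res
}

#' Two-way repeated-measures ANOVA with Sidak post-hoc comparisons
#'
#' Mixed design with one between-subject factor (strain/group) and one
#' within-subject factor (time): fitted by the standard sums-of-squares
#' decomposition (`aov` with a subject error stratum). Post-hoc group
#' comparisons at each time point use Welch t tests with Sidak adjustment
#' `p_adj = 1 - (1 - p)^m`, m = number of time points.
#'
#' @param g1,g2 Numeric matrices (subjects x time points), complete, with
#'   identical column counts.
#' @param posthoc Compute per-time-point comparisons?
#' @return List of class `anova_result`: `table` (effect, df1, df2, F, p for
#'   strain, time, time:strain) and `posthoc` (time, p, p_adj).
#' @export
rm_anova_sidak <- function(g1, g2, posthoc = TRUE) {
  g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  if (ncol(g1) != ncol(g2)) stop("groups must share the time grid")
  if (any(is.na(g1)) || any(is.na(g2))) stop("complete matrices required")
  n1 <- nrow(g1); n2 <- nrow(g2); Tn <- ncol(g1)
  df <- data.frame(
    y = c(as.vector(t(g1)), as.vector(t(g2))),
    subject = factor(rep(seq_len(n1 + n2), each = Tn)),
    strain = factor(rep(c("g1", "g2"), times = c(n1 * Tn, n2 * Tn))),
    time = factor(rep(seq_len(Tn), times = n1 + n2))
  )
  fit <- stats::aov(y ~ strain * time + Error(subject), data = df)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  # guard against numerically-zero strata (e.g. constant input matrices),
  # where aov's F is 0/0 noise: an effect with ~zero sum of squares is a
  # null effect (F = 0), one with real SS over a zero error stratum is
  # unbounded (F = Inf)
  tol <- 1e-12 * (sum((df$y - mean(df$y))^2) + 1)
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
    out <- c(df = tab$Df[i], F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
    if (tab$`Sum Sq`[r] < tol) {
      if (tab$`Sum Sq`[i] < tol) {
        out["F"] <- 0; out["p"] <- 1
      } else {
        out["F"] <- Inf; out["p"] <- 0
      }
    }
    out
  }
  b_err_df <- between$Df[match("Residuals", trimws(rownames(between)))]
  w_err_df <- within$Df[match("Residuals", trimws(rownames(within)))]
  st <- pick(between, "strain")
  tm <- pick(within, "time")
  ix <- pick(within, "strain:time")
  table <- data.frame(
    effect = c("strain", "time", "time:strain"),
    df1 = c(st["df"], tm["df"], ix["df"]),
    df2 = c(b_err_df, w_err_df, w_err_df),
    F = c(st["F"], tm["F"], ix["F"]),
    p = c(st["p"], tm["p"], ix["p"]),
    row.names = NULL
  )
  ph <- NULL
  if (posthoc) {
    p_t <- vapply(seq_len(Tn), function(j) {
      if (stats::sd(g1[, j]) == 0 && stats::sd(g2[, j]) == 0) {
        if (mean(g1[, j]) == mean(g2[, j])) 1 else 0
      } else {
        stats::t.test(g1[, j], g2[, j])$p.value
      }
    }, 0)
    ph <- data.frame(time = seq_len(Tn), p = p_t,
                     p_adj = pmin(1, 1 - (1 - p_t)^Tn))
  }
  structure(list(table = table, posthoc = ph), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Normal QQ-plot coordinates
#'
#' Observed order statistics against standard normal quantiles at plotting
#' positions (i - 0.5)/n; used to assess normality before choosing between
#' parametric and rank-based tests.
#'
#' @param x Numeric sample, n >= 3.
#' @return data.frame: `theoretical`, `observed`.
#' @export
qq_points <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  data.frame(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    observed = sort(x)
  )
}
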