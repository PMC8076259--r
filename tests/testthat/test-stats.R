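test_that("exact U tail matches the closed-form null distribution", {
  # spot checks against R's Wilcoxon null (the full enumeration sweep lives
  # in the acceptance suite)
  for (nn in list(c(8, 7), c(5, 5), c(3, 9))) {
    for (U in c(0, 1, 3, floor(nn[1] * nn[2] / 2))) {
      expect_equal(exact_u_tail(U, nn[1], nn[2]),
                   min(1, 2 * stats::pwilcox(U, nn[1], nn[2])),
                   tolerance = 1e-12)
    }
  }
  expect_equal(exact_u_tail(0, 1, 1), 1) # smallest case, capped
  expect_error(exact_u_tail(3.5, 8, 7), "ties")
  expect_error(exact_u_tail(60, 8, 7), "0, n_a")
})

test_that("mannwhitney reproduces published (U, p) pairings", {
  cases <- list(c(3, 0.002), c(6, 0.009), c(8, 0.021), c(2, 0.001))
  for (cs in cases) {
    s <- samples_with_u(cs[1], 8, 7)
    r <- mannwhitney(s$a, s$b)
    expect_equal(r$U, cs[1])
    expect_equal(round(r$p, 3), cs[2])
  }
})

test_that("mannwhitney agrees with wilcox.test on random tie-free samples", {
  set.seed(10)
  for (i in 1:30) {
    a <- rnorm(sample(3:9, 1))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    r <- mannwhitney(a, b)
    w <- stats::wilcox.test(b, a, exact = TRUE)
    expect_equal(min(w$statistic, length(a) * length(b) - w$statistic),
                 r$U)
    expect_equal(r$p, w$p.value, tolerance = 1e-10)
  }
})

test_that("fully tied samples give the null U and p = 1", {
  r <- mannwhitney(rep(2, 8), rep(2, 7))
  expect_equal(r$U, 8 * 7 / 2)
  expect_equal(r$p, 1)
  expect_equal(r$auc, 0.5)
  expect_error(mannwhitney(numeric(0), 1:3), "empty")
})

test_that("AUC effect size counts pairs with half-credit for ties", {
  expect_equal(auc_effect(rep(1, 5), rep(1, 4)), 0.5)
  expect_equal(auc_effect(1:5, 6:9), 1)
  expect_equal(auc_effect(6:9, 1:5), 0)
  set.seed(11)
  for (i in 1:50) {
    a <- sample(1:10, 6, replace = TRUE)
    b <- sample(1:10, 8, replace = TRUE)
    expect_equal(auc_effect(a, b), 1 - auc_effect(b, a))
    r <- mannwhitney(a, b)
    # AUC/U consistency: AUC is U/(nm) from one side or the other
    expect_true(abs(r$auc - r$U / 48) < 1e-12 ||
                abs(r$auc - (1 - r$U / 48)) < 1e-12)
  }
})

test_that("bootstrap CI is deterministic and degenerates correctly", {
  expect_equal(bootstrap_auc_ci(1:5, 11:15, reps = 500, seed = 3), c(1, 1))
  expect_equal(bootstrap_auc_ci(c(1, 1), c(1, 1), reps = 500, seed = 3),
               c(0.5, 0.5))
  set.seed(99)
  a <- rnorm(8); b <- rnorm(7, 0.5)
  ci1 <- bootstrap_auc_ci(a, b, reps = 1000, seed = 42)
  ci2 <- bootstrap_auc_ci(a, b, reps = 1000, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
  expect_warning(bootstrap_auc_ci(a, b, reps = 50, seed = 1), "100")
})

test_that("compare_groups bundles medians, exact p, AUC and CI", {
  set.seed(12)
  a <- rnorm(8); b <- rnorm(7, 1)
  r <- compare_groups(a, b, reps = 500, seed = 2)
  expect_equal(r$median_a, stats::median(a))
  expect_equal(r$auc, auc_effect(a, b))
  expect_true(r$ci[1] <= r$ci[2])
})

test_that("RM-ANOVA handles degenerate limits", {
  g <- matrix(5, 4, 6)
  r <- rm_anova_sidak(g, g)
  expect_equal(r$table$F, c(0, 0, 0))
  expect_equal(r$table$p, c(1, 1, 1))
  expect_equal(r$posthoc$p_adj, rep(1, 6))

  r2 <- rm_anova_sidak(g, g + 2) # constant offset, zero within-noise
  expect_true(r2$table$F[r2$table$effect == "strain"] > 1e6)
  expect_equal(r2$table$F[r2$table$effect == "time:strain"], 0)
})

test_that("RM-ANOVA F values match the sums-of-squares oracle", {
  set.seed(13)
  for (i in 1:5) {
    g1 <- matrix(rnorm(6 * 12), 6, 12)
    g2 <- matrix(rnorm(6 * 12, mean = 0.3), 6, 12)
    r <- rm_anova_sidak(g1, g2, posthoc = FALSE)
    o <- rm_anova_oracle(g1, g2)
    expect_equal(r$table$F, unname(o), tolerance = 1e-10)
    expect_equal(r$table$df1, c(1, 11, 11))
    expect_equal(r$table$df2, c(10, 110, 110))
  }
})

test_that("Sidak adjustment is monotone in p and in family size", {
  p <- seq(0.001, 0.5, length.out = 20)
  adj12 <- 1 - (1 - p)^12
  expect_true(all(diff(adj12) > 0))
  g1 <- matrix(rnorm(4 * 3), 4, 3)
  g2 <- matrix(rnorm(4 * 3), 4, 3)
  ph <- rm_anova_sidak(g1, g2)$posthoc
  expect_true(all(ph$p_adj >= ph$p))
  expect_true(all(ph$p_adj <= 1))
})

test_that("QQ points are sorted observed vs normal plotting positions", {
  set.seed(14)
  x <- rnorm(10000)
  q <- qq_points(x)
  slope <- stats::coef(stats::lm(observed ~ theoretical, data = q))[2]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)

  qc <- qq_points(rep(3, 5))
  expect_true(all(qc$observed == 3))
  expect_equal(qq_points(c(3, 1, 2))$observed, c(1, 2, 3))
  expect_identical(qq_points(x), qq_points(sample(x)))
  expect_error(qq_points(c(1, 2)), "at least 3")
})

test_that("AUC reconstruction from U matches both orientations", {
  expect_equal(auc_from_u(3, 8, 7, "b_greater"), 1 - 3 / 56)
  expect_equal(auc_from_u(3, 8, 7, "a_greater"), 3 / 56)
  # consistency with the pair-counting AUC on constructed samples
  s <- samples_with_u(6, 8, 7)
  expect_equal(auc_effect(s$a, s$b), 6 / 56)
})
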