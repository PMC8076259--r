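#!/usr/bin/env Rscript
# Statistics layer in isolation: reconstruct the published AUC effect sizes
# from the printed U statistics, verify the exact Mann-Whitney machinery
# against R's Wilcoxon null, and demonstrate QQ normality data and the
# RM-ANOVA + Sidak post-hoc on the synthetic cohort time courses.

library(murisleep)

dir.create("results", showWarnings = FALSE)

# AUC reconstruction from printed U (n = 8 vs 7, P(BL6 > S1)); direction
# from which group's median is larger
recon <- data.frame(
  comparison = c("dark WAKE %", "dark NREMS %", "dark REMS %",
                 "dark transitions", "dark REMS bouts", "NREMS latency"),
  U = c(3, 3, 2, 6, 1, 8),
  larger = c("BL6", "S1", "S1", "S1", "S1", "S1")
)
recon$auc <- mapply(function(U, larger) {
  auc_from_u(U, 8, 7, if (larger == "BL6") "b_greater" else "a_greater")
}, recon$U, recon$larger)
recon$p_exact <- vapply(recon$U, exact_u_tail, 0, n_a = 8, n_b = 7)
write.csv(recon, "results/06_auc_reconstruction.csv", row.names = FALSE)
cat("AUC effect sizes and exact p reconstructed from U (n = 8 vs 7):\n")
print(recon, row.names = FALSE, digits = 3)

# RM-ANOVA with Sidak post-hoc on cohort 2 h NREMS time courses
co <- synth_cohort(n_s1 = 8, n_bl6 = 7, duration_h = 23, seed = 1)
tc <- vapply(co$hypnograms,
             function(h) state_percentages(h, "2h")$NREMS, numeric(12))
g1 <- t(tc[, co$animals$strain == "S1"])
g2 <- t(tc[, co$animals$strain == "BL6"])
an <- rm_anova_sidak(g1, g2)
cat("\nTwo-way RM ANOVA on 2 h NREMS percentages (strain x time):\n")
print(an$table, row.names = FALSE, digits = 4)
sig <- an$posthoc[an$posthoc$p_adj < 0.05, ]
cat(sprintf("Sidak post-hoc: %d of 12 time bins differ at adjusted p < 0.05\n",
            nrow(sig)))
write.csv(an$posthoc, "results/06_posthoc_nrems.csv", row.names = FALSE)

# QQ data for a normality check of one metric
m <- cohort_metrics(co)
qq <- qq_points(m$nrems_pct_dark)
write.csv(qq, "results/06_qq_nrems_dark.csv", row.names = FALSE)
cat("QQ coordinates for dark NREMS% written to results/06_qq_nrems_dark.csv\n")
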