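#!/usr/bin/env Rscript
# Validate the stand-in epoch scorer against generator ground truth:
# synthesize short EEG/EMG recordings, run the hardware-filter emulation,
# downsample to 125 Hz, score 4 s epochs, apply the 12 s bout floor, and
# compare against the known hypnograms.

library(murisleep)

dir.create("results", showWarnings = FALSE)

v <- scoring_validation(n_seeds = 20, seed = 1, duration_min = 10)
write.csv(v, "results/02_scoring_validation.csv", row.names = FALSE)

cat("Scored 20 synthetic recordings (10 min each, BL6-like profile).\n")
cat(sprintf("Epoch-level agreement with ground truth: median %.3f (raw %.3f)\n",
            median(v$agreement), median(v$agreement_raw)))
cat(sprintf("Median absolute state-percentage error: WAKE %.2f, NREMS %.2f, REMS %.2f points\n",
            median(v$err_wake), median(v$err_nrems), median(v$err_rems)))
cat("Table written to results/02_scoring_validation.csv\n")
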