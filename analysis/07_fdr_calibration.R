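#!/usr/bin/env Rscript
# FDR calibration under independent grouped p-values: 1000 replicates of
# 500 hypotheses in 25 groups of 20, five signal groups with 10 non-null
# hypotheses each (p ~ Beta(0.1, 1)). This is the self-contained check of
# the headline claim - control of the false discovery rate at the nominal
# 5% level - and of the power ordering among the procedures.
# Writes: results/07_fdr_calibration.tsv

suppressMessages(library(groupBH))
dir.create("results", showWarnings = FALSE)

cal <- fdr_calibration(n_reps = 1000, alpha = 0.05, seed = 1)
cal$fdr <- round(cal$fdr, 5)
cal$power <- round(cal$power, 4)
cal$mc_se <- signif(cal$mc_se, 3)
write.table(cal, "results/07_fdr_calibration.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(cal, row.names = FALSE)
cat("\nBH stays below the nominal 5%; the adaptive grouped procedures buy\n",
    "power (TST-GBH most, then LSL-GBH, then SABHA) at the price of a\n",
    "small finite-sample FDR excess driven by estimation noise in the\n",
    "size-20 groups - the liberality that motivates the control study.\n")
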