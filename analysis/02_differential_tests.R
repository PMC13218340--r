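#!/usr/bin/env Rscript
# Directional paired delta-delta-Ct t-tests on complete cases (offset
# delta = 1 Ct, i.e. a 2-fold null boundary), plus the median-imputation
# sensitivity comparison: imputation deflates per-miRNA variances and
# relaxes the realized BH threshold.
# Writes: results/02_tests.tsv, results/02_imputation_sensitivity.tsv

suppressMessages(library(groupBH))
dir.create("results", showWarnings = FALSE)

d <- generate_dataset(simulation_params(seed = 1))
ddct <- compute_ddct(d$expression)

tests <- test_all(ddct, delta = 1)
write_results(tests, "results/02_tests.tsv")

p_cc <- setNames(tests$p_raw, tests$mirna_id)
bh_cc <- bh_stepup(p_cc, 0.05)

tests_imp <- test_all(median_impute(ddct), delta = 1)
p_imp <- setNames(tests_imp$p_raw, tests_imp$mirna_id)
bh_imp <- bh_stepup(p_imp, 0.05)

sens <- data.frame(
  analysis = c("complete_case", "median_imputed"),
  n_tested = nrow(tests),
  bh_rejections = c(bh_cc$k_star, bh_imp$k_star),
  bh_threshold = c(bh_cc$threshold, bh_imp$threshold))
write.table(sens, "results/02_imputation_sensitivity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- head(tests[order(tests$p_raw), c("mirna_id", "direction",
                                        "mean_ddct", "p_raw",
                                        "n_missing_pairs")], 5)
cat(sprintf("Tested %d miRNAs; %d untestable (flagged p = 1).\n",
            nrow(tests), sum(tests$note != "")))
cat("Top of the table (ascending raw p):\n")
print(top, row.names = FALSE, digits = 3)
cat(sprintf(
  "BH at 5%%: %d rejections at threshold %.2g on complete cases vs %d at\n",
  bh_cc$k_star, bh_cc$threshold, bh_imp$k_star),
  sprintf(
  "%.2g after median imputation - imputation relaxes the cutoff.\n",
  bh_imp$threshold))
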