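#!/usr/bin/env Rscript
# Control study: reassign miRNAs to the scheme (c) groups uniformly at
# random (sizes preserved, tumor-normal pairing untouched) 1000 times and
# rerun the grouped procedures on the fixed p-values. Detections that
# survive randomization are not attributable to the positional grouping.
# Writes: results/06_control_frequencies.tsv, results/06_control_summary.tsv

suppressMessages(library(groupBH))
dir.create("results", showWarnings = FALSE)

d <- generate_dataset(simulation_params(seed = 1))
tests <- test_all(compute_ddct(d$expression), delta = 1)
p <- setNames(tests$p_raw, tests$mirna_id)
scheme_c <- build_scheme(d$annotation, "chrom_strand_arm")

bh_set <- bh_stepup(p, 0.05)$rejected
groups_c <- scheme_c$assignment[names(p)]
informative <- list(
  tst_gbh = gbh(p, groups_c, 0.05, "tst")$rejected,
  lsl_gbh = gbh(p, groups_c, 0.05, "lsl")$rejected,
  sabha = sabha(p, groups_c, 0.05)$rejected)
non_bh <- setdiff(unique(unlist(informative)), bh_set)

res <- control_study(p, scheme_c, methods = c("tst_gbh", "lsl_gbh",
                                              "sabha"),
                     alpha = 0.05, n_reps = 1000, seed = 1,
                     bh_set = bh_set, comparison_set = non_bh)

# Table-2 analog: miRNAs detected under informative scheme (c) or in
# >50% of random assignments
freq <- data.frame(mirna_id = names(p),
                   p_raw = unname(p),
                   tst_gbh = res$tst_gbh$freq[names(p)],
                   lsl_gbh = res$lsl_gbh$freq[names(p)],
                   sabha = res$sabha$freq[names(p)])
for (m in names(informative))
  freq[[paste0(m, "_scheme_c")]] <- freq$mirna_id %in% informative[[m]]
keep <- freq$mirna_id %in% unlist(informative) |
  pmax(freq$tst_gbh, freq$lsl_gbh, freq$sabha) > 0.5
freq <- freq[keep, ]
freq <- freq[order(freq$p_raw), ]
write.table(format(freq, digits = 4), "results/06_control_frequencies.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

summary_tab <- summarize_control(res)
write.table(summary_tab, "results/06_control_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Informative scheme (c) detections: TST-GBH %d, LSL-GBH %d, SABHA %d; BH %d.\n",
            lengths(informative)[["tst_gbh"]],
            lengths(informative)[["lsl_gbh"]],
            lengths(informative)[["sabha"]], length(bh_set)))
cat("Across 1000 random reassignments (mean detections / BH overlap):\n")
print(summary_tab[summary_tab$statistic != "nonbh_overlap", ],
      row.names = FALSE, digits = 3)
cat("Detections lost under randomization are attributable to the grouping.\n")
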