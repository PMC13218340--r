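#!/usr/bin/env Rscript
# The central comparison: BH vs TST-GBH, LSL-GBH and group SABHA at the
# 5% level across every grouping scheme. Emits the detection table
# (miRNAs found by at least one method, with per-method/scheme flags),
# the count-versus-scheme sweep, and the enter/exit transitions between
# consecutive schemes.
# Writes: results/04_detected_mirnas.tsv, results/04_sweep_counts.tsv,
#         results/04_sweep_transitions.tsv

suppressMessages(library(groupBH))
dir.create("results", showWarnings = FALSE)

d <- generate_dataset(simulation_params(seed = 1))
cfg <- run_config(alpha = 0.05, delta = 1, k_values = seq(25L, 5L, by = -2L),
                  seed = 1)
out <- run_pipeline(cfg, d$expression, d$annotation, verbose = TRUE)

flag_cols <- grep("\\.", names(out$results), value = TRUE)
detected <- out$results[rowSums(out$results[flag_cols]) > 0, ]
detected <- merge(detected, d$truth[c("mirna_id", "is_null")],
                  by = "mirna_id")
detected <- detected[order(detected$p_raw), ]
write_results(detected, "results/04_detected_mirnas.tsv")
write.table(out$sweep$counts, "results/04_sweep_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(out$sweep$transitions, "results/04_sweep_transitions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cnt <- out$sweep$counts
cat("\nDetections per scheme:\n")
print(cnt, row.names = FALSE)
extra <- detected$mirna_id[!detected[[grep("^bh\\.", names(detected))[1]]]]
cat(sprintf(
  "\n%d miRNAs detected by at least one method; BH alone finds %d of them;\n",
  nrow(detected), cnt$bh[1]),
  sprintf(
  "%d are found only by group-adaptive procedures. False detections among\n",
  length(extra)),
  sprintf("all flagged miRNAs: %d of %d (truth known by simulation).\n",
          sum(detected$is_null), nrow(detected)))
cat("TST-GBH is the most liberal throughout; SABHA stays closest to BH.\n")
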