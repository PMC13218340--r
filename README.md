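# groupBH

Group-adaptive Benjamini–Hochberg FDR control for paired qPCR miRNA
expression studies, built as an analysis workflow over a tested R
package.

## The problem

Targeted qPCR miRNA panels on small paired cohorts (18 tumor–normal
pairs, 522 miRNAs here) test far more hypotheses than they have samples.
The standard Benjamini–Hochberg (BH) step-up controls the false
discovery rate at level α by rejecting the k\* smallest p-values,
k\* = max{k : p₍ₖ₎ ≤ kα/n}, but its single common threshold becomes very
stringent in this regime and weak signals are lost. Physically proximal
miRNAs tend to be co-regulated, so partitioning the panel by genomic
position (chromosome, strand, arm, and adjacency blocks of at most k
members) yields groups in which true signals concentrate. Group-adaptive
BH procedures estimate the proportion of true nulls π₀ within each group
g and reweight the p-values, pᵂᵢ = pᵢ·π̂₍g₎/(1−π̂₍g₎) for the grouped BH
family (TST-GBH with the two-stage estimate at α′ = α/(1+α), LSL-GBH
with the least-slope estimate) or q̂₍g₎·pᵢ for group SABHA (τ-censored
Storey estimate clipped to [ε, 1]; τ = 0.5, ε = 0.1), then run a
step-up on the weighted values. Hypotheses in signal-rich groups face a
laxer effective threshold while overall FDR control is retained.

The package implements, with tests: paired ΔΔCt directional t-tests on
complete cases (one-sided against a 2-fold null boundary, δ = 1 Ct, the
direction fixed by the median ΔΔCt sign), position-based grouping
schemes with singleton merging and k-refinements, BH / TST-GBH /
LSL-GBH / group SABHA, a random-group-assignment control study,
intra/inter-group correlation diagnostics under an exchangeable
random-effects model, and a seeded synthetic miRNAome generator with
detection-limit (MNAR) missingness standing in for the original cohort.

## Worked example

```r
library(groupBH)

d <- generate_dataset(simulation_params(seed = 1))   # 18 x 522 panel
tests <- test_all(compute_ddct(d$expression), delta = 1)
p <- setNames(tests$p_raw, tests$mirna_id)

scheme_c <- build_scheme(d$annotation, "chrom_strand_arm")
groups <- scheme_c$assignment[names(p)]

length(bh_stepup(p, 0.05)$rejected)          # 13
length(gbh(p, groups, 0.05, "tst")$rejected) # 21
length(gbh(p, groups, 0.05, "lsl")$rejected) # 16
length(sabha(p, groups, 0.05)$rejected)      # 15
```

On this synthetic panel BH finds 13 deregulated miRNAs at the 5% level;
the group-adaptive procedures find 15–21 using the same p-values, the
extra detections coming from groups with low estimated null
proportions. The numbered scripts under `analysis/` run the full study
and print what they find, writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generates the panel, characterizes missingness (~55% of miRNAs with ≥1 missing pair, none >50%) |
| `02_differential_tests.R` | ΔΔCt t-tests; median-imputation sensitivity (BH threshold 0.0012 → 0.0015) |
| `03_grouping_schemes.R` | scheme family (22 groups at scheme (a) up to 120 at k = 5) |
| `04_fdr_comparison.R` | all four methods × all schemes; detection table and enter/exit sweep |
| `05_correlations.R` | intra- vs inter-group correlation per scheme (≈0.06–0.13 vs ≈0.02) |
| `06_control_study.R` | 1000 random group reassignments; which detections the grouping explains |
| `07_fdr_calibration.R` | empirical FDR and power of the four methods under grouped simulation |

Run them from the repository root after installing, e.g.
`Rscript analysis/04_fdr_comparison.R`.

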