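---
title: "Group-adaptive BH procedures for paired qPCR miRNA panels: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-adaptive BH procedures for paired qPCR miRNA panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupBH)
```

## The problem

Targeted qPCR miRNA panels on small paired cohorts (here, 18 tumor–normal
pairs assayed for 522 miRNAs) test hundreds of hypotheses with very little
per-hypothesis power. The standard Benjamini–Hochberg (BH) step-up controls
the false discovery rate but applies one common p-value threshold to all
miRNAs, and in the *p ≫ n* regime that threshold becomes stringent enough
to hide real signals. miRNAs, however, are not exchangeable: physically
proximal miRNAs tend to be co-regulated, so a partition of the panel by
genomic position carries information about where the non-null hypotheses
concentrate. Group-adaptive BH procedures exploit exactly this: they
estimate the proportion of true nulls within each group and spend the FDR
budget preferentially inside groups that look enriched for signal.

This package implements the complete workflow around that idea: the paired
ΔΔCt tests that produce the p-values, the position-based grouping schemes,
the grouped FDR procedures, a randomization control for the claim that the
grouping itself (and not mere adaptivity) drives extra detections,
correlation diagnostics, and a synthetic data generator that reproduces
the statistical structure of such a panel so that every stage is testable
without the original cohort.

## The testing model

Expression is measured as ΔCt (cycle-threshold difference against
endogenous controls); the change score is ΔΔCt = ΔCt(tumor) −
ΔCt(normal). On this scale +1 Ct is a halving of expression in tumor, so
*positive* ΔΔCt means *down*-regulation. Each miRNA gets a one-sided
paired t-test whose direction is fixed by the sign of its median ΔΔCt
across patients (a zero median falls back to the mean's sign; a zero mean
marks the miRNA untestable and its p is set to 1). With complete-case
mean $\bar d$, standard deviation $s$ and $m$ complete pairs, the
downregulation test has

$$t = \frac{\bar d - \delta}{s/\sqrt m}, \qquad p = P(T_{m-1} > t),$$

and the upregulation test mirrors it in the lower tail with offset
$-\delta$. The offset $\delta$ (in Ct units) encodes the null boundary
"not more than $2^\delta$-fold changed"; the default $\delta = 1$ states
the 2-fold null. $\delta$ is configurable — with $\delta = 0$ the test
becomes a plain directional paired t-test — but note a calibration
subtlety we verified by simulation: because the direction is chosen from
the data, at $\delta = 0$ the null rate of small p-values is *twice* the
nominal rate ($P(p<u) \approx 2u$), while at the composite-null boundary
$\mu = \pm\delta$ (the regime the procedure is designed for) the test is
exactly calibrated. The δ = 1 default is therefore not cosmetic.

**Missingness.** qPCR reactions that fail to amplify within 40 cycles are
recorded missing; if either tissue of a pair is missing the whole pair is
excluded (pairwise missingness — enforced by every reader, with repair of
one-sided pairs). The default analysis is complete-case. Median
imputation is available strictly as a sensitivity variant: imputing a
column's median shrinks its sample variance, deflates p-values, and
relaxes every step-up threshold downstream, which the analysis scripts
demonstrate. We treat that leniency as an artifact, not a gain.

## Grouping schemes

Schemes are hierarchical partitions by genomic position only — never by
expression, which would re-use the data and inflate type-I error:

* **(a)** chromosome; **(b)** chromosome × strand; **(c)** chromosome ×
  strand × arm;
* refinements of (c): any group with more than *k* members is chunked
  into adjacent blocks of size *k* (by start coordinate), for
  k = 25, 23, …, 5, with the final smaller block allowed and a final
  *singleton* block absorbed into the preceding one (so one block may
  have k+1 members).

Groups that would be empty never materialize, and single-miRNA groups are
merged into their nearest neighboring group, so every scheme built from
at least two miRNAs has minimum group size 2. "Nearest" is not defined by
the grouping keys alone, so we fixed a deterministic rule: candidates are
ranked lexicographically by (tier, distance, group id), with tier 0 for
same chromosome and strand, 1 for same chromosome, and 1 plus the
chromosome-index distance (order 1..22, X, Y) otherwise; distance is the
minimum absolute start-coordinate difference to any candidate member.
Coordinates are 1-based point locations (start only), which matches the
granularity of miRNA annotations; chunking ignores strand polarity and
proceeds from the lowest coordinate.

## The FDR procedures

All procedures operate on the vector of raw p-values; rejection happens
at the level of individual hypotheses.

* **BH**: reject the $k^*$ smallest p-values,
  $k^* = \max\{k: p_{(k)} \le k\alpha/n\}$; ties at the boundary are all
  rejected (and by maximality of $k^*$ this keeps $|R| = k^*$).
* **π₀ estimators** (per group of size $n_g$):
  * *TST* (two-stage step-up): run BH within the group at
    $\alpha' = \alpha/(1+\alpha)$; with $r$ rejections,
    $\hat\pi_g = (n_g - r)/n_g$.
  * *LSL* (least slope): with slopes
    $l_i = (n_g+1-i)/(1-p_{(i)})$ ($+\infty$ at $p_{(i)}=1$; a comparison
    of two infinite slopes is not an increase), stop at the first
    $i \ge 2$ with $l_i > l_{i-1}$ and set
    $\hat n_0 = \min(\lfloor l_i \rfloor + 1, n_g)$, else $n_g$.
  * *τ-censored Storey*:
    $\hat q_g = \min(1, \max(\epsilon, \#\{p>\tau\}/(n_g(1-\tau))))$,
    with the study's tuning τ = 0.5 and ε = 0.1. The detections are
    insensitive to small perturbations of either.
* **TST-GBH / LSL-GBH**: weight $p^w_i = p_i\,\hat\pi_{g(i)}/(1-\hat\pi_{g(i)})$
  ($+\infty$ at $\hat\pi_g = 1$: a group estimated fully null is never
  rejected from; 0 at $\hat\pi_g = 0$: such hypotheses are rejected
  whenever anything is — the aggressive limit of the weighting, stated
  loudly), pool, and run BH at the effective level
  $\alpha_{base}/(1-\hat\pi_0)$ with
  $\hat\pi_0 = \sum_g n_g \hat\pi_g / n$; if $\hat\pi_0 = 1$ nothing is
  rejected. $\alpha_{base}$ is $\alpha'$ for TST and $\alpha$ for LSL —
  this placement is algebraically forced by the requirement that a single
  group reduces the procedures exactly to the classical two-stage
  adaptive BH and LSL adaptive BH, which our tests verify against
  independently coded oracles.
* **Group SABHA**: reject $\{i: \hat q_{g(i)} p_i \le \hat k \alpha/n\}$
  with $\hat k = \max\{k: \#\{i: \hat q_{g(i)} p_i \le k\alpha/n\} \ge k\}$.
  No additional $p \le \tau$ cap is applied by default (at α = 0.05 and
  τ = 0.5 it is never binding; a `tau_cap` flag adds it).

Ties in weighted p-values are resolved by a stable sort on (value, id);
p-values exactly 0 or 1 are legal everywhere.

One edge deserves its own paragraph. When the LSL estimate within the
*only* group is 1, the grouped algorithm rejects nothing (infinite
weights), whereas the textbook LSL adaptive BH with $\hat n_0 = n$
degenerates to plain BH, which can still reject. The two conventions
genuinely differ on this edge; we follow the grouped-weighting convention
throughout (it is also the conservative one) and our equivalence tests
encode it explicitly. TST and Storey have no analogous edge: a first-stage
count of zero stops the two-stage procedure anyway, and $\hat q = 1$ gives
weight 1, not ∞.

## The control study

Informative groups should matter. To test that, the control study keeps
the p-values fixed (the tumor–normal pairing is never recomputed) and
reassigns miRNAs to the scheme (c) groups uniformly at random —
preserving the multiset of group sizes — 1000 times, rerunning each
grouped procedure per replicate. Detection frequencies per miRNA and
per-replicate detection counts (mean, median, and the (25th, 75th)
percentile IQR, R's default type-7/inclusive convention) are summarized,
along with overlaps against the BH set and against the grouped-only
detections. Replicate *r* draws from an RNG substream keyed by
(seed, r), so results are independent of evaluation order. BH itself is
excluded — it does not see the groups. Under non-informative random
groups the grouped procedures concentrate toward their single-group
counterparts, so detections that disappear under randomization are the
ones attributable to the positional grouping. Whether assignments are
drawn with or without replacement across replicates is immaterial at
these sizes; we draw independently per replicate.

## Correlation diagnostics

The premise that position-based groups capture co-regulation is checked
under an exchangeable random-effects model for the change score of miRNA
*i* in patient *j*:

$$z_{j,i} = \mu_i + a_j + b_{j,g(i)} + e_{j,i},$$

with independent components of variances $\sigma_a^2$ (patient),
$\sigma_b^2$ (patient × group) and $\sigma_e^2$ (residual), giving
constant correlations $\rho_{intra} = (\sigma_a^2+\sigma_b^2)/V$ and
$\rho_{inter} = \sigma_a^2/V$, $V = \sigma_a^2+\sigma_b^2+\sigma_e^2$.
We estimate these by averaging pairwise Pearson correlations over
within-group and between-group miRNA pairs (pairwise-complete
observations; pairs sharing fewer than 3 patients, or with constant
profiles, are skipped). This moment estimator is consistent under the
stated model, assumption-light, and invariant to per-miRNA mean shifts;
a REML variance-components fit would be a natural extension point but is
deliberately not the default, since the averaged-correlation estimator
makes no normality or balance assumptions. Note the precision limit: with
18 patients the estimates are dominated by the realized patient effects,
so adding miRNAs does not shrink the Monte-Carlo error — tolerances of
±0.03 on the recovery tests reflect that, and single datasets can miss by
more.

## The synthetic generator

The generator emulates the statistical structure the analysis relies on,
with all defaults fixed once to the study conditions:

* 18 patients × 522 miRNAs on 22 autosomes; Zipf-like chromosome weights
  and uneven strand/arm probabilities (0.6 "+", 0.65 "q") so the
  chromosome/strand/arm partition mixes small and large groups and at
  least one group exceeds 25 members (every k-refinement is exercised);
* normal-tissue ΔCt = per-miRNA baseline + exchangeable components;
  tumor ΔCt adds the true effect $\mu_i$ plus fresh components, so the
  change score carries the exchangeable correlation structure with
  targets (ρ_intra, ρ_inter) = (0.15, 0.04) from the variance split
  0.04 V / 0.11 V / 0.85 V and V = 25 (within-miRNA ΔΔCt sd of 5 Ct —
  the scale implied by the strongest observed effects, e.g. a mean ΔΔCt
  of 6.7 Ct at p ≈ 5×10⁻⁵ with 18 pairs);
* signals concentrated in 10% of groups, half the members of a signal
  group non-null, |μ| uniform on [1.5, 7] Ct with random signs — the
  group-wise null-proportion heterogeneity that grouped methods exploit;
* missingness is mechanistic, not painted on: raw Ct is ΔCt plus a
  housekeeping level of 20 cycles, the per-miRNA baseline is N(28, 3) on
  the raw scale, and any raw Ct beyond the 40-cycle detection limit makes
  the whole pair missing. Low-abundance (high-Ct) miRNAs are therefore
  lost more often — missing not at random, in the detection-limit sense —
  and miRNAs with more than 50% missing pairs are dropped, mirroring the
  source preprocessing. These constants land the profile on the study's
  quoted summaries (~55–62% of miRNAs with at least one missing pair
  across seeds; none beyond half).

What the generator does *not* emulate: heterogeneous per-miRNA variances
(real panels mix tight and noisy assays; our V is constant, which is why
moderate |μ| values are harder to detect here than in the real table),
batch effects, amplification-curve artifacts, and any sequence-level
structure. Passing tests on this generator therefore validate the
*procedures* and their interplay, not biological claims about any real
cohort.

## Numerical and design choices

* Problem sizes: the calibration study runs 1000 replicates × 500
  hypotheses (25 groups of 20; 5 signal groups with 10 non-nulls each,
  alternative p ~ Beta(0.1, 1)); the control study runs 1000
  reassignments of the full panel; correlation recovery uses 18 × 500
  with a fixed seed. These sizes give Monte-Carlo standard errors around
  0.13 percentage points on the FDR estimates and complete in seconds to
  a couple of minutes.
* Observed calibration: BH sits at ≈4.6% empirical FDR. The adaptive
  grouped procedures pay for their extra power (≈0.68 vs 0.56 true-positive
  fraction) with a small finite-sample excess over 5% (TST-GBH ≈6.4%,
  SABHA ≈5.9%, LSL-GBH ≈5.2% under these conditions): with size-20
  groups, the per-group estimates are noisy enough that a group is
  occasionally down-weighted by the very p-value it then rejects. This
  liberality — strongest for TST-GBH — is a real property of the methods,
  consistent with their reputation, and is precisely why the control
  study and the scheme-stability inspection belong to the workflow.
* Scheme choice is reported, never auto-selected: the sweep emits counts
  and enter/exit transitions per scheme and the analyst picks (e.g., by
  the elbow where detection counts start reacting sharply to *k*), since
  any automatic elbow rule would hard-code a visual judgment.
* Determinism: grouping contains no randomness; every stochastic stage
  (generator, control study, calibration) is seeded, with per-replicate
  substreams below 2³¹.

## Known limitations

The constant-correlation model is a diagnostic summary, not a claimed
generative truth; per-group correlation heterogeneity is out of scope.
The t-tests assume approximate normality of ΔΔCt within miRNA; no
nonparametric or moderated variants are provided. Complete-case analysis
with MNAR missingness can still bias individual effect estimates — the
package controls what the FDR machinery sees, not the missingness
mechanism itself. And on a single small cohort, grouped procedures can
only reweight the evidence that is present; they cannot recover signals
the data do not contain.
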