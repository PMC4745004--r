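---
title: "Abundance-weighted miRNA target repression profiling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-weighted miRNA target repression profiling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirepress)
```

## The problem

A single miRNA typically represses many mRNAs, and a single mRNA is
typically repressed by many miRNAs, each with a different predicted
strength. Screens that first call differentially expressed miRNAs and only
then look up their targets discard this many-to-many structure. `mirepress`
instead works on the *comprehensive repression* an mRNA receives from the
whole miRNA pool: each miRNA's abundance is spread across its predicted
targets in proportion to interaction strength, and the per-mRNA totals are
compared between tumour samples and a control.

## Model

**Normalization.** Raw counts are placed on the transcripts-per-million
scale,

$$\mathrm{TPM}(a) = \frac{c_a}{\sum_{a' \in A} c_{a'}} \times 10^6,$$

where $A$ is the set of miRNAs assayed in the sample and $c_a$ the
transcript count of miRNA $a$. TPM is invariant to library size, which is
the only property the downstream model uses. The control group's profiles
are averaged *after* normalization — on the TPM scale each control sample
then carries equal weight regardless of its sequencing depth, which is the
behaviour one wants from an "averaged control". (Averaging raw counts
instead would weight controls by depth; that alternative is deliberately
not offered.)

**Repression apportionment.** Given a table of predicted interactions with
non-negative repression scores $RS_{a\alpha}$ (e.g. derived from miRanda
output), each miRNA's abundance is apportioned across its targets,

$$w_{a\alpha} = \frac{RS_{a\alpha}}{\sum_{t \in T(a)} RS_{at}}, \qquad
R(\alpha) = \sum_{a:\,\alpha \in T(a)} \mathrm{TPM}(a)\, w_{a\alpha},$$

where $T(a)$ is the target set of miRNA $a$. The weights of every retained
miRNA sum to one, so repression mass is *conserved*:
$\sum_\alpha R(\alpha)$ equals the summed TPM of all target-bearing
miRNAs. This conservation is the model's central invariant and is verified
by property tests on random instances. A miRNA whose scores sum to zero
predicts no repression and is dropped (with a warning) rather than spread
uniformly — a zero score is read as "no predicted interaction strength",
not as ignorance.

**Differential testing.** For each mRNA (or each individual miRNA–mRNA
interaction), the mass $x$ it holds out of its group's total mass $n$ is
compared between control (1) and test (2) with the pooled two-proportion
Z-test:

$$p_0 = \frac{x_1 + x_2}{n_1 + n_2}, \qquad
Z = \frac{\hat p_1 - \hat p_2}
         {\sqrt{p_0 (1 - p_0)\left(\frac{1}{n_1}+\frac{1}{n_2}\right)}},$$

with a two-sided standard-normal p-value. Masses are real-valued TPM
quantities, not integers; the test is applied to them as-is because the
model is stated on repression masses. When $p_0 \in \{0, 1\}$ the statistic
is undefined and the feature is reported with $p = 1$, never significant —
degeneracy must not fabricate discoveries. Sidedness was an open choice;
the two-sided form is used so that the statistic itself stays directionless
and direction is handled explicitly at the screening stage (below).

**Enrichment and recurrence.** Each tumour sample is compared
independently against the single averaged control; a pooled across-tumour
test is deliberately not offered, because recurrence *across* per-sample
analyses is itself the screening device. Per sample, the significantly
more-repressed genes are tested for pathway over-representation with the
one-sided hypergeometric upper tail $P(X \ge k)$ — the standard
formalization of enrichment, testable in-package, unlike a web service.
Pathways enriched in *every* sample form the overlapped set; the
interaction-level differential tables are then restricted to genes of those
pathways, and the miRNAs (and mRNAs) significant there in every sample are
the recurrent candidates.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | 0.05 | per-feature significance for the Z-test screen; raw p-values by default, mirroring an uncorrected screen; `adjust = TRUE` switches the decision to BH q-values (q-values are always reported) |
| `enrich_alpha` | 0.05 | hypergeometric enrichment threshold, uncorrected by default for the same reason |
| `direction` | `"repressed"` | which significant features count as screen hits; see below |
| enrichment universe | annotated target genes | all genes of the interaction table annotated to at least one pathway; a practitioner can pass any background to `hypergeom_enrich()` directly |
| `distance`, `linkage` | euclidean, average | panel clustering on `log2(TPM+1)`; no metric is canonical for miRNA panels, and both are selectable (`correlation`, `complete`, `single`) |

**Why the screen is directional.** Repression shares sum to one within a
sample. If a subset of genes genuinely gains share in the tumour, every
other gene must lose share by exactly the compensating amount, and with
group totals on the order of $10^6$ TPM the Z-test resolves that loss
easily: a two-sided screen therefore marks essentially the whole
transcriptome significant whenever anything changes, and enrichment loses
all contrast. The scientific question is "which mRNAs does the tumour
miRNA pool repress *more*", so the default hit set is
significant-and-share-increased (`direction = "repressed"`);
`direction = "both"` restores the sign-blind behaviour for users who want
it. The two-sided `significant` flag in the tables is unaffected — the
choice only governs which rows the enrichment/recurrence screens consume.

## What the synthetic generator emulates

`simulate_dataset()` stands in for the study design the package targets:
a handful of tumour profiles compared against an averaged control, a
scored bipartite miRNA→mRNA network, and pathway annotations with a
planted subset of pathways differentially repressed in all tumours.

* **Counts** are negative binomial (default dispersion 0.1, variance
  $\mu + 0.1\mu^2$), the standard overdispersion model for small-RNA
  sequencing; per-miRNA baseline means are log-uniform over one decade
  either side of `baseline_mean` (default 100), giving the decades-wide
  abundance spread real miRNA profiles show.
* **Network**: each of 300 miRNAs targets 5–15 of 1000 genes uniformly at
  random, with scores uniform on [50, 200] (the scale of miRanda alignment
  scores). 20 disjoint pathways partition the genes; disjointness makes
  planted-recovery scoring unambiguous (real KEGG pathways overlap — see
  limitations).
* **Planting**: for each of 4 planted pathways, 5 dedicated miRNAs
  (~20 planted miRNAs in all, echoing the ~21-miRNA panels such studies
  report) are rewired so that at least 80% of their targets lie inside the
  pathway, and their mean counts are multiplied by `fold_change`
  (default 4) in tumour samples only.
* **Reproducibility**: three RNG streams (network, planting, expression)
  are derived from the master seed, so the same configuration always
  regenerates the identical dataset bit for bit, and changing, say, the
  expression noise leaves the network untouched.

What it does *not* emulate: microarray probe effects, batch effects,
overlapping pathways (available behind no flag — disjoint by
construction), miRNA families with shared seed sequences, or correlated
target structure. Passing the planted-recovery tests therefore shows the
pipeline recovers coherent abundance-driven signal under sequencing-like
noise; it does not certify performance on real tumour cohorts.

## Numerical and degenerate-input choices

* TPM sums are renormalized after control averaging to absorb float drift;
  the `NormalizedProfile` constructor enforces the $10^6$ sum to a
  relative $10^{-9}$.
* Weight sums per miRNA are exact to $10^{-12}$; repression accumulation
  is plain summation (masses are all non-negative, so no cancellation
  arises).
* All-zero profiles cannot be normalized (error), all-zero-score miRNAs
  are dropped with a warning, empty interaction tables yield all-zero
  repression, and empty differential inputs yield empty tables rather
  than errors.
* Agglomeration is delegated to `stats::hclust`, whose merge order is
  deterministic for tied distances; partitions at each cut come from
  `stats::cutree`. Identical inputs give identical trees on every
  platform this package supports.
* Percentages in the literature tabulation are rounded half-up to one
  decimal (plain `round()` rounds half to even, which would misreport
  e.g. a x.x5 boundary case).

## Calibration of the Z-test

The Z-test's sampling model treats a group's repression vector as a mass
multinomially allocated over genes. Under that model the test is
calibrated, and the acceptance suite verifies it: gene shares are taken
from a `fold_change = 1` dataset's control repression distribution, two
groups are drawn multinomially from those same shares at TPM totals, and
the empirical rejection rate at $\alpha = 0.05$ over 2000 gene-level tests
must fall within the binomial 99% interval around 0.05.

This is also the test's known limitation: real replicate-to-replicate
variation in sequencing data is overdispersed relative to the multinomial,
so with TPM-scale totals the per-gene test is anticonservative against
biological noise — which is precisely why the pipeline relies on
directional screening, per-sample recurrence, and pathway-level
intersection rather than on any single p-value. Users wanting
replicate-aware inference should treat the per-gene p-values as scores,
not probabilities.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to exercise every code path
while keeping the suite fast: 200 random instances for conservation, 1000
draws for the Z-test oracle, the full $N \le 60$ grid for the
hypergeometric oracle, 2000 gene-level null tests for calibration, ten
generator seeds for planted recovery, and the default 300-miRNA/1000-gene
configuration for the end-to-end runs. Power measured at these sizes
(planted-pathway and planted-miRNA recall are recomputed, not asserted as
constants) reflects the generator's own difficulty: planted miRNAs that
draw a low baseline abundance contribute repression below the noise floor,
so recall a little short of 100% is the honest operating characteristic of
the method under these conditions, not a defect.

## Known limitations

* Identifier matching is exact and case-sensitive; no alias resolution is
  attempted, and mapping miRanda output (positive alignment scores or
  negative binding energies) to non-negative repression scores is the
  caller's responsibility.
* The score-proportional apportionment assumes repression scales linearly
  with miRNA abundance and that scores are comparable across targets of
  one miRNA; saturation, cooperative binding and target-site competition
  are outside the model.
* The enrichment background defaults to annotated target genes; with
  sparse annotation this background is small and p-values optimistic.
* Purity at `k = 2` is a coarse summary of a dendrogram; it is the right
  readout for a two-group biomarker panel and nothing more.
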