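---
title: "Methods: inheritance patterns and mid-parent heterosis in trio omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inheritance patterns and mid-parent heterosis in trio omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

Hybrid vigor (heterosis) is studied at the molecular level by profiling a
female parent (F), a male parent (M) and their F1 hybrid (H) side by side
— here the maize reciprocal-cross design with inbreds B73 and Mo17 and
hybrids BM (B73 x Mo17) and MB (Mo17 x B73), grown under four light
conditions (darkness, far-red, red, blue), with three RNA-seq replicates
and six metabolome replicates per genotype and condition. Two questions
drive every stage of this package:

1. **How does each feature behave in the hybrid relative to its
   parents?** Additively (at the parental average), like one parent
   (expression-level dominance, ELD), or outside the parental range
   (overdominance)?
2. **How large is mid-parent heterosis (MPH)** for metabolites and for
   biomass, where `MPH = 100% x (F1 - A) / A` with `A` the mid-parent
   (parental average)?

## Differential testing

Counts are filtered (a gene is kept when its CPM reaches 10, inclusive,
in at least `min_samples` samples — by default the smallest replicate
group, a documented choice since the filter rule does not itself fix the
sample requirement) and normalized by median-of-ratios size factors: the
median over all-nonzero genes of the ratio of a sample's count to the
gene's geometric mean, rescaled to geometric mean one. The median is
taken on the ratio scale; the log-scale median used by some tools differs
only in even-count interpolation (they agree to about 1% and are
cross-checked in the tests).

`nb_test()` is a self-contained negative-binomial Wald test: per-gene
dispersion by method of moments on normalized counts within each group
(pooled across the two groups, floored at 1e-8), the log2 fold change of
group means, a delta-method standard error, and a **t reference with
nA + nB - 2 degrees of freedom**. The t reference is a deliberate
calibration choice: with three replicates per group the dispersion
estimate is noisy, and a normal reference rejects far too often (about
12% at nominal 5% in the null simulation the test suite runs), whereas
the residual-df t reference holds the size at 4-5%. Calls use the study
thresholds: fold change at or above 1.5 (or at or below 1/1.5) and
BH-FDR below 0.3 for genes; BH correction is `stats::p.adjust`.

Zero handling: when a group mean is zero, 0.5 is added to both group
means before the ratio (symmetric, so swapping groups exactly negates
the log2 fold change); genes with all-zero counts in both groups report
log2FC 0 and p 1.

Metabolites instead combine a PLS-DA VIP score (NIPALS on autoscaled
columns, class indicator centered; VIP normalized so its mean square is
exactly one) with per-feature Welch t-tests on log2(x+1), BH-corrected;
a metabolite is called at VIP strictly above 1 and FDR below 0.05. The
t-tests are unpaired by default — biological replicates of different
genotypes carry no natural pairing — with an opt-in replicate-index
pairing. The orthogonal signal correction some tools prepend is omitted:
the VIP threshold, not the orthogonal rotation, drives the calls.

## Mid-parent construction and the twelve types

The expected additive hybrid (mid-parent value, MPV) is built as
pseudo-replicates: pseudo-replicate i is the mean of female replicate i
and male replicate i, paired in replicate order and truncated to the
smaller parental count. This yields a replicate-level MPV sample so the
same test machinery applies; the hybrid is compared to it with Welch
t-tests on log2(x+1) rather than a count model, because averaging two
count samples no longer follows a count distribution. In the pipeline
this stage runs on size-factor-normalized counts, not CPM: strong
overdominant genes change the hybrid's library composition, and CPM
would convert that compositional shift into a spurious downward bias of
every other gene.

`classify_inheritance()` maps each feature to one of twelve F-H-M types
from three pairwise calls (H vs F, H vs M, F vs M, all at the same
FC/FDR thresholds) plus the group means:

* **additive (I, II)** — H differs from both parents, the parents
  differ, and H lies strictly between them; I when the female parent is
  higher.
* **ELD-M (III, IV)** — H statistically indistinguishable from the male
  parent and different from the female ("similar to a parent" is the
  absence of a call, not an equivalence test). **ELD-F (V, VI)** is the
  mirror image.
* **overdominant low (VII, VIII, IX)** — H below both parents; VII when
  the male parent is significantly higher than the female, IX the
  reverse, VIII when the parents do not differ. **Overdominant high (X,
  XI, XII)** splits the same way.
* anything else is unclassified. Additivity deliberately requires
  *both* hybrid-parent contrasts significant, the stricter of the two
  possible readings.

Within the ELD pairs the first label (III, V) is assigned when the
*resembled* parent is the higher-expressed one. This is the only
convention under which the labels are covariant with a parent swap
(III maps to V, IV to VI), so that a gene pinned to B73 reads as type V
in the cross where B73 is the female parent and as type III in the
reciprocal cross — which is how reciprocal trios are reported in this
field. Keying the split to the female parent instead would break that
symmetry (III would map to VI). The equivalence is enforced by an
exhaustive enumeration test against an independently coded decision
table, and by a 10,000-feature parent-swap test.

Categories roll up deterministically: I-II additive, III-IV ELD-M, V-VI
ELD-F, VII-XII overdominant; "non-additive" is everything except
additive and unclassified. Up/down asymmetry of hybrid-vs-MPV calls is
tested with a chi-square goodness of fit against 50:50 (df 1).

## Heterosis statistics

MPH is computed on group means (the published formula's "average
values"), never per replicate; it is scale-invariant and antisymmetric
around the mid-parent, both asserted to 1e-12. Class-level metabolite
summaries test each class's MPH against zero with a one-sample t-test;
a zero-variance class reports p = 1 with a flag — constant data should
never generate a significance claim.

## Co-expression networks

The network stage is written from scratch: unsigned soft-threshold
adjacency `|cor|^beta` (signed available; unsigned is the default since
the source protocol does not state a type), topological overlap

    TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)

average-linkage clustering of 1 - TOM, a static branch cut at 0.99 of
the tallest merge, branches below `min_module_size` (default 30) set to
grey, then iterative merging of the closest module pair while eigengene
dissimilarity (1 - cor) is below `merge_cut_height` (0.25, the study's
setting). The full dynamic hybrid tree cut with its PAM stage is
deliberately simplified to this deterministic static cut plus eigengene
merging: the protocol pins only `mergeCutHeight`, and the simplification
is oracle-testable. Eigengenes are leading singular vectors of the
standardized member matrix, unit norm, sign-oriented to correlate
positively with their members on average; merge ties resolve to the
pair found first in row order, and the merged module keeps the larger
member's label.

The soft power is user-supplied (18 for genes, 17 for metabolites per
the study); a scale-free-fit helper reports signed R^2 per candidate
power but is never applied automatically. Module-trait association is
the Pearson correlation of each eigengene with a binary trait (parents
coded 0, hybrids 1), significant at |r| > 0.6 and p < 0.05.

## Enrichment

Hypergeometric upper tail per term with at least one hit, BH across
tested terms. Filtering follows the study's reporting and is on the raw
p (GO at 0.05, KEGG at 0.01, strict inequality), with BH values kept in
the table. The default background is the set of features surviving the
expression filter, not the whole annotation — the standard guard against
detection bias — and is configurable.

## The synthetic generator

`simulate_trio_counts()` emulates the study design: four genotypes by
four light conditions, three count replicates (six for metabolites),
negative-binomial counts at dispersion 0.05 around mode-determined
means, log2 parental effect 2, per-gene base means log-uniform on
2^[5, 10], library size 1e6, and a shared per-condition log2 multiplier
(sd 0.3) that preserves each gene's mode across conditions. Modes are
allocated in exact proportions (largest remainder, shuffled): additive
puts the hybrid at the parental mean; ELD at one parent; overdominant
high/low at 2^2 above the higher / below the lower parent. Reciprocal
hybrids share the hybrid mean — parent-of-origin effects are off by
default so classifier tests are not confounded with reciprocal
asymmetry. Metabolites use mean-preserving log-normal noise at CV 0.2,
so CV 0 reproduces group means exactly. Planted co-expression modules
are drawn from null-mode genes only, keeping module structure orthogonal
to inheritance modes; members share a per-sample latent factor at the
requested correlation and can be depressed in hybrid samples to plant a
module-trait signal.

What the generator does **not** emulate: batch effects, GC/length bias,
count outliers, correlated genes outside planted modules, missing
metabolite values, or parent-of-origin expression. Passing tests
therefore demonstrate the statistical machinery on a clean instance of
the design, not robustness to every artifact of real data.

The biomass generator draws replicate weights with multiplicative noise
around fixed parental means (0.8 g and 1.0 g fresh; dry at one tenth)
and sets the hybrid mean to the mid-parent scaled by the target MPH. At
the study's conditions (CV 5%, six replicates) a single
cross-condition-trait MPH estimate has a standard deviation near 4
points by straightforward error propagation, so recovery is assessed on
the cross-level estimate averaged over the four light conditions (sd
near 2 points), which lands within +/-5 points in at least 95% of
seeded runs.

## Problem sizes and reproducibility

The acceptance checks run at the sizes a laptop handles in seconds:
6,000 genes (1,000 per mode) for the headline classification run,
10,000 genes for null calibration, 200 seeded biomass studies, 80
features for planted-module recovery. Every simulation is seeded;
`run_pipeline()` writes a manifest of parameters and output md5 hashes
with no timestamps, so identical configs reproduce byte-identical
manifests.

## Known limitations

* The NB test has no dispersion shrinkage or covariates; with three
  replicates its power at small fold changes is modest, which is why
  additive genes are the hardest mode to recover (about 70% at effect 2;
  misclassifications land mostly in the ELD categories when one
  hybrid-parent contrast narrowly misses significance).
* Statistical calls treat "similar to a parent" as absence of evidence
  of difference, as the field's operational definition does; it is not
  an equivalence test.
* The module stage targets a few thousand features; it builds dense
  adjacency matrices and is not intended for whole-genome blockwise
  decomposition.
* Correlation-based QC reports both r and r^2 explicitly because
  published summaries are ambiguous between the two.
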