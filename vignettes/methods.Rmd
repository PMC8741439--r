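---
title: "Methods: estrogen-response analysis for window-of-opportunity studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estrogen-response analysis for window-of-opportunity studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2response)
```

## The setting

In a window-of-opportunity design, post-menopausal women with newly diagnosed
low-grade ER+/HER2- breast cancer receive a short course of estradiol between
the diagnostic core biopsy (Bx) and surgical resection (Sx), giving a paired
before/after comparison of the same tumour. `e2response` implements the
analysis chain such a study needs:

1. paired biomarker statistics (Ki67, the immunohistochemical proliferation
   fraction, and ROR, a 0-100 gene-expression risk-of-recurrence score) and a
   rule for flagging prototypical *responders* and *non-responders*;
2. derivation of responder-vs-non-responder gene-expression signatures by
   random-forest (bagged decision tree) importance pruning;
3. scoring of external cohorts against a derived signature, with
   Kaplan-Meier / log-rank validation against distant-relapse-free survival;
4. gene-set, promoter-motif and peak-proximity enrichment of a signature
   (e.g. against the DREAM-repressed late-cell-cycle program, whose promoters
   carry the CHR element `TTTGAA`);
5. a negative-binomial simulator that stands in for the study's raw
   sequencing data in every test.

## Paired biomarker statistics

For a biomarker with baseline $b_i$ and post-treatment value $p_i$ we work
with the natural-log ratio $d_i = \ln(p_i/b_i)$. The headline effect is the
percentage change of the geometric mean,
$100\,(e^{\bar d} - 1)$,
and its test is the paired t-test on the $d_i$ (statistic
$\bar d / (s_d/\sqrt n)$, $n-1$ degrees of freedom, two-tailed). Sample
(n−1) standard deviations are used throughout; with the packaged 19-patient
table this convention reproduces the table's responder trio exactly, which
is why it was frozen.

A *responder* is a patient whose ROR change falls more than one standard
deviation below the cohort's mean change (strict inequality); *non-responders*
are the $k = 3$ patients with the smallest absolute ROR change, ties broken
by patient id. Direction concordance between Ki67 and ROR changes is Cohen's
kappa on the 2x2 table of increase vs non-increase, after excluding patients
with exactly zero ROR change. The zero-handling convention is asymmetric by
design: a zero Ki67 change is a non-increase, a zero ROR change drops the
pair. It is the only simple convention that reproduces both of the table's reported
summary numbers (10/11 concordant, kappa = 0.7442) from the packaged table,
and it is flagged as a convention, not a fact about the method.

Values below the estradiol detection limit (30 pg/mL) are stored as the
limit with a flag and never enter any computation. One patient row in the
packaged table is typographically ambiguous in the source document; the
packaged reading (Ki67 2.4 -> 1.0) is the one that reproduces the reported
geometric-mean change and p-value, and the reader preserves it bit-exactly
on write/read round trips.

## Signature derivation

Derivation runs on one timepoint at a time (core-only for a predictive
pre-treatment signature, surgical-only for a post-treatment signature),
because the two sample types answer different questions.

**Normalization.** Raw counts are normalized by median-of-ratios: each
sample's size factor is the median over genes (restricted to genes with a
positive geometric mean across samples) of the count divided by the gene's
geometric mean. This also absorbs any global per-patient scale effect.

**Fold prefilter.** Genes whose pseudocounted group-mean ratio
$(\bar x_R + c)/(\bar x_N + c)$, $c = 0.5$, is at least 2-fold in either
direction are retained. The pseudocount guards against division by zero on
count data; at typical depths it is negligible.

**Iterative importance pruning.** A bagged ensemble of unpruned CART trees
(default 500) classifies responders vs non-responders using every candidate
gene at every split (no feature subsampling - bagging, not the
random-subspace forest). Per-gene importance is the out-of-bag permutation
importance (mean decrease in OOB accuracy when the gene's values are
permuted among a tree's OOB samples), which can be negative; genes with zero
or negative importance are removed and the ensemble refit, until every
remaining gene has positive importance, the set stops changing, at most
`min_genes` (5) remain, or `max_iterations` (100) is reached. A fit with all
importances positive and OOB error at or below `oob_target` (0.10) is marked
converged. The 0.10 constant quantifies "low out-of-bag error"; nothing in
the pipeline branches on it.

Determinism is taken seriously: bootstrap draws, split tie-breaks and
permutations come from an internal splitmix64 stream with one substream per
tree, so a fit is bit-identical for a given (data, seed) on any platform.
Exact split-gain ties — common in tiny cohorts where many genes separate the
in-bag classes perfectly — are broken uniformly at random from the tree's
stream; a deterministic "first gene wins" rule would collapse the ensemble
onto low-index genes and destroy the importance estimates.

**Cluster refinement.** Protocols of this kind refine signatures by visual
inspection of a clustered heat map. The automated surrogate clusters the
candidate genes by average-linkage hierarchical clustering on
1 − Pearson correlation (computed on log2 values; tree cut at height 0.5,
i.e. within-cluster correlation ≥ 0.5), discards clusters whose mean
absolute standardized between-group difference falls below
`cluster_sep_threshold` (1.0 pooled-sd units on the log2 scale), and passes
the survivors through the pruning loop once more with an independent seed
substream. If no cluster passes, the best one is kept rather than returning
an empty signature. This surrogate is the loosest link to the original
protocol: a human looking at a heat map applies judgement no threshold rule
captures, and any automated stand-in changes results in ways that cannot be
calibrated against the original.

**PC1 reporting.** The share of variance on the first principal component of
the gene-centered signature submatrix (samples as observations) is reported
on the log2 scale. On raw normalized counts a single high-variance gene can
dominate the decomposition, which is why the log scale is the package's
convention.

## Response scoring and survival validation

To score an external cohort, its matrix is restricted to symbols shared with
the training data (uppercased symbol matching; unannotated probes simply
drop out, mirroring how a 30-gene signature can shrink to 12 measurable
genes on an older array platform) and quantile-normalized onto the training
reference: each target column is rank-mapped onto the mean of the sorted
training columns, ties receiving the mean of the profile values their
positions span.

The scoring model is the same bagged ensemble, trained with the prototypical
responders as the positive class against all other training samples. A
sample's **response score** is the fraction of each reached leaf's training
observations that are responders, averaged over trees — a value in [0, 1]
rather than a hard vote, which is what lets a 3-vs-10 training set produce a
graded score. Score splits (default: fixed 0.5 cut; optionally the cohort
median — how the original analysis dichotomized is unknown) feed a standard
Kaplan-Meier / two-group log-rank validation, with events preceding
censorings at tied times and two-sided p from the chi-square distribution
with 1 df.

## Enrichment statistics

Gene-set overlap uses the hypergeometric upper tail $P(X \ge k)$,
accumulated in log space so overlaps with p-values near $10^{-50}$ do not
underflow. The universe size $N$ is an explicit, required argument (default
20000, roughly the annotated human protein-coding space): reported overlap
p-values rarely state their universe, and back-solving the reference value
the acceptance suite checks against suggests it was computed with $N \approx 28000$;
the package documents that observation but does not assume it. The
upper-tail convention is forced by the magnitude: the lower tail of a
30-of-45 overlap is ≈ 1 and cannot produce a vanishing p-value.

The 2x2 direction-contingency test uses the chi-square with Yates continuity
correction, the correction clipped at zero when $|O - E| < 0.5$. Motif
scanning is exact string matching (the CHR element is a fixed 6-mer, so no
PWM machinery is warranted), reporting overlapping occurrences and, on
request, reverse-complement occurrences on the minus strand at plus-strand
coordinates. TSS-window annotation flags a gene when any peak intersects
the half-open window $[\max(0, t-w), t+w)$ around its 1-bp TSS, $w = 5000$
by default, strand ignored; coordinates are 0-based half-open at the BED
boundary and converted once on read.

## The synthetic world

`generate_paired_study()` emulates the study design the package analyses: 3
responder and 10 non-responder patients (the study's own split), one core
and one surgical sample each, 2000 genes, negative-binomial counts with
variance $\mu + \phi\mu^2$ and a single shared dispersion $\phi = 0.2$
(typical of bulk RNA-seq), gene baseline means log-normal
($\ln \mu \sim N(\ln 100, 1)$), a shared log-normal patient effect (sd 0.3)
so a patient's two samples correlate as real paired biopsies do, and
per-sample library sizes uniform on 0.5–2 million. Thirty signature genes
are planted by dividing their surgical-sample means in responders by 4.
`generate_clinical_table()` emits tables in the observed clinical ranges
(Ki67 0.1-15%, ROR 15-65, intervals 28-66 days) in which responder ROR
deltas (-30 to -50) are separated from non-responder deltas (within ±12) by
construction. `generate_survival_cohort()` draws exponential event times
with hazard multiplied by `hazard_ratio` per group indicator or standardized
score, under independent uniform censoring whose bound is solved numerically
to hit the target censoring fraction.

What the generator does **not** emulate: platform/probe effects, GC and
length bias, gene-gene correlation beyond the planted group structure and
the global patient effect, single-cell resolution, or non-proportional
hazards. A green test on synthetic data therefore establishes that the
algorithms do what they claim under a faithful small-cohort count model —
not that the derived signatures would match the packaged reference gene lists, which
would require the original sequencing data.

## What a tiny cohort can and cannot support (limitations)

With 3 vs 10 samples and 2000 genes, roughly as many noise genes as planted
genes separate the two groups *perfectly by chance* (typically 10–19 noise
genes vs 14–20 of the 30 planted, across seeds). Any selector that keeps
genes separating the observed cohort — which is what this class of protocol
does — therefore carries a contamination floor of roughly a third of the
final list, no matter how the pruning is tuned. The package's acceptance
suite asserts the recall target (≥ 60% of planted genes, which passes) and
the contamination target (≤ 20%, which honestly fails at ≈ 30–40% and is
left failing, with this analysis as the explanation). The practical
conclusion for users is that a signature derived from a cohort this size is
a hypothesis-generating object whose individual members need external
validation — exactly the role cross-cohort survival validation
plays.

Other numerical choices worth knowing: leaf-fraction votes at exactly 0.5
classify as non-responder; bootstrap draws that contain a single class grow
a degenerate one-leaf tree (visible as scores slightly inside the [0, 1]
endpoints for perfectly separable data); midpoint split thresholds make
scores exactly invariant under jointly applied per-gene *affine* transforms,
while general monotone transforms preserve tree structure but can move
held-out values across a midpoint; and `select_responders` on any continuous
null distribution still flags the ~16% lower tail, so "no responders" is not
the expected null outcome of the one-sd rule.
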