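---
title: "Paired-timepoint TCR repertoire dynamics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-timepoint TCR repertoire dynamics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedyn)
```

# The analysis problem

Neoadjuvant immunochemotherapy trials collect a small biopsy before
treatment and the resected tumour afterwards. Single-cell RNA + V(D)J
sequencing of both specimens lets one ask which T-cell clones expanded
under treatment, in which phenotypic subsets the expansion happened, and
whether those dynamics differ between patients who achieved a
pathological response (PCR/MPR) and those who did not (non-MPR).
`clonedyn` implements that paired-repertoire analysis as a pipeline of
small, individually tested operations, together with a synthetic-data
generator that stands in for patient data, which for such studies is
typically under restricted access.

# Clonotype calling

A cell's TCR identity is its dominant productive α/β chain pair.
Quality control is two-step:

1. **Cell level.** Contigs must be flagged `is_cell`,
   `high_confidence`, `productive` and `full_length`, and the barcode
   must appear in the cell metadata whitelist. The whitelist models
   expression-side QC (gene-count and mitochondrial filters, doublet
   removal), which this package deliberately does not re-implement: its
   input contract is "cells that survived expression QC".
2. **Clonotype level.** Per cell and locus, the dominant contig is the
   one with the most UMIs; ties fall back to read count, then to the
   lexicographically smallest nucleotide CDR3. The data give no
   principled ordering beyond UMIs, so the remaining tie-breaks are
   chosen purely for determinism — reruns must give identical output.
   Cells lacking a surviving chain of either locus are dropped; dual-TCR
   cells are not modelled (exactly one contig per locus survives).

Clonotype identity is the 6-tuple (TRA V, TRA J, TRA CDR3, TRB V,
TRB J, TRB CDR3) under exact string equality. The nucleotide CDR3 is the
default because it is the stricter definition and matches how upstream
callers report clonotypes; grouping by amino-acid CDR3 (which merges
convergent recombinations) is available via `key_mode = "aa"`.

# Diversity and clonality

For a specimen with clone copy numbers $c_1,\dots,c_N$ (cells per
clonotype) and frequencies $p_i = c_i / \sum_j c_j$:

- **Richness** is $N$.
- **Clonality** is $1 - H/\log N$ with $H = -\sum_i p_i \log p_i$;
  equivalently one minus Pielou's evenness. Numerator and denominator
  use the same logarithm, so the base cancels — the package tests this
  to $10^{-12}$. A single-clonotype repertoire makes the ratio $0/0$;
  the package defines clonality 0 there (a one-clone repertoire is
  trivially even), with `singleton = "na"` available for analysts who
  prefer a missing value.
- **Gini coefficient**
  $G = \sum_i \sum_j |p_i - p_j| \,/\, (2 N^2 \bar p)$, the mean
  absolute difference of clone frequencies normalised by twice their
  mean. It is computed via the sorted-frequency identity
  $\sum_{ij}|p_i-p_j| = 2\sum_i (2i - N - 1)\, p_{(i)}$ ($O(N\log N)$),
  and verified against an independent Lorenz-curve formulation in the
  tests.

Copy-number spectra use the bins $\{1\}$, $[2,10]$, $[11,50]$,
$(50,\infty)$ by default, separating nonexpanded, moderately expanded,
highly expanded and hyperexpanded clones; the edges are configurable.

Stratified summaries (`repertoire_summary()`) pool patients within a
response × timepoint group by default — group-level repertoire
statistics are the primary readout, and per-patient strata at biopsy
depth are noisy — but per-patient mode is one argument away. Strata
with fewer than 3 clonotypes are flagged `low_confidence` rather than
dropped.

# Expansion classes

Each clone of a patient is matched across timepoints by exact clonotype
equality (no similarity clustering) and classified from its
whole-specimen copy pair:

| class | rule |
|---|---|
| novel expanded | pre = 0, post ≥ 2 |
| persistent expanded | pre ≥ 1, post ≥ 2, post > pre |
| novel nonexpanded | pre = 0, post = 1 |
| other | everything else |

The four rules partition all attainable pairs; the test suite verifies
this by brute force over the full $[0,50]^2$ grid. Contracted clones
(pre ≥ 1, post = 0) fall in *other* but carry a `lost` tag, which keeps
pre-treatment-only expansion visible in downstream summaries.

Classes are assigned at whole-specimen level and then *projected* onto
subsets: a clone spanning effector-memory and exhausted cells keeps one
class and contributes its cells to each subset's profile. The
alternative — classifying from per-subset copy numbers — would let one
biological clone be "expanded" in one cluster and "nonexpanded" in
another, which contradicts the clone-level definition of the classes;
expansion is a property of the clone, membership of the cell.

# Subset enrichment (Ro/e)

For a subset × condition contingency table of cell counts, expected
counts are the chi-square independence values
$E_{ij} = n_{i\cdot} n_{\cdot j} / n$ and Ro/e is $O_{ij}/E_{ij}$.
Values above 1 indicate the subset is over-represented in that
condition. By construction the expected-count-weighted row mean of Ro/e
is exactly 1, and the ratio is invariant to uniform scaling of the
table — both are tested invariants. Conditions default to
response × timepoint, pooling patients. No significance test is
attached: Ro/e is reported as a descriptive enrichment ratio, and any
threshold (commonly Ro/e > 1) is presentation-layer. The post-minus-pre
difference of two Ro/e values, when exported, is labelled interpretive:
a difference of ratios has no calibrated null.

Specimen-level composition summaries exclude specimens with fewer than
20 T cells (configurable), since proportions estimated from fewer cells
are dominated by sampling noise.

# Clonal sharing between subsets

The observed statistic is the size of the intersection of two subsets'
clonotype sets. Published analyses of this kind rarely state their null;
this package defines one explicitly: shuffle subset labels across cells
(preserving every subset's size and the clone structure), recount, and
report $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$,
whose attainable minimum is $1/(n_{\text{perm}}+1)$. Because relabelling
cells outside the two subsets cannot change their intersection, the
implementation permutes within the union of the two subsets' cells —
an exact conditional equivalent that is several-fold faster. The draw
size is canonicalised by label order, making the result exactly
symmetric in the two subsets. A Spearman rank correlation of the shared
clones' cell counts in the two subsets is reported as a secondary
descriptive statistic. Calibration (type-I error 5% within Monte-Carlo
tolerance on label-exchangeable data) is part of the acceptance tests.
No claim is made that these p-values reproduce any previously published
sharing p-values, whose method is not public.

# Pathway activity scoring

Per-cell gene-set activity is the rank-based recovery-curve AUC: order
a cell's genes by decreasing expression, walk the top
$k = \lceil \text{top\_fraction} \cdot n_{\text{genes}} \rceil$ ranks
(default 5%), accumulate gene-set hits, and divide the area under that
curve by its maximum (all set genes at the very top). Only ranks enter,
so any monotone transform of one cell's expression (log, scaling,
library-size normalisation) leaves the score unchanged — a tested
invariant. Expression ties are resolved by gene name; sparse count data
tie heavily at zero, and a deterministic resolution is preferable to a
random one for reproducibility (the alternative of fractional ranks
would make the recovery curve non-integer without changing group-level
conclusions).

Group summaries z-score the per-group mean AUC across groups with the
sample standard deviation. Two-group comparisons use Welch's two-sided
unpaired t-test — chosen over Student's because equal variances between
e.g. expanded and nonexpanded clones' cells is not defensible a priori.
Two degenerate-input conventions: both groups constant and equal gives
p = 1 ("no evidence of difference" rather than an error), and a single
group yields means with an undefined (NA) z-score. Helpers implement
the two stratifications used with these scores: PDCD1-positive
(count > 0) versus PDCD1-negative (count = 0) cells, and clone-size
strata (expanded: specimen-level copy number > 2; nonexpanded: copy
number = 1; intermediate copies excluded).

# The synthetic-data generator

`simulate_repertoire()` emulates the statistical structure of a paired
neoadjuvant cohort; its defaults are the package's reference study
conditions, and the acceptance tests run against them unchanged:

- 5 patients (2 PCR, 1 MPR, 2 non-MPR), 2,000 cells per specimen;
- 14 T-cell subsets at fixed baseline proportions, spanning CD4
  naive/memory/helper/regulatory and CD8
  naive/memory/effector/resident/exhausted compartments plus MAIT, γδ
  and proliferating cells;
- background clone sizes from a discrete truncated power law
  $P(s) \propto s^{-\alpha}$, $\alpha = 2.5$, $s \le 30$;
- planted dynamics per patient: 50 novel expanded (pre 0, post ≥ 2),
  50 persistent expanded (pre 1–3, post > pre, scaled by boost
  $b = 5$), 200 novel nonexpanded (pre 0, post 1);
- planted expanded clones home to the response group's target subset —
  CD8 Tem (`c05_CD8_Tem-GZMA`) for responders, Treg
  (`c04_CD4_Treg-FOXP3`) for nonresponders — with odds multiplied by
  $b$;
- 5% of cells "spill" into a random subset, modelling imperfect cluster
  purity and creating cross-subset clones.

Two generator design choices deserve their rationale:

**Background carry-forward subsamples without replacement.** The
post-treatment background is drawn by subsampling the surviving
pre-treatment cells at the depth left over after planting, so every
background clone satisfies post ≤ pre (hypergeometric marginals), and
contracted and lost clones arise naturally. Resampling *with*
replacement would instead inflate roughly a quarter of background
singletons to post ≥ 2 > pre — hundreds of spurious
"persistent expanded" clones per specimen that no detection method
could distinguish from planted ones, because under that model they
genuinely are expanded. Ground truth must be recoverable in principle
for recovery metrics to mean anything, so the generator reserves
expansion for the planted classes.

**The clone-size cap is 30** (1.5% of a 2,000-cell specimen). The cap
bounds the exchangeable background's upper tail: treatment-driven
expansion — the signal — must dominate the top of the post-treatment
clone-size distribution, and the directional property the generator is
required to exhibit (post-treatment clonality and Gini of the boosted
subset exceeding pre-treatment values in ≥ 95% of seeds, mirroring the
qualitative finding in responders) fails sporadically if a single
background clone can occupy several percent of a subset by chance.
Real repertoires do contain larger clones; in this generator's
vocabulary those are precisely the expanded classes, planted with known
labels, not background.

`simulate_expression()` adds negative-binomial counts (gene-level
log-normal baseline means, dispersion 2) for 500 genes plus a PDCD1
marker row, with two planted 30-gene pathway sets whose means are
multiplied by $1+\delta$ in designated cells. With $\delta = 0$ the
mean AUC difference between matched groups stays below 0.02 at 500
cells per group; with $\delta = 2$ the Welch test detects the effect at
p < 0.01 in ≥ 95% of seeds — both run as acceptance checks.

**What the generator does not emulate**, and hence what passing tests
do not show about real data: V(D)J recombination biology (CDR3s are
random in-frame nucleotide strings; V/J names come from a small fixed
vocabulary), convergent recombination and dual-TCR cells, ambient-RNA
or doublet artefacts in the contig table (all synthetic contigs pass
QC, so QC rejection paths are exercised by hand-built fixtures
instead), transcriptome structure beyond independent NB genes
(no gene–gene correlation, batch effects or subset-specific expression
programmes), and clinical covariates. Recovery results on synthetic
data certify the pipeline's correctness, not the discriminative power
of these statistics on any real cohort.

# Numerical and validation choices

- All randomness flows through explicit integer seeds;
  `sharing_significance()` restores the caller's RNG state on exit.
- Clone tables order clones by decreasing copy number, ties by
  clonotype id, so written outputs are byte-stable across reruns.
- The run manifest records md5 digests of every input and output file;
  rerun-digest equality is the pipeline-level determinism test.
- Validation problem sizes: metric oracles on hand-sized repertoires
  plus 100 random repertoires (N ≤ 200) against the Lorenz oracle;
  expansion classification brute-forced over the $[0,50]^2$ grid;
  sharing calibration on 200 label-exchangeable datasets of 500 cells
  at 1,000 permutations each; pathway null/power at 500 cells per group
  over 20 seeds; end-to-end recovery at the default study conditions
  over 20 seeds. These sizes give the recovery and calibration rates
  stable second decimals while keeping the full suite fast enough to
  run on every change.

# Known limitations

- No BCR support, no dual-TCR modelling, no CDR3 similarity clustering
  (clones match only by exact key).
- Ro/e differences between timepoints are descriptive; the package
  provides no differential-abundance model (no CLR transforms or
  count-model alternatives).
- The sharing permutation null conditions on the observed clone
  structure; it does not model clonal selection processes that could
  correlate subset membership with clone size under the null.
- Pathway gene sets are user-supplied (GMT); the package ships none
  beyond the synthetic generator's planted sets.
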