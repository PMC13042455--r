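Package: clonedyn
Title: Paired-Timepoint Single-Cell TCR Repertoire Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired pre- and post-treatment single-cell T-cell
    receptor (TCR) repertoires. Parses 10x Genomics V(D)J contig annotation
    tables, applies two-step cell- and clonotype-level quality control, and
    tracks alpha/beta clonotypes across treatment timepoints. Computes
    repertoire richness, clonality (1 minus Pielou's evenness), the Gini
    coefficient of clone frequencies and copy-number spectra; classifies
    clones as novel expanded, persistent expanded, novel nonexpanded or
    other; quantifies T-cell subset enrichment via observed/expected (Ro/e)
    ratios; tests inter-subset clonal sharing with a label-permutation null;
    and scores per-cell gene-set activity with a rank-based recovery-curve
    AUC. A seeded synthetic-repertoire generator with planted ground truth
    supports end-to-end validation without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
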