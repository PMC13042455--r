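# clonedyn

Paired-timepoint single-cell TCR repertoire dynamics.

`clonedyn` analyses how the T-cell receptor (TCR) repertoire of a tumour
changes between a pre-treatment biopsy and a post-treatment resection,
the design used to study response to neoadjuvant immunochemotherapy in
non-small-cell lung cancer. It is aimed at immunologists and
computational biologists working with 10x Genomics single-cell V(D)J
data who want a tested, scriptable implementation of the standard
paired-repertoire toolkit:

- **Clonotype calling** from contig annotation tables with two-step QC:
  keep cells on the expression-QC whitelist that carry productive,
  full-length TRA and TRB chains, then select the dominant α/β pair per
  cell (highest UMI support; ties by reads, then CDR3). Each unique α/β
  combination is a clonotype; its copy number is the number of cells
  carrying it.
- **Repertoire diversity**: richness *N* (unique clonotypes), clonality

  `clonality = 1 − H / log N`, with `H = −Σ p_i log p_i`

  (one minus Pielou's evenness; base-independent), and the Gini
  coefficient of clone frequencies

  `G = Σ_i Σ_j |p_i − p_j| / (2 N² p̄)`,

  plus copy-number spectra over the bins {1}, [2,10], [11,50], >50.
- **Expansion-class tracking** across timepoints: each clone's
  (pre, post) copy pair is classified as *novel expanded* (0, ≥2),
  *persistent expanded* (≥1, ≥2, post > pre), *novel nonexpanded*
  (0, 1), or *other* (contracted/lost clones are tagged).
- **Subset enrichment** via Ro/e, the ratio of observed to chi-square
  expected cell counts per subset × condition.
- **Inter-subset clonal sharing** with a label-permutation significance
  test on the shared-clonotype count.
- **Per-cell pathway activity** as a rank-based recovery-curve AUC
  (AUCell-style, top 5% of genes by default), with z-scored group means
  and Welch t-tests, including PDCD1+/− and clone-size stratifications.
- A **seeded synthetic-data generator** that emits paired repertoires in
  the 10x contig dialect with planted ground truth (power-law clone
  sizes, response-dependent expansion of a target subset, planted
  pathway effects), so the whole pipeline is testable without access to
  restricted patient data.

## Worked example

Simulate two patients (one responder with pathological complete
response, one nonresponder), 1,000 cells per specimen, with 25 novel +
25 persistent expanded clones planted per patient, and run the full
pipeline on the written fixture files:

```r
library(clonedyn)

cfg <- simulation_config(n_patients = c(PCR = 1L, nonMPR = 1L),
                         n_cells = 1000L,
                         n_novel_expanded = 25L,
                         n_persistent_expanded = 25L,
                         n_novel_nonexpanded = 100L, seed = 42L)
sim <- simulate_repertoire(cfg)
dir <- file.path(tempdir(), "demo")
paths <- write_fixture_bundle(sim, dir)

contig_paths <- paths[grep("^contigs_", names(paths))]
names(contig_paths) <- sub("^contigs_", "", names(contig_paths))
bundle <- run_pipeline(run_config(contig_paths, paths[["metadata"]],
                                  n_permutations = 500L, seed = 42L,
                                  out_dir = file.path(dir, "out")))
summarize_report(bundle)
```

```
clonedyn run: 5 of 6 stages present (cells, metrics, dynamics, roe, sharing)
absent stages: scores
  nonMPR/post: richness 483, clonality 0.082, gini 0.451 (1000 cells)
  nonMPR/pre: richness 559, clonality 0.061, gini 0.378 (1000 cells)
  PCR/post: richness 538, clonality 0.067, gini 0.404 (1000 cells)
  PCR/pre: richness 628, clonality 0.044, gini 0.320 (1000 cells)
  top expanded subsets (post-treatment cells in expanded clones): c05_CD8_Tem-GZMA (165), c01_CD4_Tn (91), c04_CD4_Treg-FOXP3 (76)
  top Ro/e in nonMPR_post: c08_CD8_Trm-ZNF683 (1.43), c11_CD4_Tfh (1.41), c03_CD4_Th-CXCL13 (1.24)
  top Ro/e in nonMPR_pre: c07_CD8_Teff-IFNG (1.37), c14_Tprolif (1.31), c11_CD4_Tfh (1.26)
  top Ro/e in PCR_post: c05_CD8_Tem-GZMA (1.59), c12_MAIT (1.20), c02_CD4_Tcm (1.19)
  top Ro/e in PCR_pre: c04_CD4_Treg-FOXP3 (1.29), c02_CD4_Tcm (1.22), c06_CD8_Tem-EGR1 (1.20)
  sharing pairs at p < 0.05: 0 of 364 tested
```

Reading the output: clonality and Gini rise from pre to post in both
patients (treatment-driven expansion), the responder's expansion
concentrates in the CD8 effector-memory subset (`c05_CD8_Tem-GZMA`,
which also tops the post-treatment responder Ro/e at 1.59), and no
subset pair shares clonotypes beyond what label permutation explains —
the generator plants subset-pure clones, so this is the expected null.
Per-stage tables (cell-level clonotypes, paired clone classes, Ro/e in
long format, sharing p-values) and a JSON manifest with md5 digests are
in `file.path(dir, "out")`.

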