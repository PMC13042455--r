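#' Default 14-subset T-cell composition
#'
#' Baseline subset proportions used by the simulator, covering the CD4/CD8
#' compartments observed in neoadjuvant NSCLC tumours (naive, central and
#' effector memory, effector, tissue-resident memory, exhausted, regulatory,
#' MAIT, gamma-delta and proliferating T cells).
#'
#' @return Named numeric vector of 14 proportions summing to 1.
#' @export
default_subset_proportions <- function() {
  c("c01_CD4_Tn"          = 0.12,
    "c02_CD4_Tcm"         = 0.10,
    "c03_CD4_Th-CXCL13"   = 0.08,
    "c04_CD4_Treg-FOXP3"  = 0.10,
    "c05_CD8_Tem-GZMA"    = 0.12,
    "c06_CD8_Tem-EGR1"    = 0.08,
    "c07_CD8_Teff-IFNG"   = 0.08,
    "c08_CD8_Trm-ZNF683"  = 0.07,
    "c09_CD8_Tex-HAVCR2"  = 0.07,
    "c10_CD8_Tn"          = 0.06,
    "c11_CD4_Tfh"         = 0.04,
    "c12_MAIT"            = 0.04,
    "c13_gdT"             = 0.02,
    "c14_Tprolif"         = 0.02)
}

#' Simulation configuration
#'
#' Parameters of the synthetic paired-repertoire generator. Defaults
#' describe the study conditions the package is validated under: five
#' patients across the three pathological-response strata, two specimens
#' (pre-/post-treatment) of 2,000 T cells each, a discrete truncated
#' power-law clone-size law with exponent 2.5, a five-fold expansion boost
#' concentrated in the CD8 effector-memory subset for responders (PCR/MPR)
#' and in the regulatory subset for nonresponders, and 50 novel-expanded,
#' 50 persistent-expanded and 200 novel-nonexpanded clones planted per
#' specimen pair.
#'
#' @param n_patients Named integer vector: patients per response group.
#' @param n_cells Cells per specimen.
#' @param subsets Named baseline subset proportions (must sum to 1).
#' @param alpha Power-law exponent (> 1) of the clone-size law.
#' @param max_copy Truncation cap of the clone-size law.
#' @param boost Expansion boost factor `b >= 1`: scales planted expanded
#'   clone sizes and the odds that a planted expanded clone homes to the
#'   response group's target subset.
#' @param target_subsets Named character vector: target subset per response
#'   group.
#' @param n_novel_expanded,n_persistent_expanded,n_novel_nonexpanded
#'   Planted clone counts per specimen pair.
#' @param spill Probability that a cell is annotated outside its clone's
#'   home subset (models imperfect cluster purity; creates cross-subset
#'   clones).
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_patients = c(PCR = 2L, MPR = 1L, nonMPR = 2L),
                              n_cells = 2000L,
                              subsets = default_subset_proportions(),
                              alpha = 2.5,
                              max_copy = 30L,
                              boost = 5,
                              target_subsets = c(
                                PCR = "c05_CD8_Tem-GZMA",
                                MPR = "c05_CD8_Tem-GZMA",
                                nonMPR = "c04_CD4_Treg-FOXP3"),
                              n_novel_expanded = 50L,
                              n_persistent_expanded = 50L,
                              n_novel_nonexpanded = 200L,
                              spill = 0.05,
                              seed = 1L) {
  stopifnot(all(n_patients >= 0), n_cells >= 1, alpha > 1, max_copy >= 2,
            boost >= 1, spill >= 0, spill < 1)
  if (abs(sum(subsets) - 1) > 1e-8) stop("subset proportions must sum to 1")
  if (!all(names(n_patients) %in% RESPONSES))
    stop("response groups must be among: ", paste(RESPONSES, collapse = ", "))
  if (!all(target_subsets %in% names(subsets)))
    stop("target subsets must be named subset labels")
  structure(list(n_patients = n_patients, n_cells = as.integer(n_cells),
                 subsets = subsets, alpha = alpha,
                 max_copy = as.integer(max_copy), boost = boost,
                 target_subsets = target_subsets,
                 n_novel_expanded = as.integer(n_novel_expanded),
                 n_persistent_expanded = as.integer(n_persistent_expanded),
                 n_novel_nonexpanded = as.integer(n_novel_nonexpanded),
                 spill = spill, seed = as.integer(seed)),
            class = "sim_config")
}

# discrete truncated power law on 1..max_copy: P(s) propto s^-alpha.
# The default cap (30 = 1.5% of a 2,000-cell specimen) keeps the background
# upper tail below the planted treatment-driven expansion it must not mimic.
sample_power_law <- function(n, alpha, max_copy) {
  s <- seq_len(max_copy)
  sample(s, n, replace = TRUE, prob = s^(-alpha))
}

V_GENES_TRA <- paste0("TRAV", c("1-1", "1-2", "3", "8-2", "12-1", "13-1",
                                "17", "21", "26-1", "38-1"))
J_GENES_TRA <- paste0("TRAJ", c(4, 9, 13, 20, 23, 30, 33, 42, 49, 53))
V_GENES_TRB <- paste0("TRBV", c("2", "4-1", "5-1", "6-5", "7-2", "9",
                                "12-3", "19", "20-1", "28"))
J_GENES_TRB <- paste0("TRBJ", c("1-1", "1-2", "1-5", "2-1", "2-3", "2-7"))

# n unique synthetic clonotypes: random V/J picks + random in-frame CDR3s
make_clonotypes <- function(n) {
  draw <- function(m) {
    len <- 3L * sample(9:15, m, replace = TRUE)
    vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
  }
  tra <- draw(n); trb <- draw(n)
  key <- paste0(tra, "+", trb)
  while (anyDuplicated(key)) {        # collisions are ~impossible, but exact
    dup <- which(duplicated(key))
    trb[dup] <- draw(length(dup))
    key <- paste0(tra, "+", trb)
  }
  data.frame(tra_v = sample(V_GENES_TRA, n, replace = TRUE),
             tra_j = sample(J_GENES_TRA, n, replace = TRUE),
             tra_cdr3 = tra,
             trb_v = sample(V_GENES_TRB, n, replace = TRUE),
             trb_j = sample(J_GENES_TRB, n, replace = TRUE),
             trb_cdr3 = trb, stringsAsFactors = FALSE)
}

# home-subset sampler: planted expanded clones prefer the target subset with
# odds multiplied by the boost factor
sample_subsets <- function(n, proportions, target = NULL, boost = 1) {
  w <- proportions
  if (!is.null(target)) w[target] <- w[target] * boost
  sample(names(proportions), n, replace = TRUE, prob = w / sum(w))
}

#' Simulate paired pre/post-treatment TCR repertoires with planted truth
#'
#' For each synthetic patient: the pre-treatment repertoire mixes planted
#' persistent clones (1-3 copies) into a background of clones drawn from
#' the truncated power law; the post-treatment repertoire is built from
#' (i) the planted persistent clones expanded by the boost factor
#' (`post > pre >= 1, post >= 2`), (ii) planted novel expanded clones
#' (`pre = 0, post >= 2`), (iii) planted novel nonexpanded clones
#' (`pre = 0, post = 1`), and (iv) background carry-forward that subsamples
#' the surviving pre-treatment cells without replacement, so background
#' clones satisfy `post <= pre` and contracted/lost clones arise naturally.
#' Planted expanded clones home to the response group's target subset with
#' boosted odds. Output is emitted in the 10x contig-table dialect: one
#' productive, full-length TRA and TRB contig per cell.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_bundle`: `contigs` (named list of contig
#'   `data.frame`s, one per `patient_timepoint` specimen), `metadata` (one
#'   row per cell), `ground_truth` (one row per clonotype: `patient`,
#'   `clonotype_id`, `planted_class` — `background` for unplanted clones —
#'   `home_subset`, `pre_copies`, `post_copies`), and `config`.
#' @export
simulate_repertoire <- function(config = simulation_config()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  n_planted_min <- config$n_persistent_expanded * 2L +
    config$n_novel_expanded * 2L + config$n_novel_nonexpanded
  if (n_planted_min > config$n_cells)
    stop("planted clone counts exceed the specimen cell budget")

  patients <- unlist(lapply(names(config$n_patients), function(r)
    rep(r, config$n_patients[[r]])))
  patient_ids <- sprintf("P%02d", seq_along(patients))

  contigs <- list(); metadata <- list(); truth <- list()
  for (i in seq_along(patient_ids)) {
    sim <- simulate_patient(patient_ids[i], patients[i], config)
    contigs <- c(contigs, sim$contigs)
    metadata[[i]] <- sim$metadata
    truth[[i]] <- sim$truth
  }
  structure(list(contigs = contigs,
                 metadata = do.call(rbind, metadata),
                 ground_truth = do.call(rbind, truth),
                 config = config),
            class = "sim_bundle")
}

simulate_patient <- function(patient, response, config) {
  target <- config$target_subsets[[response]]
  b <- config$boost
  n_pers <- config$n_persistent_expanded
  n_nov <- config$n_novel_expanded
  n_nn <- config$n_novel_nonexpanded

  # planted persistent clones: small pre size, boosted post size
  pers_pre <- sample(1:3, n_pers, replace = TRUE)
  pers_post <- pers_pre + 1L + if (b > 1)
    rpois(n_pers, (b - 1) * pers_pre) else rep(0L, n_pers)
  # planted novel expanded: absent pre, boosted post
  nov_post <- 2L + if (b > 1) rpois(n_nov, max(0, b - 2)) else rep(0L, n_nov)

  planted_cells_post <- sum(pers_post) + sum(nov_post) + n_nn
  if (planted_cells_post > config$n_cells)
    stop("planted post-treatment cells exceed the specimen cell budget")

  # pre-treatment background: power-law clones until the cell budget fills
  bg_budget <- config$n_cells - sum(pers_pre)
  bg_sizes <- integer(0)
  while (sum(bg_sizes) < bg_budget)
    bg_sizes <- c(bg_sizes, sample_power_law(
      max(64L, ceiling((bg_budget - sum(bg_sizes)) / 2)),
      config$alpha, config$max_copy))
  over <- which(cumsum(bg_sizes) >= bg_budget)[1]
  bg_sizes <- bg_sizes[seq_len(over)]
  bg_sizes[over] <- bg_sizes[over] - (sum(bg_sizes) - bg_budget)
  bg_sizes <- bg_sizes[bg_sizes > 0L]
  n_bg <- length(bg_sizes)

  # background carry-forward: subsample surviving pre cells w/o replacement
  bg_post_budget <- config$n_cells - planted_cells_post
  if (bg_post_budget > sum(bg_sizes))
    stop("background carry-forward depth exceeds pre-treatment background")
  bg_cell_clone <- rep.int(seq_len(n_bg), bg_sizes)
  kept <- sample(bg_cell_clone, bg_post_budget)
  bg_post <- tabulate(kept, nbins = n_bg)

  n_clones <- n_pers + n_nov + n_nn + n_bg
  keys <- make_clonotypes(n_clones)
  classes <- rep(c("persistent_expanded", "novel_expanded",
                   "novel_nonexpanded", "background"),
                 c(n_pers, n_nov, n_nn, n_bg))
  home <- c(sample_subsets(n_pers, config$subsets, target, b),
            sample_subsets(n_nov, config$subsets, target, b),
            sample_subsets(n_nn, config$subsets),
            sample_subsets(n_bg, config$subsets))
  pre_copies <- c(pers_pre, rep(0L, n_nov + n_nn), bg_sizes)
  post_copies <- c(pers_post, nov_post, rep(1L, n_nn), bg_post)

  clone_ids <- paste0(keys$tra_v, "|", keys$tra_j, "|", keys$tra_cdr3, "+",
                      keys$trb_v, "|", keys$trb_j, "|", keys$trb_cdr3)
  truth <- data.frame(patient = patient, response = response,
                      clonotype_id = clone_ids, planted_class = classes,
                      home_subset = home, pre_copies = pre_copies,
                      post_copies = post_copies, stringsAsFactors = FALSE)

  out_contigs <- list(); out_meta <- list()
  for (tp in TIMEPOINTS) {
    copies <- if (tp == "pre") pre_copies else post_copies
    cell_clone <- rep.int(seq_len(n_clones), copies)
    n <- length(cell_clone)
    barcode <- sprintf("%s_%s_%05d", patient, tp, seq_len(n))
    subset <- home[cell_clone]
    if (config$spill > 0) {
      flip <- runif(n) < config$spill
      subset[flip] <- sample_subsets(sum(flip), config$subsets)
    }
    out_meta[[tp]] <- data.frame(barcode = barcode, patient = patient,
                                 timepoint = tp, response = response,
                                 subset = subset, stringsAsFactors = FALSE)
    out_contigs[[paste0(patient, "_", tp)]] <-
      emit_contigs(barcode, keys[cell_clone, , drop = FALSE])
  }
  list(contigs = out_contigs, metadata = do.call(rbind, out_meta),
       truth = truth)
}

# one productive full-length TRA and TRB contig row per cell, 10x dialect
emit_contigs <- function(barcodes, keys) {
  n <- length(barcodes)
  umis_a <- sample(1:10, n, replace = TRUE)
  umis_b <- sample(1:10, n, replace = TRUE)
  one <- function(chain, v, j, nt, umis) {
    data.frame(barcode = barcodes, is_cell = TRUE,
               high_confidence = TRUE, chain = chain, v_gene = v,
               j_gene = j, cdr3 = translate_cdr3(nt), cdr3_nt = nt,
               reads = umis * sample(2:8, n, replace = TRUE), umis = umis,
               productive = TRUE, full_length = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("TRA", keys$tra_v, keys$tra_j, keys$tra_cdr3, umis_a),
               one("TRB", keys$trb_v, keys$trb_j, keys$trb_cdr3, umis_b))
  out[order(out$barcode, out$chain, method = "radix"), , drop = FALSE]
}

# crude standard-code translation, adequate for synthetic amino-acid CDR3s
translate_cdr3 <- function(nt) {
  codons <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  vapply(nt, function(s) {
    cs <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(codons[cs], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a sparse expression matrix with planted pathway activity
#'
#' Negative-binomial background counts per gene and cell; the two planted
#' pathway gene sets have their means multiplied by `1 + effect` in the
#' designated cells (in the study design, expanded regulatory-T clones of
#' nonresponsive tumours), and a PDCD1 marker gene is switched on in a
#' designated subpopulation.
#'
#' @param cells Cell metadata (`barcode` column used, one column per cell).
#' @param n_genes Number of background genes (default 500).
#' @param pathway_sizes Named integer vector: genes per planted set.
#' @param effect Effect size `delta >= 0`; pathway gene means are scaled by
#'   `1 + delta` in `boosted_cells`.
#' @param boosted_cells Barcodes receiving the pathway effect.
#' @param pdcd1_positive Barcodes with nonzero PDCD1 expression.
#' @param nb_size Negative-binomial dispersion (default 2).
#' @param seed Integer seed.
#' @return A list of class `sim_expression`: `matrix` (genes x cells
#'   `dgCMatrix`), `gene_sets` (named list), `pdcd1_gene`.
#' @export
simulate_expression <- function(cells, n_genes = 500L,
                                pathway_sizes = c(IL2_STAT5 = 30L,
                                                  TGFB_SMAD = 30L),
                                effect = 2, boosted_cells = character(),
                                pdcd1_positive = character(),
                                nb_size = 2, seed = 1L) {
  if (effect < 0) stop("effect size must be non-negative")
  if (any(pathway_sizes < 1L)) stop("pathway gene sets must be non-empty")
  if (sum(pathway_sizes) > n_genes)
    stop("pathway sets exceed the gene budget")
  set.seed(seed)
  barcodes <- cells$barcode
  n_cells <- length(barcodes)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  set_idx <- split(seq_len(sum(pathway_sizes)),
                   rep(names(pathway_sizes), pathway_sizes))
  gene_sets <- lapply(set_idx, function(ix) genes[ix])

  mu <- exp(rnorm(n_genes, log(0.5), 0.8))   # gene-level baseline means
  boosted <- barcodes %in% boosted_cells
  in_set <- seq_len(n_genes) %in% unlist(set_idx)
  counts <- matrix(0L, n_genes, n_cells)
  for (j in seq_len(n_cells)) {
    mu_j <- mu
    if (boosted[j]) mu_j[in_set] <- mu_j[in_set] * (1 + effect)
    counts[, j] <- rnbinom(n_genes, mu = mu_j, size = nb_size)
  }
  pdcd1 <- integer(n_cells)
  pos <- barcodes %in% pdcd1_positive
  pdcd1[pos] <- 1L + rpois(sum(pos), 2)
  counts <- rbind(counts, PDCD1 = pdcd1)
  rownames(counts) <- c(genes, "PDCD1")
  colnames(counts) <- barcodes
  structure(list(matrix = methods::as(methods::as(counts, "CsparseMatrix"),
                                      "generalMatrix"),
                 gene_sets = gene_sets, pdcd1_gene = "PDCD1"),
            class = "sim_expression")
}

#' Write a simulated bundle to plain-text fixture files
#'
#' Emits the formats the pipeline reads back: one 10x-dialect contig CSV per
#' specimen, a tab-delimited metadata table, the ground-truth clone table,
#' and (when expression is supplied) a MatrixMarket matrix with gene and
#' barcode lists plus a GMT file of the planted gene sets. Two runs from
#' the same seeded bundle produce byte-identical files.
#'
#' @param bundle A `sim_bundle` from [simulate_repertoire()].
#' @param dir Output directory (created if needed).
#' @param expression Optional `sim_expression` from [simulate_expression()].
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir, expression = NULL) {
  if (!inherits(bundle, "sim_bundle")) stop("bundle must be a sim_bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)
  for (sp in names(bundle$contigs)) {
    p <- file.path(dir, paste0(sp, "_contigs.csv"))
    df <- bundle$contigs[[sp]]
    for (col in c("is_cell", "high_confidence", "productive", "full_length"))
      df[[col]] <- ifelse(df[[col]], "True", "False")  # 10x boolean tokens
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    paths[paste0("contigs_", sp)] <- p
  }
  p <- file.path(dir, "cell_metadata.tsv")
  write.table(bundle$metadata, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["metadata"] <- p
  p <- file.path(dir, "ground_truth.tsv")
  write.table(bundle$ground_truth, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["ground_truth"] <- p
  if (!is.null(expression)) {
    m <- expression$matrix
    paths["matrix"] <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(m, paths["matrix"])
    paths["genes"] <- file.path(dir, "genes.tsv")
    writeLines(rownames(m), paths["genes"])
    paths["barcodes"] <- file.path(dir, "barcodes.tsv")
    writeLines(colnames(m), paths["barcodes"])
    paths["gmt"] <- file.path(dir, "gene_sets.gmt")
    gmt <- vapply(names(expression$gene_sets), function(s)
      paste(c(s, "synthetic planted gene set",
              expression$gene_sets[[s]]), collapse = "\t"), character(1))
    writeLines(gmt, paths["gmt"])
  }
  invisible(paths)
}
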