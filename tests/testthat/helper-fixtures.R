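# in-code fixture builders shared across test files

# one contig row with sensible defaults; override any field
contig_row <- function(barcode, chain, umis = 5L, reads = 20L,
                       productive = TRUE, full_length = TRUE,
                       is_cell = TRUE, high_confidence = TRUE,
                       cdr3_nt = "TGTGCAAGC", v_gene = paste0(chain, "V1"),
                       j_gene = paste0(chain, "J1"), cdr3 = "CAS") {
  data.frame(barcode = barcode, is_cell = is_cell,
             high_confidence = high_confidence, chain = chain,
             v_gene = v_gene, j_gene = j_gene, cdr3 = cdr3,
             cdr3_nt = cdr3_nt, reads = reads, umis = umis,
             productive = productive, full_length = full_length,
             stringsAsFactors = FALSE)
}

make_metadata <- function(barcodes, patient = "P1", timepoint = "pre",
                          response = "PCR", subset = "c05_CD8_Tem-GZMA") {
  data.frame(barcode = barcodes, patient = patient, timepoint = timepoint,
             response = response, subset = subset, stringsAsFactors = FALSE)
}

# cell-clonotype table straight from (barcode, clonotype, subset) triples,
# bypassing contig parsing, for modules downstream of vdj_io
make_cells <- function(clonotype, subset, patient = "P1",
                       timepoint = "post", response = "PCR",
                       barcode = NULL) {
  n <- length(clonotype)
  data.frame(barcode = (barcode %||% sprintf("bc%04d", seq_len(n)))[seq_len(n)],
             patient = rep_len(patient, n), timepoint = rep_len(timepoint, n),
             response = rep_len(response, n),
             subset = rep_len(subset, n), tra_v = rep_len("TRAV1", n),
             tra_j = rep_len("TRAJ1", n),
             tra_cdr3 = clonotype, trb_v = rep_len("TRBV1", n),
             trb_j = rep_len("TRBJ1", n), trb_cdr3 = clonotype,
             clonotype_id = if (n) paste0("TRAV1|TRAJ1|", clonotype,
                                          "+TRBV1|TRBJ1|", clonotype)
                            else character(0),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a contig data.frame as a 10x-dialect csv (logicals as True/False)
write_contig_csv <- function(df, path = tempfile(fileext = ".csv")) {
  for (col in c("is_cell", "high_confidence", "productive", "full_length"))
    if (is.logical(df[[col]]))
      df[[col]] <- ifelse(df[[col]], "True", "False")
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

# random clone table as a bare copy-number vector
random_copies <- function(n_max = 200L) {
  n <- sample(2:n_max, 1L)
  sample(1:50, n, replace = TRUE)
}

# independent Lorenz-curve gini oracle (trapezoid-free discrete form)
gini_lorenz_oracle <- function(copies) {
  p <- sort(copies / sum(copies))
  n <- length(p)
  lorenz <- cumsum(p) / sum(p)
  1 - (2 * sum(lorenz) - 1) / n
}
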