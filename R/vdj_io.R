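#' Column dialect for 10x-style contig annotation tables
#'
#' Describes how a delimited contig annotation file (one row per assembled
#' V(D)J contig) maps onto the fields the pipeline needs. The default matches
#' the 10x Genomics `filtered_contig_annotations.csv` layout.
#'
#' @param sep Field separator (default `","`).
#' @param columns Named character vector mapping internal field names
#'   (`barcode`, `is_cell`, `high_confidence`, `chain`, `v_gene`, `j_gene`,
#'   `cdr3`, `cdr3_nt`, `reads`, `umis`, `productive`, `full_length`) to the
#'   column names used in the file.
#' @param true_tokens,false_tokens Tokens accepted as logical TRUE/FALSE in
#'   the boolean columns (case-sensitive match after trimming).
#' @return A list of class `contig_dialect`.
#' @export
contig_dialect <- function(sep = ",",
                           columns = NULL,
                           true_tokens = c("True", "TRUE", "true"),
                           false_tokens = c("False", "FALSE", "false", "None")) {
  default_cols <- c(barcode = "barcode", is_cell = "is_cell",
                    high_confidence = "high_confidence", chain = "chain",
                    v_gene = "v_gene", j_gene = "j_gene",
                    cdr3 = "cdr3", cdr3_nt = "cdr3_nt",
                    reads = "reads", umis = "umis",
                    productive = "productive", full_length = "full_length")
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), names(default_cols))
    if (length(bad))
      stop("unknown dialect fields: ", paste(bad, collapse = ", "))
    default_cols[names(columns)] <- columns
  }
  structure(list(sep = sep, columns = default_cols,
                 true_tokens = true_tokens, false_tokens = false_tokens),
            class = "contig_dialect")
}

parse_dialect_logical <- function(x, column, dialect, lines) {
  x <- trimws(x)
  out <- rep(NA, length(x))
  out[x %in% dialect$true_tokens] <- TRUE
  out[x %in% dialect$false_tokens] <- FALSE
  if (anyNA(out))
    stop(sprintf("column '%s': unparseable boolean value '%s' at line %d",
                 column, x[which(is.na(out))[1]], lines[which(is.na(out))[1]]))
  out
}

parse_dialect_integer <- function(x, column, lines) {
  x <- trimws(x)
  out <- suppressWarnings(as.integer(x))
  bad <- is.na(out) | out < 0L
  if (any(bad))
    stop(sprintf("column '%s': unparseable or negative integer '%s' at line %d",
                 column, x[which(bad)[1]], lines[which(bad)[1]]))
  out
}

#' Read a contig annotation table
#'
#' Parses a delimited 10x-dialect contig annotation file into one record per
#' assembled contig. Chain labels other than TRA/TRB (e.g. IGH, Multi) are
#' preserved verbatim; filtering happens later in [call_clonotypes()].
#'
#' @param path Path to the delimited text file (header row required).
#' @param dialect A [contig_dialect()] describing separator, column names and
#'   boolean tokens.
#' @return A `data.frame` with columns `barcode`, `is_cell`,
#'   `high_confidence`, `chain`, `v_gene`, `j_gene`, `cdr3`, `cdr3_nt`,
#'   `reads`, `umis`, `productive`, `full_length`.
#' @export
read_contigs <- function(path, dialect = contig_dialect()) {
  if (!file.exists(path)) stop("contig file not found: ", path)
  raw <- read.delim(path, sep = dialect$sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  cols <- dialect$columns
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols))
    stop("contig file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  lines <- seq_len(n) + 1L  # file line numbers (header is line 1)
  out <- data.frame(
    barcode = raw[[cols["barcode"]]],
    chain   = raw[[cols["chain"]]],
    v_gene  = raw[[cols["v_gene"]]],
    j_gene  = raw[[cols["j_gene"]]],
    cdr3    = raw[[cols["cdr3"]]],
    cdr3_nt = raw[[cols["cdr3_nt"]]],
    stringsAsFactors = FALSE
  )
  for (b in c("is_cell", "high_confidence", "productive", "full_length"))
    out[[b]] <- parse_dialect_logical(raw[[cols[b]]], cols[b], dialect, lines)
  for (i in c("reads", "umis"))
    out[[i]] <- parse_dialect_integer(raw[[cols[i]]], cols[i], lines)
  out[, c("barcode", "is_cell", "high_confidence", "chain", "v_gene",
          "j_gene", "cdr3", "cdr3_nt", "reads", "umis", "productive",
          "full_length")]
}

#' Read a cell metadata table
#'
#' Tab-delimited table with one row per cell barcode that passed expression
#' quality control, carrying the patient, timepoint, response-group and
#' T-cell subset annotations used throughout the pipeline.
#'
#' @param path Path to a tab-delimited file with header columns `barcode`,
#'   `patient`, `timepoint`, `response`, `subset`.
#' @return A `data.frame` with those five character columns.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, sep = "\t", colClasses = "character",
                   stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(metadata) {
  required <- c("barcode", "patient", "timepoint", "response", "subset")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(metadata$barcode))
    stop("metadata barcodes are not unique")
  bad_tp <- setdiff(unique(metadata$timepoint), TIMEPOINTS)
  if (length(bad_tp))
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "))
  invisible(metadata)
}

#' Assign a paired alpha/beta clonotype to each quality-passing cell
#'
#' Two-step quality control. Step 1 (cell level): drop contigs failing any of
#' `is_cell`, `high_confidence`, `productive`, `full_length`, and drop cells
#' whose barcode is absent from the metadata whitelist (cells that failed
#' expression QC). Step 2 (clonotype level): within each cell pick the
#' dominant TRA and dominant TRB contig — highest UMI count, ties broken by
#' highest read count, then by lexicographically smallest nucleotide CDR3 —
#' and drop cells lacking a surviving chain of either locus. The dominant
#' pair defines the cell's functional TCR; every unique alpha/beta
#' combination is one clonotype and all cells sharing it form one clone.
#'
#' @param contigs Contig table as returned by [read_contigs()].
#' @param metadata Cell metadata as returned by [read_cell_metadata()].
#' @param key_mode `"nt"` (default) keys clonotypes on the nucleotide CDR3;
#'   `"aa"` uses the amino-acid CDR3 (coarser grouping).
#' @return A `data.frame` with one row per retained cell: `barcode`,
#'   `patient`, `timepoint`, `response`, `subset`, the six clonotype-key
#'   fields `tra_v`, `tra_j`, `tra_cdr3`, `trb_v`, `trb_j`, `trb_cdr3`, and
#'   `clonotype_id` (the six fields joined with `"|"` / `"+"`; exact string
#'   equality of ids is clonotype identity).
#' @export
call_clonotypes <- function(contigs, metadata, key_mode = c("nt", "aa")) {
  key_mode <- match.arg(key_mode)
  validate_metadata(metadata)
  if (nrow(contigs) == 0L) return(empty_cell_clonotypes())

  keep <- contigs$is_cell & contigs$high_confidence &
    contigs$productive & contigs$full_length &
    contigs$chain %in% c("TRA", "TRB") &
    contigs$barcode %in% metadata$barcode
  surv <- contigs[keep, , drop = FALSE]
  if (nrow(surv) == 0L) return(empty_cell_clonotypes())

  surv$cdr3_key <- if (key_mode == "nt") surv$cdr3_nt else surv$cdr3
  # dominant contig per (barcode, chain): umis desc, reads desc, cdr3_nt asc
  ord <- order(surv$barcode, surv$chain,
               -surv$umis, -surv$reads, surv$cdr3_nt, method = "radix")
  surv <- surv[ord, , drop = FALSE]
  dominant <- surv[!duplicated(paste0(surv$barcode, "\r", surv$chain)), ,
                   drop = FALSE]

  tra <- dominant[dominant$chain == "TRA", , drop = FALSE]
  trb <- dominant[dominant$chain == "TRB", , drop = FALSE]
  paired <- intersect(tra$barcode, trb$barcode)
  if (length(paired) == 0L) return(empty_cell_clonotypes())
  tra <- tra[match(paired, tra$barcode), , drop = FALSE]
  trb <- trb[match(paired, trb$barcode), , drop = FALSE]

  md <- metadata[match(paired, metadata$barcode), , drop = FALSE]
  out <- data.frame(
    barcode = paired,
    patient = md$patient, timepoint = md$timepoint,
    response = md$response, subset = md$subset,
    tra_v = tra$v_gene, tra_j = tra$j_gene, tra_cdr3 = tra$cdr3_key,
    trb_v = trb$v_gene, trb_j = trb$j_gene, trb_cdr3 = trb$cdr3_key,
    stringsAsFactors = FALSE
  )
  out$clonotype_id <- clonotype_key(out)
  rownames(out) <- NULL
  out
}

empty_cell_clonotypes <- function() {
  data.frame(barcode = character(), patient = character(),
             timepoint = character(), response = character(),
             subset = character(), tra_v = character(), tra_j = character(),
             tra_cdr3 = character(), trb_v = character(), trb_j = character(),
             trb_cdr3 = character(), clonotype_id = character(),
             stringsAsFactors = FALSE)
}

clonotype_key <- function(df) {
  paste0(df$tra_v, "|", df$tra_j, "|", df$tra_cdr3, "+",
         df$trb_v, "|", df$trb_j, "|", df$trb_cdr3)
}

#' Build a per-specimen clone table
#'
#' Counts cells per clonotype for one specimen (one patient at one
#' timepoint). The copy number of a clonotype is the number of cells
#' carrying it, so copy numbers always sum to the specimen's retained cell
#' count.
#'
#' @param cells Cell-level clonotype assignments from [call_clonotypes()].
#' @param patient,timepoint Specimen identity; all `cells` must belong to it.
#' @return An integer vector of class `clone_table`, named by clonotype id,
#'   sorted by decreasing copy number (ties by id), with a `specimen`
#'   attribute `c(patient, timepoint)`.
#' @export
build_clone_table <- function(cells, patient, timepoint) {
  if (nrow(cells) > 0L) {
    if (!all(cells$patient == patient & cells$timepoint == timepoint))
      stop("cells from a different specimen than (", patient, ", ",
           timepoint, ")")
  }
  counts <- table(cells$clonotype_id)
  out <- setNames(as.integer(counts), names(counts))
  # stable order: copies desc, id asc
  if (length(out))
    out <- out[order(-out, names(out), method = "radix")]
  structure(out, specimen = c(patient = patient, timepoint = timepoint),
            class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  sp <- attr(x, "specimen")
  cat(sprintf("clone_table: %s / %s — %d clonotypes, %d cells\n",
              sp["patient"], sp["timepoint"], length(x), sum(x)))
  if (length(x)) {
    show <- head(x, 5L)
    for (i in seq_along(show))
      cat(sprintf("  %3d  %s\n", show[i], substr(names(show)[i], 1, 60)))
    if (length(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

# coerce clone_table / named vector / bare numeric to a copy-number vector
as_copies <- function(x) {
  if (inherits(x, "clone_table")) return(as.integer(unclass(x)))
  if (is.numeric(x)) {
    if (any(x < 0)) stop("copy numbers must be non-negative")
    return(x)
  }
  stop("expected a clone_table or numeric copy-number vector")
}

#' Write cell-level clonotype assignments or a clone table to TSV
#'
#' @param x A cell-clonotype `data.frame` or a `clone_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(x, path) {
  if (inherits(x, "clone_table")) {
    sp <- attr(x, "specimen")
    x <- data.frame(patient = sp["patient"], timepoint = sp["timepoint"],
                    clonotype_id = names(x), copies = as.integer(x),
                    row.names = NULL, stringsAsFactors = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
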