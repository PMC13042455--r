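#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: one set per line — name, description, then
#' gene names.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene names.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Read a sparse expression matrix in MatrixMarket triplet layout
#'
#' Reads the 10x-style trio: MatrixMarket `.mtx` counts plus plain-text
#' gene and barcode lists (one name per line, genes in rows).
#'
#' @param mtx,genes,barcodes File paths.
#' @return A `dgCMatrix` with gene rownames and barcode colnames.
#' @export
read_expression_mtx <- function(mtx, genes, barcodes) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  g <- readLines(genes); b <- readLines(barcodes)
  if (nrow(m) != length(g) || ncol(m) != length(b))
    stop(sprintf("matrix is %d x %d but %d genes / %d barcodes listed",
                 nrow(m), ncol(m), length(g), length(b)))
  dimnames(m) <- list(g, b)
  m
}

#' Per-cell gene-set activity as a recovery-curve AUC
#'
#' Rank-based activity score in the AUCell style. For each cell, genes are
#' ordered by decreasing expression (ties resolved by gene name for
#' determinism); the recovery curve counts cumulative gene-set hits along
#' the top `k = ceiling(top_fraction * n_genes)` ranks, and the score is
#' the area under that curve divided by the maximal area attained if all
#' set genes sat at the very top. Because only ranks are used, the score is
#' invariant to any monotone transform of a cell's expression values.
#'
#' @param expression Gene-by-cell matrix (dense or `dgCMatrix`) with gene
#'   rownames and cell colnames.
#' @param gene_set Character vector of gene names; must overlap the rows.
#' @param top_fraction Fraction of top-ranked genes forming the scoring
#'   window (default 0.05).
#' @return A `data.frame` with columns `cell`, `auc` (in `[0, 1]`), and the
#'   window size `threshold_rank`.
#' @export
aucell_score <- function(expression, gene_set, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  genes <- rownames(expression)
  if (is.null(genes)) stop("expression matrix must have gene rownames")
  hits <- genes %in% gene_set
  if (!any(hits)) {
    missing <- setdiff(gene_set, genes)
    stop("no gene-set genes found in the matrix; missing: ",
         paste(head(missing, 10), collapse = ", "))
  }
  n_genes <- length(genes)
  k <- as.integer(ceiling(top_fraction * n_genes))
  n_set <- sum(hits)
  # maximal recovery: all set genes at the very top of the ranking
  cmax <- sum(pmin(seq_len(k), n_set))
  dense <- as.matrix(expression)
  # deterministic tie-break: order by expression desc, then gene name asc
  name_rank <- order(genes)
  name_pos <- integer(n_genes); name_pos[name_rank] <- seq_len(n_genes)
  n_cells <- ncol(dense)
  auc <- numeric(n_cells)
  for (j in seq_len(n_cells)) {
    ord <- order(-dense[, j], name_pos, method = "radix")[seq_len(k)]
    auc[j] <- sum(cumsum(hits[ord])) / cmax
  }
  data.frame(cell = colnames(dense) %||% as.character(seq_len(n_cells)),
             auc = auc, threshold_rank = k, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-score-normalised group means of per-cell scores
#'
#' Averages per-cell AUC scores within groups, then z-scores the group
#' means across groups (sample standard deviation). With a single group the
#' mean is returned and the z flagged undefined (`NA`).
#'
#' @param scores Output of [aucell_score()] (or any data.frame with `cell`
#'   and `auc`).
#' @param grouping Named character vector mapping cell -> group label.
#' @return A `data.frame` with `group`, `mean_auc`, `z_mean`, `n_cells`.
#' @export
zscore_group_means <- function(scores, grouping) {
  g <- grouping[scores$cell]
  if (anyNA(g)) stop("grouping is missing ",
                     sum(is.na(g)), " of the scored cells")
  means <- tapply(scores$auc, g, mean)
  n <- tapply(scores$auc, g, length)
  z <- if (length(means) >= 2L) {
    s <- sd(means)
    if (s == 0) rep(0, length(means)) else (means - mean(means)) / s
  } else rep(NA_real_, length(means))
  data.frame(group = names(means), mean_auc = as.numeric(means),
             z_mean = as.numeric(z), n_cells = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided unpaired (Welch) t-test between two cell groups' scores
#'
#' Compares per-cell AUC scores between two groups with a Welch two-sample
#' t-test and attaches the figure-legend significance tier
#' (`****` < 1e-4, `***` < 1e-3, `**` < 0.01, `*` < 0.05, else `ns`).
#' When both groups are constant with equal means the comparison is
#' degenerate and `p = 1` is returned by convention.
#'
#' @param scores Output of [aucell_score()].
#' @param grouping Named character vector mapping cell -> group label.
#' @param groups Length-2 character vector naming the groups to compare
#'   (difference is `groups[1] - groups[2]`).
#' @return A list: `statistic`, `p_value`, `tier`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(scores, grouping, groups) {
  if (length(groups) != 2L) stop("exactly two group labels required")
  g <- grouping[scores$cell]
  a <- scores$auc[!is.na(g) & g == groups[1]]
  b <- scores$auc[!is.na(g) & g == groups[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 cells")
  if (sd(a) == 0 && sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    stat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    p <- tt$p.value
    stat <- unname(tt$statistic)
  }
  tier <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(statistic = stat, p_value = p, tier = tier,
       mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' PDCD1 positive/negative cell grouping
#'
#' Stratifies cells by PDCD1 (PD-1) expression: positive when the count is
#' greater than zero, negative when exactly zero.
#'
#' @param expression Gene-by-cell matrix containing a `PDCD1` row (or the
#'   row named by `gene`).
#' @param gene Marker gene name (default `"PDCD1"`).
#' @return Named character vector (`"PDCD1_pos"` / `"PDCD1_neg"`) keyed by
#'   cell barcode.
#' @export
pdcd1_groups <- function(expression, gene = "PDCD1") {
  if (!gene %in% rownames(expression))
    stop("gene not found in the matrix: ", gene)
  x <- as.numeric(expression[gene, ])
  setNames(ifelse(x > 0, paste0(gene, "_pos"), paste0(gene, "_neg")),
           colnames(expression))
}

#' Clone-size cell grouping (expanded vs novel nonexpanded)
#'
#' Stratifies cells by their clone's specimen-level copy number: `expanded`
#' when the copy number exceeds `expanded_min` (default 2, i.e. copy number
#' > 2) and `nonexpanded` when it is exactly 1; cells at intermediate copy
#' numbers get `NA` and are excluded from grouped comparisons.
#'
#' @param cells Cell-level clonotype assignments for one specimen.
#' @param table `clone_table` of the same specimen.
#' @param expanded_min Copy number strictly above which a clone counts as
#'   expanded.
#' @return Named character vector keyed by barcode.
#' @export
clone_size_groups <- function(cells, table, expanded_min = 2L) {
  copies <- unclass(table)[cells$clonotype_id]
  grp <- rep(NA_character_, nrow(cells))
  grp[!is.na(copies) & copies > expanded_min] <- "expanded"
  grp[!is.na(copies) & copies == 1L] <- "nonexpanded"
  setNames(grp, cells$barcode)
}
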