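#' Repertoire richness
#'
#' Number of unique clonotypes in a repertoire.
#'
#' @param x A `clone_table` or numeric vector of clone copy numbers.
#' @return Integer richness; 0 for an empty repertoire.
#' @export
clonotype_richness <- function(x) {
  length(as_copies(x))
}

#' Repertoire clonality (1 minus Pielou's evenness)
#'
#' Clonality is `1 - H / log(N)` where `H = -sum(p_i log p_i)` is the
#' Shannon entropy of the clone frequencies `p_i = copies_i / total cells`
#' and `N` is the richness. The logarithm base cancels between numerator and
#' denominator, so the result is base-independent. A repertoire where every
#' clone has one cell gives 0 (perfectly even); a single dominant clone
#' drives the value towards 1.
#'
#' @param x A `clone_table` or numeric vector of clone copy numbers.
#' @param base Logarithm base (default natural log); result is invariant.
#' @param singleton For a repertoire with a single clonotype `H/log(1)` is
#'   0/0; `"zero"` (default) returns 0 (trivially even), `"na"` returns
#'   `NA_real_`.
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(x, base = exp(1), singleton = c("zero", "na")) {
  singleton <- match.arg(singleton)
  copies <- as_copies(x)
  copies <- copies[copies > 0]
  n <- length(copies)
  if (n == 0L) stop("clonality is undefined for an empty repertoire")
  if (n == 1L) return(if (singleton == "zero") 0 else NA_real_)
  p <- copies / sum(copies)
  h <- -sum(p * log(p, base = base))
  1 - h / log(n, base = base)
}

#' Gini coefficient of clone frequencies
#'
#' Mean absolute difference of clone frequencies normalised by twice the
#' mean: `sum_ij |p_i - p_j| / (2 N^2 pbar)`. Measures inequality of clone
#' sizes independently of richness: 0 for a perfectly even repertoire,
#' approaching `1 - 1/N` when one clone holds all cells.
#'
#' @param x A `clone_table` or numeric vector of clone copy numbers.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_coefficient <- function(x) {
  copies <- as_copies(x)
  copies <- copies[copies > 0]
  n <- length(copies)
  if (n == 0L) stop("gini coefficient is undefined for an empty repertoire")
  if (n == 1L) return(0)
  p <- sort(copies / sum(copies))
  # sum_ij |p_i - p_j| = 2 * sum_i (2i - n - 1) p_(i) for sorted p
  mad_sum <- 2 * sum((2 * seq_len(n) - n - 1) * p)
  mad_sum / (2 * n^2 * mean(p))
}

#' Copy-number spectrum of a repertoire
#'
#' Bins clonotypes by copy number. The default bins separate nonexpanded
#' clones (copy number 1), moderately expanded (2-10), highly expanded
#' (11-50) and hyperexpanded (>50) clones. Reports clonotype counts per bin
#' and the cell-weighted proportion of the repertoire each bin occupies.
#'
#' @param x A `clone_table` or numeric vector of clone copy numbers.
#' @param bin_edges Strictly increasing integer lower edges of the bins; the
#'   last bin is open-ended. Default `c(1, 2, 11, 51)`.
#' @return A `data.frame` with columns `bin` (label), `lower`, `upper`,
#'   `n_clonotypes`, `n_cells`, `proportion_cells`.
#' @export
copy_number_spectrum <- function(x, bin_edges = c(1L, 2L, 11L, 51L)) {
  copies <- as_copies(x)
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  lower <- as.integer(bin_edges)
  upper <- c(lower[-1] - 1L, NA_integer_)  # NA = open-ended
  labels <- ifelse(is.na(upper), paste0(">", lower - 1L),
                   ifelse(lower == upper, as.character(lower),
                          paste0(lower, "-", upper)))
  if (length(copies) && any(copies < lower[1]))
    stop("copy number below the smallest bin edge")
  idx <- findInterval(copies, lower)
  n_clo <- tabulate(idx, nbins = length(lower))
  n_cells <- vapply(seq_along(lower),
                    function(b) sum(copies[idx == b]), numeric(1))
  total <- sum(copies)
  data.frame(bin = labels, lower = lower, upper = upper,
             n_clonotypes = n_clo, n_cells = as.integer(n_cells),
             proportion_cells = if (total > 0) n_cells / total else
               rep(0, length(lower)),
             stringsAsFactors = FALSE)
}

#' Per-stratum repertoire summary table
#'
#' Computes richness, clonality, Gini coefficient and cell counts for
#' repertoires stratified by any combination of metadata columns (patient,
#' timepoint, response, subset). Strata may pool patients within a
#' response-by-timepoint group (default) or be kept per patient.
#'
#' @param cells Cell-level clonotype assignments from [call_clonotypes()].
#' @param by Character vector of stratifying columns among `patient`,
#'   `timepoint`, `response`, `subset`. Default `c("response", "timepoint")`
#'   pools patients within each response group.
#' @param min_clonotypes Strata with fewer clonotypes than this are flagged
#'   `low_confidence = TRUE` in the output (default 3).
#' @return A `data.frame` with one row per stratum: the stratifying columns
#'   plus `richness`, `clonality`, `gini`, `total_cells`, `low_confidence`.
#' @export
repertoire_summary <- function(cells, by = c("response", "timepoint"),
                               min_clonotypes = 3L) {
  bad <- setdiff(by, c("patient", "timepoint", "response", "subset"))
  if (length(bad)) stop("unknown stratifier(s): ", paste(bad, collapse = ", "))
  if (nrow(cells) == 0L)
    return(data.frame(matrix(nrow = 0, ncol = length(by) + 5,
                             dimnames = list(NULL, c(by, "richness",
                               "clonality", "gini", "total_cells",
                               "low_confidence")))))
  key <- interaction(cells[by], drop = TRUE, sep = "\r", lex.order = TRUE)
  groups <- split(cells$clonotype_id, key)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    copies <- as.integer(table(ids))
    labels <- strsplit(g, "\r", fixed = TRUE)[[1]]
    df <- as.data.frame(as.list(setNames(labels, by)),
                        stringsAsFactors = FALSE)
    df$richness <- length(copies)
    df$clonality <- clonality(copies)
    df$gini <- gini_coefficient(copies)
    df$total_cells <- sum(copies)
    df$low_confidence <- length(copies) < min_clonotypes
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
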