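#' Per-specimen T-cell fraction and its pre-to-post change
#'
#' Computes, per specimen, the fraction of T cells among nonmalignant cells
#' and among all cells, then the post-minus-pre difference per patient.
#' Specimens with fewer than `min_t_cells` T cells are excluded (and listed
#' in the `excluded` attribute) to avoid imprecise proportion estimates.
#'
#' @param cell_annotations A `data.frame` with one row per cell and columns
#'   `patient`, `timepoint`, `major_type` (label containing the value of
#'   `t_label` for T cells) and logical `malignant`.
#' @param min_t_cells Minimum T cells for a specimen to be kept (default 20).
#' @param t_label Value of `major_type` identifying T cells.
#' @return A `data.frame` with one row per retained specimen: `patient`,
#'   `timepoint`, `n_t_cells`, `t_fraction_nonmalignant`, `t_fraction_all`,
#'   and per patient the post-minus-pre `delta_nonmalignant` / `delta_all`
#'   (`NA` when the partner timepoint is missing or excluded). Excluded
#'   specimens are recorded in `attr(, "excluded")`.
#' @export
composition_change <- function(cell_annotations, min_t_cells = 20L,
                               t_label = "T cell") {
  required <- c("patient", "timepoint", "major_type", "malignant")
  missing_cols <- setdiff(required, names(cell_annotations))
  if (length(missing_cols))
    stop("cell annotations missing column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste0(cell_annotations$patient, "\r", cell_annotations$timepoint)
  specs <- split(cell_annotations, key)
  rows <- lapply(specs, function(sp) {
    is_t <- sp$major_type == t_label
    data.frame(patient = sp$patient[1], timepoint = sp$timepoint[1],
               n_t_cells = sum(is_t),
               t_fraction_nonmalignant = sum(is_t & !sp$malignant) /
                 max(1L, sum(!sp$malignant)),
               t_fraction_all = sum(is_t) / nrow(sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excluded <- out[out$n_t_cells < min_t_cells, c("patient", "timepoint",
                                                 "n_t_cells")]
  out <- out[out$n_t_cells >= min_t_cells, , drop = FALSE]
  delta_of <- function(p, col) {
    pre <- out[[col]][out$patient == p & out$timepoint == "pre"]
    post <- out[[col]][out$patient == p & out$timepoint == "post"]
    if (length(pre) == 1L && length(post) == 1L) post - pre else NA_real_
  }
  out$delta_nonmalignant <- vapply(out$patient, delta_of, numeric(1),
                                   col = "t_fraction_nonmalignant")
  out$delta_all <- vapply(out$patient, delta_of, numeric(1),
                          col = "t_fraction_all")
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Ro/e: observed over expected cell counts per subset and condition
#'
#' For a subset-by-condition contingency table of cell counts, computes the
#' chi-square expected counts under independence,
#' `E_ij = rowsum_i * colsum_j / total`, and the enrichment ratio
#' `Ro/e_ij = O_ij / E_ij`. A ratio above 1 indicates that the subset is
#' observed in that condition more often than expected from the margins,
#' i.e. a condition preference.
#'
#' @param counts Non-negative integer matrix (subsets in rows, conditions —
#'   typically response group by timepoint — in columns), with dimnames.
#' @return A list of class `roe_matrix` with elements `observed`,
#'   `expected` and `roe` (all matrices; `roe` is `NA` where the expected
#'   count is 0).
#' @export
roe <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop("all-zero contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / total
  ratio <- counts / expected
  ratio[expected == 0] <- NA_real_
  structure(list(observed = counts, expected = expected, roe = ratio),
            class = "roe_matrix")
}

#' @export
print.roe_matrix <- function(x, digits = 3, ...) {
  cat("Ro/e (observed / chi-square expected cell counts)\n")
  print(round(x$roe, digits))
  invisible(x)
}

#' Long-format Ro/e table, with an interpretive post-minus-pre column
#'
#' Flattens a [roe()] result to one row per subset-condition cell. When the
#' condition labels encode `response.timepoint` pairs (the default layout
#' produced by [roe_from_cells()]), a `roe_delta` column with
#' `roe[post] - roe[pre]` per response group can be attached; the difference
#' of two ratios is interpretive, not a calibrated statistic.
#'
#' @param x A `roe_matrix`.
#' @return A `data.frame` with `subset`, `condition`, `observed`,
#'   `expected`, `roe`.
#' @export
as.data.frame.roe_matrix <- function(x, ...) {
  data.frame(subset = rep(rownames(x$observed), ncol(x$observed)),
             condition = rep(colnames(x$observed),
                             each = nrow(x$observed)),
             observed = as.vector(x$observed),
             expected = as.vector(x$expected),
             roe = as.vector(x$roe),
             stringsAsFactors = FALSE)
}

#' Subset-by-condition Ro/e from cell annotations
#'
#' Convenience wrapper: cross-tabulates cells by subset and by a condition
#' label (response group by timepoint, pooling patients, by default, or per
#' patient) and applies [roe()].
#'
#' @param cells Cell-level table with `subset`, `response`, `timepoint`
#'   (and `patient`) columns, e.g. from [call_clonotypes()].
#' @param condition Columns pasted (with `"_"`) into the condition label.
#' @return A `roe_matrix`.
#' @export
roe_from_cells <- function(cells, condition = c("response", "timepoint")) {
  bad <- setdiff(condition, names(cells))
  if (length(bad)) stop("unknown condition column(s): ",
                        paste(bad, collapse = ", "))
  cond <- do.call(paste, c(cells[condition], sep = "_"))
  roe(table(cells$subset, cond))
}
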