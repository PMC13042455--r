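#' Clonotypes shared between two T-cell subsets
#'
#' Intersection of the clonotype sets carried by two subsets within a pool
#' of cells (typically one response-by-timepoint group). Symmetric in its
#' subset arguments.
#'
#' @param cells Cell-level clonotype assignments.
#' @param subset_a,subset_b Subset labels; both must occur in `cells`.
#' @return A list with `shared_count` and the character vector `clonotypes`.
#' @export
shared_clonotypes <- function(cells, subset_a, subset_b) {
  for (s in c(subset_a, subset_b))
    if (!s %in% cells$subset) stop("unknown subset label: ", s)
  a <- unique(cells$clonotype_id[cells$subset == subset_a])
  b <- unique(cells$clonotype_id[cells$subset == subset_b])
  shared <- sort(intersect(a, b))
  list(shared_count = length(shared), clonotypes = shared)
}

#' Permutation significance of inter-subset clonal sharing
#'
#' Tests whether two subsets share more clonotypes than expected if subset
#' labels were exchangeable across cells. The null shuffles the subset
#' labels over all cells in the pool (preserving every subset's size and
#' the clone structure) and recounts shared clonotypes each time;
#' `p = (1 + #permutations >= observed) / (1 + n_permutations)`, so the
#' attainable minimum is `1/(n_permutations + 1)`. A secondary descriptive
#' statistic, the Spearman rank correlation of the shared clonotypes'
#' cell counts in the two subsets, is reported alongside (NA with fewer
#' than 3 shared clonotypes).
#'
#' @param cells Cell-level clonotype assignments (the pool to permute
#'   within, e.g. one response-by-timepoint group).
#' @param subset_a,subset_b Subset labels, both non-empty in `cells`.
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Integer seed; the result is deterministic given it.
#' @return A list of class `sharing_result`: `subset_a`, `subset_b`,
#'   `shared_count`, `clonotypes`, `p_value`, `rank_correlation`,
#'   `n_permutations`, `seed`.
#' @export
sharing_significance <- function(cells, subset_a, subset_b,
                                 n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 100L) stop("n_permutations must be at least 100")
  for (s in c(subset_a, subset_b))
    if (sum(cells$subset == s) == 0L) stop("subset has no cells: ", s)
  obs <- shared_clonotypes(cells, subset_a, subset_b)

  clone_id <- match(cells$clonotype_id, unique(cells$clonotype_id))
  k <- max(clone_id)
  in_a <- cells$subset == subset_a
  in_b <- cells$subset == subset_b
  n_a <- sum(in_a); n_b <- sum(in_b)
  # restrict the shuffle to the two subsets' cells: label exchange among the
  # pool's other subsets cannot change the a/b intersection
  pool <- which(in_a | in_b)
  cl_pool <- clone_id[pool]
  # canonical draw size so the result is exactly symmetric in (a, b)
  n_take <- if (subset_a <= subset_b) n_a else n_b
  null_counts <- integer(n_permutations)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(length(pool), n_take)
    ta <- tabulate(cl_pool[idx], nbins = k)
    tb <- tabulate(cl_pool[-idx], nbins = k)
    null_counts[i] <- sum(ta > 0L & tb > 0L)
  }
  p <- (1 + sum(null_counts >= obs$shared_count)) / (1 + n_permutations)

  rank_cor <- NA_real_
  if (obs$shared_count >= 3L) {
    fa <- tabulate(clone_id[in_a], nbins = k)
    fb <- tabulate(clone_id[in_b], nbins = k)
    sh <- match(obs$clonotypes, unique(cells$clonotype_id))
    rank_cor <- suppressWarnings(
      stats::cor(fa[sh], fb[sh], method = "spearman"))
  }
  structure(list(subset_a = subset_a, subset_b = subset_b,
                 shared_count = obs$shared_count,
                 clonotypes = obs$clonotypes,
                 p_value = p, rank_correlation = rank_cor,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "sharing_result")
}

#' @export
print.sharing_result <- function(x, ...) {
  cat(sprintf("clonal sharing %s ~ %s: %d shared clonotypes, p = %.4g (%d permutations, seed %d)\n",
              x$subset_a, x$subset_b, x$shared_count, x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}

#' Pairwise sharing table across all subsets of a pool
#'
#' Runs [sharing_significance()] for every unordered pair of subsets with at
#' least `min_cells` cells each.
#'
#' @param cells Cell pool to analyse.
#' @param n_permutations,seed Passed to [sharing_significance()]; the seed
#'   is advanced per pair for independent permutation streams.
#' @param min_cells Minimum cells per subset to consider (default 2).
#' @return A long-format `data.frame`: `subset_a`, `subset_b`,
#'   `shared_count`, `p_value`, `rank_correlation`, `n_permutations`, `seed`.
#' @export
sharing_table <- function(cells, n_permutations = 1000L, seed = 1L,
                          min_cells = 2L) {
  sizes <- table(cells$subset)
  subs <- sort(names(sizes)[sizes >= min_cells])
  if (length(subs) < 2L)
    return(data.frame(subset_a = character(), subset_b = character(),
                      shared_count = integer(), p_value = numeric(),
                      rank_correlation = numeric(),
                      n_permutations = integer(), seed = integer()))
  pairs <- utils::combn(subs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    r <- sharing_significance(cells, pairs[1, j], pairs[2, j],
                              n_permutations = n_permutations,
                              seed = seed + j - 1L)
    data.frame(subset_a = r$subset_a, subset_b = r$subset_b,
               shared_count = r$shared_count, p_value = r$p_value,
               rank_correlation = r$rank_correlation,
               n_permutations = r$n_permutations, seed = r$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
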