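#' Match clonotypes across the pre- and post-treatment repertoires
#'
#' Takes the union of clonotypes across a patient's two specimens, filling
#' zero for the timepoint where a clonotype is absent, and classifies each
#' clone's expansion behaviour with [classify_expansion()]. Copy totals are
#' preserved: the `pre_copies` column sums to the pre-treatment cell count
#' and `post_copies` to the post-treatment cell count.
#'
#' @param pre,post `clone_table` objects for the same patient at the `pre`
#'   and `post` timepoints.
#' @return A `data.frame` of class `paired_clones`, one row per clonotype in
#'   the union: `clonotype_id`, `patient`, `pre_copies`, `post_copies`,
#'   `expansion_class`, `lost` (pre >= 1 and post == 0 — a contracted clone,
#'   a subset of class `other` tagged for interpretability).
#' @export
pair_repertoires <- function(pre, post) {
  sp_pre <- attr(pre, "specimen"); sp_post <- attr(post, "specimen")
  if (is.null(sp_pre) || is.null(sp_post))
    stop("pair_repertoires expects clone_table inputs")
  if (sp_pre[["patient"]] != sp_post[["patient"]])
    stop("clone tables come from different patients: ",
         sp_pre[["patient"]], " vs ", sp_post[["patient"]])
  if (sp_pre[["timepoint"]] != "pre" || sp_post[["timepoint"]] != "post")
    stop("arguments must be the pre- and post-treatment tables, in order")
  ids <- union(names(pre), names(post))
  pre_c <- unclass(pre)[ids];  pre_c[is.na(pre_c)] <- 0L
  post_c <- unclass(post)[ids]; post_c[is.na(post_c)] <- 0L
  out <- data.frame(clonotype_id = ids,
                    patient = sp_pre[["patient"]],
                    pre_copies = as.integer(pre_c),
                    post_copies = as.integer(post_c),
                    stringsAsFactors = FALSE)
  out$expansion_class <- classify_expansion(out$pre_copies, out$post_copies)
  out$lost <- out$pre_copies >= 1L & out$post_copies == 0L
  rownames(out) <- NULL
  class(out) <- c("paired_clones", "data.frame")
  out
}

#' Classify a clone's pre/post expansion behaviour
#'
#' Deterministic partition of `(pre, post)` copy numbers into four classes:
#' \describe{
#'   \item{novel_expanded}{absent before treatment, expanded after:
#'     `pre == 0, post >= 2`}
#'   \item{persistent_expanded}{present before and further expanded after:
#'     `pre >= 1, post >= 2, post > pre`}
#'   \item{novel_nonexpanded}{newly detected at one copy:
#'     `pre == 0, post == 1`}
#'   \item{other}{everything else, including contracted and lost clones}
#' }
#' The classes are mutually exclusive and exhaustive over all pairs with
#' `pre + post >= 1`.
#'
#' @param pre,post Non-negative integer copy-number vectors (recycled).
#' @return Character vector of class labels.
#' @export
classify_expansion <- function(pre, post) {
  if (length(pre) != length(post)) {
    n <- max(length(pre), length(post))
    pre <- rep_len(pre, n); post <- rep_len(post, n)
  }
  if (any(pre < 0 | post < 0)) stop("copy numbers must be non-negative")
  if (any(pre + post == 0)) stop("a clone must have at least one cell")
  ifelse(pre == 0L & post >= 2L, "novel_expanded",
    ifelse(pre >= 1L & post >= 2L & post > pre, "persistent_expanded",
      ifelse(pre == 0L & post == 1L, "novel_nonexpanded", "other")))
}

#' Project specimen-level expansion classes onto a T-cell subset
#'
#' Expansion classes are assigned at the whole-specimen level by
#' [pair_repertoires()]; this projects them onto one subset's
#' post-treatment cells. Every post-treatment cell of the subset contributes
#' to the class of its clone, so a clone spanning two subsets keeps a single
#' class but is counted in each subset it occupies.
#'
#' @param paired A `paired_clones` table for the patient.
#' @param cells Cell-level clonotype assignments (post-treatment cells of
#'   the same patient; other rows are ignored).
#' @param subset Subset label to profile.
#' @return A `data.frame` with one row per expansion class: `subset`,
#'   `expansion_class`, `n_cells`, `n_clonotypes`, `mean_post_copies`
#'   (specimen-level mean post copy number of the clones observed in the
#'   subset; `NaN` when the class is absent).
#' @export
subset_expansion_profile <- function(paired, cells, subset) {
  if (!subset %in% cells$subset)
    stop("unknown subset label: ", subset)
  post_cells <- cells[cells$timepoint == "post" & cells$subset == subset &
                        cells$patient == paired$patient[1], , drop = FALSE]
  cls <- paired$expansion_class[match(post_cells$clonotype_id,
                                      paired$clonotype_id)]
  if (anyNA(cls))
    stop("post-treatment cells carry clonotypes absent from the paired table")
  out <- data.frame(subset = subset, expansion_class = EXPANSION_CLASSES,
                    stringsAsFactors = FALSE)
  out$n_cells <- vapply(EXPANSION_CLASSES,
                        function(k) sum(cls == k), integer(1))
  out$n_clonotypes <- vapply(EXPANSION_CLASSES, function(k)
    length(unique(post_cells$clonotype_id[cls == k])), integer(1))
  out$mean_post_copies <- vapply(EXPANSION_CLASSES, function(k) {
    ids <- unique(post_cells$clonotype_id[cls == k])
    mean(paired$post_copies[match(ids, paired$clonotype_id)])
  }, numeric(1))
  rownames(out) <- NULL
  out
}
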