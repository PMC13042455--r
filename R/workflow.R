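#' Pipeline run configuration
#'
#' Collects the input paths and analysis parameters for [run_pipeline()].
#' All gap-filling defaults of the analysis (copy-number bin edges, minimum
#' T cells per specimen, AUC window, permutation count) surface here.
#'
#' @param contig_paths Named character vector of contig CSV paths; names are
#'   `patient_timepoint` specimen labels (e.g. `"P01_pre"`).
#' @param metadata_path Cell metadata TSV (see [read_cell_metadata()]).
#' @param expression_paths Optional named character vector with entries
#'   `mtx`, `genes`, `barcodes` for pathway scoring.
#' @param gmt_path Optional GMT file of gene sets to score.
#' @param key_mode Clonotype key on nucleotide (`"nt"`) or amino-acid
#'   (`"aa"`) CDR3.
#' @param min_t_cells Minimum T cells for a specimen to enter composition
#'   summaries (default 20).
#' @param bin_edges Copy-number spectrum bin lower edges.
#' @param top_fraction AUC scoring window (default 0.05).
#' @param n_permutations Permutations for the sharing test.
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(contig_paths, metadata_path,
                       expression_paths = NULL, gmt_path = NULL,
                       key_mode = "nt", min_t_cells = 20L,
                       bin_edges = c(1L, 2L, 11L, 51L),
                       top_fraction = 0.05, n_permutations = 1000L,
                       seed = 1L, out_dir = tempfile("clonedyn_run_")) {
  if (is.null(names(contig_paths)) || any(!nzchar(names(contig_paths))))
    stop("contig_paths must be named by patient_timepoint specimen labels")
  structure(list(contig_paths = contig_paths,
                 metadata_path = metadata_path,
                 expression_paths = expression_paths, gmt_path = gmt_path,
                 key_mode = key_mode, min_t_cells = as.integer(min_t_cells),
                 bin_edges = bin_edges, top_fraction = top_fraction,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_stage <- function(df, out_dir, name) {
  p <- file.path(out_dir, name)
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

#' Run the full repertoire-dynamics pipeline
#'
#' Executes the stages in order — clonotype calling, repertoire metrics,
#' paired expansion dynamics, subset enrichment (Ro/e), inter-subset clonal
#' sharing, and (when an expression matrix is configured) pathway scoring —
#' writing one tab-delimited table per stage plus a JSON run manifest with
#' the seed, parameters and md5 digests of all inputs and outputs. A stage
#' failure aborts with the stage name; completed outputs are retained next
#' to a `FAILED` marker naming the broken stage.
#'
#' @param config A [run_config()].
#' @return A list of class `run_bundle`: `out_dir`, `manifest` (also written
#'   to `manifest.json`), and the per-stage in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir <- config$out_dir
  stages <- character(0)
  outputs <- character(0)
  results <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  # -- clonotypes ------------------------------------------------------
  results$cells <- run_stage("clonotypes", function() {
    metadata <- read_cell_metadata(config$metadata_path)
    contigs <- do.call(rbind, lapply(config$contig_paths, read_contigs))
    cells <- call_clonotypes(contigs, metadata, key_mode = config$key_mode)
    outputs["cells"] <<- write_stage(cells, out_dir, "cell_clonotypes.tsv")
    cells
  })
  cells <- results$cells

  specimen_of <- paste0(cells$patient, "_", cells$timepoint)
  tables <- lapply(split(cells, specimen_of), function(cc)
    build_clone_table(cc, cc$patient[1], cc$timepoint[1]))

  # -- metrics ---------------------------------------------------------
  results$metrics <- run_stage("metrics", function() {
    pooled <- repertoire_summary(cells, by = c("response", "timepoint"))
    per_patient <- repertoire_summary(cells, by = c("patient", "timepoint"))
    per_subset <- repertoire_summary(cells,
      by = c("response", "timepoint", "subset"))
    spectra <- do.call(rbind, lapply(names(tables), function(sp) {
      s <- copy_number_spectrum(tables[[sp]], config$bin_edges)
      cbind(specimen = sp, s)
    }))
    outputs["metrics_pooled"] <<-
      write_stage(pooled, out_dir, "metrics_pooled.tsv")
    outputs["metrics_per_patient"] <<-
      write_stage(per_patient, out_dir, "metrics_per_patient.tsv")
    outputs["metrics_per_subset"] <<-
      write_stage(per_subset, out_dir, "metrics_per_subset.tsv")
    outputs["spectra"] <<- write_stage(spectra, out_dir, "copy_spectra.tsv")
    list(pooled = pooled, per_patient = per_patient,
         per_subset = per_subset, spectra = spectra)
  })

  # -- dynamics --------------------------------------------------------
  results$dynamics <- run_stage("dynamics", function() {
    paired_all <- list(); profiles <- list()
    for (p in unique(cells$patient)) {
      pre_k <- paste0(p, "_pre"); post_k <- paste0(p, "_post")
      if (!pre_k %in% names(tables) || !post_k %in% names(tables)) next
      paired <- pair_repertoires(tables[[pre_k]], tables[[post_k]])
      paired_all[[p]] <- paired
      post_cells <- cells[cells$patient == p & cells$timepoint == "post", ]
      profiles[[p]] <- do.call(rbind, lapply(
        sort(unique(post_cells$subset)), function(s)
          cbind(patient = p,
                subset_expansion_profile(paired, post_cells, s))))
    }
    paired_df <- do.call(rbind, lapply(paired_all, as.data.frame))
    rownames(paired_df) <- NULL
    profile_df <- do.call(rbind, profiles)
    rownames(profile_df) <- NULL
    outputs["paired_clones"] <<-
      write_stage(paired_df, out_dir, "paired_clones.tsv")
    outputs["subset_profiles"] <<-
      write_stage(profile_df, out_dir, "subset_expansion_profiles.tsv")
    list(paired = paired_all, profiles = profile_df)
  })

  # -- roe -------------------------------------------------------------
  results$roe <- run_stage("roe", function() {
    r <- roe_from_cells(cells)
    outputs["roe"] <<- write_stage(as.data.frame(r), out_dir, "roe.tsv")
    r
  })

  # -- sharing ---------------------------------------------------------
  results$sharing <- run_stage("sharing", function() {
    pools <- split(cells, paste0(cells$response, "_", cells$timepoint))
    tab <- do.call(rbind, lapply(names(pools), function(g)
      cbind(pool = g, sharing_table(pools[[g]],
                                    n_permutations = config$n_permutations,
                                    seed = config$seed))))
    rownames(tab) <- NULL
    outputs["sharing"] <<- write_stage(tab, out_dir, "clonal_sharing.tsv")
    tab
  })

  # -- scoring (optional) ----------------------------------------------
  if (!is.null(config$expression_paths) && !is.null(config$gmt_path)) {
    results$scores <- run_stage("scoring", function() {
      ep <- config$expression_paths
      m <- read_expression_mtx(ep[["mtx"]], ep[["genes"]], ep[["barcodes"]])
      sets <- read_gmt(config$gmt_path)
      grouping <- setNames(paste0(cells$response, "_", cells$timepoint),
                           cells$barcode)
      score_tab <- do.call(rbind, lapply(names(sets), function(s) {
        sc <- aucell_score(m, sets[[s]], config$top_fraction)
        cbind(gene_set = s, sc)
      }))
      summary_tab <- do.call(rbind, lapply(names(sets), function(s) {
        sc <- score_tab[score_tab$gene_set == s, ]
        keep <- sc$cell %in% names(grouping)
        cbind(gene_set = s, zscore_group_means(sc[keep, ], grouping))
      }))
      outputs["scores"] <<-
        write_stage(score_tab, out_dir, "pathway_scores.tsv")
      outputs["score_summary"] <<-
        write_stage(summary_tab, out_dir, "pathway_score_summary.tsv")
      list(scores = score_tab, summary = summary_tab)
    })
  } else {
    message("no expression matrix configured; pathway scoring skipped")
  }

  inputs <- c(config$contig_paths, metadata = config$metadata_path,
              config$expression_paths,
              if (!is.null(config$gmt_path)) c(gmt = config$gmt_path))
  manifest <- list(
    package = "clonedyn",
    version = as.character(utils::packageVersion("clonedyn")),
    seed = config$seed,
    parameters = list(key_mode = config$key_mode,
                      min_t_cells = config$min_t_cells,
                      bin_edges = config$bin_edges,
                      top_fraction = config$top_fraction,
                      n_permutations = config$n_permutations),
    stages = stages,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(out_dir = out_dir, manifest = manifest, results = results),
            class = "run_bundle")
}

#' Human-readable summary of a pipeline run
#'
#' Prints, per response-group and timepoint: richness, clonality and Gini
#' coefficient; the subsets with the most expanded post-treatment cells;
#' the top Ro/e subsets per condition; and the subset pairs sharing
#' clonotypes at p < `alpha`. Missing stages are listed rather than
#' summarised.
#'
#' @param bundle A `run_bundle` from [run_pipeline()].
#' @param alpha Significance cut for reported sharing pairs (default 0.05).
#' @param top_n Subsets/pairs to show per section (default 3).
#' @return The summary lines, invisibly (also printed).
#' @export
summarize_report <- function(bundle, alpha = 0.05, top_n = 3L) {
  lines <- character(0)
  say <- function(...) lines <<- c(lines, sprintf(...))
  present <- names(bundle$results)
  expected <- c("cells", "metrics", "dynamics", "roe", "sharing", "scores")
  say("clonedyn run: %d of %d stages present (%s)",
      length(present), length(expected), paste(present, collapse = ", "))
  missing <- setdiff(expected, present)
  if (length(missing)) say("absent stages: %s", paste(missing, collapse = ", "))

  if ("metrics" %in% present) {
    m <- bundle$results$metrics$pooled
    for (i in seq_len(nrow(m)))
      say("  %s/%s: richness %d, clonality %.3f, gini %.3f (%d cells)",
          m$response[i], m$timepoint[i], m$richness[i], m$clonality[i],
          m$gini[i], m$total_cells[i])
  }
  if ("dynamics" %in% present && nrow(bundle$results$dynamics$profiles)) {
    pr <- bundle$results$dynamics$profiles
    exp_cells <- pr[pr$expansion_class %in%
                      c("novel_expanded", "persistent_expanded"), ]
    agg <- stats::aggregate(n_cells ~ subset, exp_cells, sum)
    agg <- agg[order(-agg$n_cells), ]
    top <- head(agg, top_n)
    say("  top expanded subsets (post-treatment cells in expanded clones): %s",
        paste(sprintf("%s (%d)", top$subset, top$n_cells), collapse = ", "))
  }
  if ("roe" %in% present) {
    r <- as.data.frame(bundle$results$roe)
    r <- r[!is.na(r$roe), ]
    for (cond in sort(unique(r$condition))) {
      rc <- r[r$condition == cond, ]
      rc <- rc[order(-rc$roe), ]
      say("  top Ro/e in %s: %s", cond,
          paste(sprintf("%s (%.2f)", head(rc$subset, top_n),
                        head(rc$roe, top_n)), collapse = ", "))
    }
  }
  if ("sharing" %in% present && nrow(bundle$results$sharing)) {
    sh <- bundle$results$sharing
    sig <- sh[sh$p_value < alpha, ]
    say("  sharing pairs at p < %.2f: %d of %d tested", alpha,
        nrow(sig), nrow(sh))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
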