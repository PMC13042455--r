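small_config <- function(seed = 1L, n_cells = 400L, ...) {
  simulation_config(n_patients = c(PCR = 1L), n_cells = n_cells,
                    n_novel_expanded = 10L, n_persistent_expanded = 10L,
                    n_novel_nonexpanded = 30L, seed = seed, ...)
}

test_that("configuration validates its invariants", {
  expect_error(simulation_config(subsets = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(simulation_config(alpha = 1), "alpha")
  expect_error(simulation_config(n_patients = c(XX = 1L)), "response groups")
  expect_error(simulation_config(target_subsets = c(PCR = "zzz", MPR = "zzz",
                                                    nonMPR = "zzz")),
               "target subsets")
  expect_error(simulate_repertoire(small_config(n_cells = 30L)), "budget")
})

test_that("planted ground truth matches the configured clone counts exactly", {
  sim <- simulate_repertoire(small_config(seed = 5L))
  tr <- sim$ground_truth
  expect_equal(sum(tr$planted_class == "novel_expanded"), 10L)
  expect_equal(sum(tr$planted_class == "persistent_expanded"), 10L)
  expect_equal(sum(tr$planted_class == "novel_nonexpanded"), 30L)
  # planted copy numbers satisfy the class definitions by construction
  ne <- tr[tr$planted_class == "novel_expanded", ]
  expect_true(all(ne$pre_copies == 0L & ne$post_copies >= 2L))
  pe <- tr[tr$planted_class == "persistent_expanded", ]
  expect_true(all(pe$pre_copies >= 1L & pe$post_copies >= 2L &
                    pe$post_copies > pe$pre_copies))
  nn <- tr[tr$planted_class == "novel_nonexpanded", ]
  expect_true(all(nn$pre_copies == 0L & nn$post_copies == 1L))
  bg <- tr[tr$planted_class == "background", ]
  expect_true(all(bg$post_copies <= bg$pre_copies))
  # specimen budgets respected on both sides
  expect_equal(sum(tr$pre_copies), 400L)
  expect_equal(sum(tr$post_copies), 400L)
  expect_equal(nrow(sim$metadata), 800L)
})

test_that("a unit boost with no planted clones yields a null specimen pair", {
  cfg <- simulation_config(n_patients = c(PCR = 1L), n_cells = 400L,
                           boost = 1, n_novel_expanded = 0L,
                           n_persistent_expanded = 0L,
                           n_novel_nonexpanded = 0L, seed = 2L)
  sim <- simulate_repertoire(cfg)
  expect_true(all(sim$ground_truth$planted_class == "background"))
  # carry-forward without replacement: no background clone can expand
  md <- sim$metadata
  cells <- call_clonotypes(do.call(rbind, sim$contigs),
                           md[, c("barcode", "patient", "timepoint",
                                  "response", "subset")])
  pre <- build_clone_table(cells[cells$timepoint == "pre", ], "P01", "pre")
  post <- build_clone_table(cells[cells$timepoint == "post", ], "P01", "post")
  paired <- pair_repertoires(pre, post)
  expect_equal(sum(paired$expansion_class %in%
                     c("novel_expanded", "persistent_expanded")), 0L)
})

test_that("fixture bundles are byte-identical across reruns of one seed", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  sim1 <- simulate_repertoire(small_config(seed = 9L))
  sim2 <- simulate_repertoire(small_config(seed = 9L))
  sim3 <- simulate_repertoire(small_config(seed = 10L))
  p1 <- write_fixture_bundle(sim1, d1)
  p2 <- write_fixture_bundle(sim2, d2)
  p3 <- write_fixture_bundle(sim3, d3)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # a different seed changes the synthetic CDR3 sequences
  expect_false(identical(readLines(p1[["ground_truth"]]),
                         readLines(p3[["ground_truth"]])))
})

test_that("written bundles read back to the generated cell counts", {
  sim <- simulate_repertoire(small_config(seed = 4L))
  d <- tempfile()
  paths <- write_fixture_bundle(sim, d)
  md <- read_cell_metadata(paths[["metadata"]])
  expect_equal(nrow(md), nrow(sim$metadata))
  contigs <- do.call(rbind, lapply(paths[grep("^contigs_", names(paths))],
                                   read_contigs))
  expect_equal(nrow(contigs), 2L * nrow(sim$metadata))  # one TRA + TRB each
  cells <- call_clonotypes(contigs, md)
  expect_equal(nrow(cells), nrow(sim$metadata))  # all synthetic cells pass QC
  expect_setequal(unique(cells$clonotype_id), sim$ground_truth$clonotype_id)
})

test_that("expression simulation plants pathway activity and the PDCD1 marker", {
  md <- data.frame(barcode = sprintf("bc%03d", 1:60))
  boosted <- md$barcode[1:30]
  ex <- simulate_expression(md, n_genes = 200L, effect = 3,
                            boosted_cells = boosted,
                            pdcd1_positive = md$barcode[seq(1, 60, 2)],
                            seed = 8L)
  expect_equal(dim(ex$matrix), c(201L, 60L))
  expect_equal(lengths(ex$gene_sets), c(IL2_STAT5 = 30L, TGFB_SMAD = 30L))
  in_set <- rownames(ex$matrix) %in% unlist(ex$gene_sets)
  m <- as.matrix(ex$matrix)
  boosted_mean <- mean(m[in_set, md$barcode %in% boosted])
  other_mean <- mean(m[in_set, !md$barcode %in% boosted])
  expect_gt(boosted_mean, other_mean * 2)
  pd <- pdcd1_groups(ex$matrix)
  expect_equal(unname(pd[md$barcode[1]]), "PDCD1_pos")
  expect_equal(unname(pd[md$barcode[2]]), "PDCD1_neg")
  expect_error(simulate_expression(md, effect = -1), "non-negative")
  expect_error(simulate_expression(md, pathway_sizes = c(a = 0L)),
               "non-empty")
})
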