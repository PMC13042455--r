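ranked_matrix <- function(values, cells = "c1") {
  n <- length(values)
  matrix(rep(values, length(cells)), ncol = length(cells),
         dimnames = list(sprintf("g%02d", seq_len(n)), cells))
}

test_that("recovery-curve AUC reproduces the worked examples", {
  expr <- ranked_matrix(10:1)
  # single set gene at the top of a k = 5 window -> maximal recovery
  expect_equal(aucell_score(expr, "g01", 0.5)$auc, 1.0)
  # set entirely below the window -> zero
  expect_equal(aucell_score(expr, c("g09", "g10"), 0.5)$auc, 0.0)
  # set at ranks 1 and 4: c = 1,1,1,2,2 over cmax = 1,2,2,2,2
  expect_equal(aucell_score(expr, c("g01", "g04"), 0.5)$auc, 7 / 9)
  expect_equal(aucell_score(expr, c("g01", "g04"), 0.5)$threshold_rank, 5L)
  expect_error(aucell_score(expr, c("nope1", "nope2")), "nope1")
  expect_error(aucell_score(expr, "g01", 0), "top_fraction")
})

test_that("AUC is invariant to monotone transforms and monotone in rank", {
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rexp(300), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
    gene_set <- sample(rownames(m), 6)
    base <- aucell_score(m, gene_set, 0.2)$auc
    expect_equal(aucell_score(log1p(m), gene_set, 0.2)$auc, base)
    expect_equal(aucell_score(m^3, gene_set, 0.2)$auc, base)
    expect_equal(aucell_score(m * 100 + 7, gene_set, 0.2)$auc, base)
  }
  # promoting a set gene one rank never decreases the score
  expr <- ranked_matrix(10:1)
  for (r in 2:10) {
    lower <- aucell_score(expr, sprintf("g%02d", r), 0.5)$auc
    higher <- aucell_score(expr, sprintf("g%02d", r - 1), 0.5)$auc
    expect_gte(higher, lower)
  }
})

test_that("expression ties resolve deterministically by gene name", {
  m <- matrix(1, nrow = 4, ncol = 1,
              dimnames = list(c("gb", "ga", "gd", "gc"), "c1"))
  s1 <- aucell_score(m, "ga", 0.25)
  expect_equal(s1$auc, 1)   # alphabetically first gene wins the only slot
  s2 <- aucell_score(m, "gd", 0.25)
  expect_equal(s2$auc, 0)
})

test_that("group means are z-scored with the sample standard deviation", {
  sc <- data.frame(cell = letters[1:6], auc = c(1, 1, 2, 2, 3, 3))
  grouping <- setNames(rep(c("g1", "g2", "g3"), each = 2), letters[1:6])
  z <- zscore_group_means(sc, grouping)
  expect_equal(z$mean_auc, c(1, 2, 3))
  expect_equal(z$z_mean, c(-1, 0, 1))
  expect_equal(mean(z$z_mean), 0)
  expect_equal(sd(z$z_mean), 1)

  flat <- zscore_group_means(data.frame(cell = letters[1:4],
                                        auc = rep(0.5, 4)),
                             setNames(rep(c("g1", "g2"), 2), letters[1:4]))
  expect_equal(flat$z_mean, c(0, 0))

  two <- zscore_group_means(data.frame(cell = c("a", "b"), auc = c(0, 1)),
                            setNames(c("g1", "g2"), c("a", "b")))
  expect_equal(two$z_mean, c(-1, 1) / sqrt(2))  # symmetric two-point z

  one <- zscore_group_means(sc, setNames(rep("g", 6), letters[1:6]))
  expect_true(is.na(one$z_mean))
})

test_that("Welch comparison handles identical, shifted and degenerate groups", {
  grouping <- setNames(rep(c("x", "y"), each = 50), sprintf("c%03d", 1:100))
  sc_same <- data.frame(cell = names(grouping), auc = rep(c(0.2, 0.8), 50))
  sc_same$auc <- rep(sc_same$auc[1:50], 2)  # identical score vectors
  r <- compare_groups(sc_same, grouping, c("x", "y"))
  expect_equal(r$p_value, 1)
  expect_equal(r$tier, "ns")

  set.seed(6)
  sc_shift <- data.frame(cell = names(grouping),
                         auc = c(rnorm(50), rnorm(50, 2)))
  rs <- compare_groups(sc_shift, grouping, c("x", "y"))
  expect_lt(rs$p_value, 0.001)
  rswap <- compare_groups(sc_shift, grouping, c("y", "x"))
  expect_equal(rswap$p_value, rs$p_value)
  expect_equal(rswap$statistic, -rs$statistic)

  sc_const <- data.frame(cell = names(grouping), auc = rep(0.5, 100))
  expect_equal(compare_groups(sc_const, grouping, c("x", "y"))$p_value, 1)
})

test_that("PDCD1 and clone-size groupings implement the stated rules", {
  m <- matrix(c(0, 1, 3, 0), nrow = 1,
              dimnames = list("PDCD1", sprintf("c%d", 1:4)))
  g <- pdcd1_groups(m)
  expect_equal(unname(g), c("PDCD1_neg", "PDCD1_pos", "PDCD1_pos",
                            "PDCD1_neg"))
  expect_error(pdcd1_groups(m, gene = "CD8A"), "not found")

  cells <- make_cells(c("A", "A", "A", "B", "C", "C"), subset = "s")
  tab <- build_clone_table(cells, "P1", "post")
  grp <- clone_size_groups(cells, tab)
  expect_equal(unname(grp[cells$tra_cdr3 == "A"]), rep("expanded", 3))
  expect_equal(unname(grp[cells$tra_cdr3 == "B"]), "nonexpanded")
  expect_true(all(is.na(grp[cells$tra_cdr3 == "C"])))  # copy 2: excluded
})

test_that("GMT and MatrixMarket readers round-trip simulator output", {
  md <- data.frame(barcode = sprintf("bc%02d", 1:8))
  ex <- simulate_expression(md, n_genes = 40L,
                            pathway_sizes = c(S1 = 5L, S2 = 4L),
                            effect = 0, seed = 12L)
  d <- tempfile(); dir.create(d)
  sim <- structure(list(contigs = list(), metadata = md,
                        ground_truth = data.frame(), config = NULL),
                   class = "sim_bundle")
  paths <- write_fixture_bundle(sim, d, expression = ex)
  m <- read_expression_mtx(paths[["matrix"]], paths[["genes"]],
                           paths[["barcodes"]])
  expect_equal(dim(m), c(41L, 8L))  # 40 genes + PDCD1 marker row
  expect_equal(unname(as.matrix(m)), unname(as.matrix(ex$matrix)))
  sets <- read_gmt(paths[["gmt"]])
  expect_equal(lengths(sets), c(S1 = 5L, S2 = 4L))
  expect_identical(sets$S1, ex$gene_sets$S1)
  expect_error(read_expression_mtx(paths[["matrix"]], paths[["genes"]],
                                   paths[["genes"]]), "listed")
})
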