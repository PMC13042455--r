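test_that("contig parsing preserves rows and chain labels verbatim", {
  df <- rbind(contig_row("c1", "TRA"), contig_row("c1", "TRB"),
              contig_row("c2", "IGH"))
  got <- read_contigs(write_contig_csv(df))
  expect_equal(nrow(got), 3L)
  expect_equal(got$chain, c("TRA", "TRB", "IGH"))
  expect_type(got$umis, "integer")
  expect_type(got$productive, "logical")
})

test_that("contig parsing reports missing columns and bad values by position", {
  df <- contig_row("c1", "TRA")
  p <- write_contig_csv(df[, setdiff(names(df), "umis")])
  expect_error(read_contigs(p), "umis")

  df2 <- rbind(contig_row("c1", "TRA"), contig_row("c2", "TRB"))
  df2$umis <- c("4", "x")
  expect_error(read_contigs(write_contig_csv(df2)), "line 3")

  df3 <- contig_row("c1", "TRA")
  df3$productive <- "maybe"
  expect_error(read_contigs(write_contig_csv(df3)), "boolean")
})

test_that("alternative dialects remap column names and boolean tokens", {
  df <- contig_row("c1", "TRA")
  names(df)[names(df) == "umis"] <- "umi_count"
  df$is_cell <- "yes"
  p <- write_contig_csv(df)
  dial <- contig_dialect(columns = c(umis = "umi_count"),
                         true_tokens = c("True", "yes"))
  got <- read_contigs(p, dial)
  expect_equal(got$umis, 5L)
  expect_true(got$is_cell)
})

test_that("two-step QC retains only whitelisted cells with a productive full-length pair", {
  # c1 clean pair; c2 TRB only; c3 two productive TRAs (umis 5 vs 2) + TRB;
  # c4 nonproductive TRA + productive TRB
  contigs <- rbind(
    contig_row("c1", "TRA", cdr3_nt = "AAA"), contig_row("c1", "TRB"),
    contig_row("c2", "TRB"),
    contig_row("c3", "TRA", umis = 5L, cdr3_nt = "CCC"),
    contig_row("c3", "TRA", umis = 2L, cdr3_nt = "GGG"),
    contig_row("c3", "TRB"),
    contig_row("c4", "TRA", productive = FALSE), contig_row("c4", "TRB"))
  md <- make_metadata(c("c1", "c2", "c3", "c4"))
  got <- call_clonotypes(contigs, md)
  expect_setequal(got$barcode, c("c1", "c3"))
  expect_equal(got$tra_cdr3[got$barcode == "c3"], "CCC")
})

test_that("cells outside the metadata whitelist are dropped", {
  contigs <- rbind(contig_row("c1", "TRA"), contig_row("c1", "TRB"))
  got <- call_clonotypes(contigs, make_metadata("other_cell"))
  expect_equal(nrow(got), 0L)
})

test_that("dominance ties fall back to reads then lexicographic CDR3", {
  contigs <- rbind(
    contig_row("c1", "TRA", umis = 3L, reads = 10L, cdr3_nt = "TTT"),
    contig_row("c1", "TRA", umis = 3L, reads = 8L, cdr3_nt = "AAA"),
    contig_row("c1", "TRB"))
  got <- call_clonotypes(contigs, make_metadata("c1"))
  expect_equal(got$tra_cdr3, "TTT")
  # full tie on umis and reads: lexicographically smallest CDR3 wins
  contigs2 <- rbind(
    contig_row("c1", "TRA", umis = 3L, reads = 10L, cdr3_nt = "TTT"),
    contig_row("c1", "TRA", umis = 3L, reads = 10L, cdr3_nt = "AAA"),
    contig_row("c1", "TRB"))
  got2 <- call_clonotypes(contigs2, make_metadata("c1"))
  expect_equal(got2$tra_cdr3, "AAA")
})

test_that("amino-acid key mode groups distinct nucleotide CDR3s together", {
  contigs <- rbind(
    contig_row("c1", "TRA", cdr3_nt = "TGTGCA", cdr3 = "CA"),
    contig_row("c1", "TRB", cdr3_nt = "TGCGCA", cdr3 = "CA"),
    contig_row("c2", "TRA", cdr3_nt = "TGCGCC", cdr3 = "CA"),
    contig_row("c2", "TRB", cdr3_nt = "TGTGCC", cdr3 = "CA"))
  md <- make_metadata(c("c1", "c2"))
  expect_equal(length(unique(call_clonotypes(contigs, md, "nt")$clonotype_id)), 2L)
  expect_equal(length(unique(call_clonotypes(contigs, md, "aa")$clonotype_id)), 1L)
})

test_that("clone tables count cells per clonotype and preserve totals", {
  cells <- make_cells(c("A", "A", "A", "B", "C"), subset = "s")
  tab <- build_clone_table(cells, "P1", "post")
  expect_equal(sum(tab), 5L)
  expect_equal(length(tab), 3L)
  expect_equal(unname(tab[grepl("\\|A\\+", names(tab))]), 3L)

  empty <- build_clone_table(make_cells(character(0), character(0)),
                             "P1", "post")
  expect_equal(length(empty), 0L)

  # keys differing only in one CDR3 field are distinct clonotypes
  two <- make_cells(c("A", "A"), subset = "s")
  two$tra_cdr3 <- c("A", "B")
  two$clonotype_id <- paste0("TRAV1|TRAJ1|", two$tra_cdr3,
                             "+TRBV1|TRBJ1|A")
  expect_equal(length(build_clone_table(two, "P1", "post")), 2L)

  expect_error(build_clone_table(make_cells("A", "s", timepoint = "pre"),
                                 "P1", "post"), "specimen")
})

test_that("copy-number conservation and idempotence hold on generated inputs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    clones <- sample(LETTERS[1:10], n, replace = TRUE)
    contigs <- do.call(rbind, lapply(seq_len(n), function(i) rbind(
      contig_row(sprintf("b%03d", i), "TRA", cdr3_nt = clones[i],
                 umis = sample(1:6, 1)),
      contig_row(sprintf("b%03d", i), "TRB", cdr3_nt = clones[i],
                 umis = sample(1:6, 1)))))
    md <- make_metadata(sprintf("b%03d", seq_len(n)), timepoint = "post")
    cells <- call_clonotypes(contigs, md)
    expect_equal(nrow(cells), n)  # exactly one TRA and TRB selected per cell
    tab <- build_clone_table(cells, "P1", "post")
    expect_equal(sum(tab), n)
    # idempotence: re-calling on the dominant contigs reproduces assignments
    again <- call_clonotypes(contigs, md)
    expect_identical(again$clonotype_id, cells$clonotype_id)
  }
})

test_that("clonotype tables survive a TSV round trip", {
  cells <- make_cells(c("A", "B", "B"), subset = "s")
  p <- tempfile(fileext = ".tsv")
  write_clonotype_table(cells, p)
  back <- read.delim(p, colClasses = "character")
  expect_equal(nrow(back), 3L)
  tab <- build_clone_table(cells, "P1", "post")
  p2 <- tempfile(fileext = ".tsv")
  write_clonotype_table(tab, p2)
  back2 <- read.delim(p2)
  expect_equal(sum(back2$copies), 3L)
})
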