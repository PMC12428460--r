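# Domain types and tabular readers/writers.

test_that("gene_signature validates and upper-cases symbols", {
  sig <- gene_signature(c("pim1", "Chek1"))
  expect_equal(sig$genes, c("PIM1", "CHEK1"))
  expect_error(gene_signature(character()), class = "cerna_argument_error")
  expect_error(gene_signature(c("PIM1", "pim1")), class = "cerna_argument_error")
})

test_that("miRNA target reader parses, deduplicates and errors usefully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tTarget Gene\tEvidence",
               "hsa-miR-16-5p\tPIM1\tstrong",
               "hsa-miR-16-5p\tPIM1\tstrong",
               "hsa-miR-195-5p\tCHEK1\tstrong"), path)
  expect_message(tb <- read_mir_target_table(path), "1 duplicate")
  expect_equal(nrow(tb), 2)
  expect_equal(sort(tb$target_gene), c("CHEK1", "PIM1"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mirna_id\ttarget_gene", empty)
  expect_equal(nrow(read_mir_target_table(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "a\tb"), bad)
  expect_error(read_mir_target_table(bad), regexp = "miRNA",
               class = "cerna_format_error")
})

test_that("non-hsa miRNA ids are accepted with a warning", {
  expect_warning(mir_target_records("mmu-miR-1", "PIM1"),
                 class = "ceRNAfunnel_warning")
})

test_that("sponge tables parse p-value bounds and check integrity", {
  fx <- fixture_network()
  expect_equal(nrow(fx$sponges), 15)
  expect_equal(length(unique(fx$sponges$circ_id)), 7)
  # "<= 10^-6"-style cells become numeric bounds
  e <- fx$sponges[fx$sponges$circ_id == "hsa_circ_0024791", ]
  expect_equal(e$agoclip_p_bound, 1e-6)
  e2 <- fx$sponges[fx$sponges$circ_id == "hsa_circ_0076215" &
                     fx$sponges$mirna_id == "hsa-miR-16-5p", ]
  expect_equal(e2$agoclip_p_bound, 1e-12)

  # ascii spellings parse to the same bound
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("circ_id\tmirna_id\tn_sites\tp_value",
               "hsa_circ_0000001\thsa-miR-1-5p\t2\t<=10^-8",
               "hsa_circ_0000001\thsa-miR-2-5p\t1\t1e-4"), sp)
  an <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("circ_id\thost_gene\tchrom\tstart\tend",
               "hsa_circ_0000001\tPIM1\tchr6\t100\t900"), an)
  out <- read_sponge_tables(sp, an)
  expect_equal(out$sponges$agoclip_p_bound, c(1e-8, 1e-4))

  # an edge referencing an unannotated circRNA is a referential error
  writeLines(c("circ_id\tmirna_id\tn_sites\tp_value",
               "hsa_circ_0000002\thsa-miR-1-5p\t2\t1e-8"), sp)
  expect_error(read_sponge_tables(sp, an), regexp = "hsa_circ_0000002",
               class = "cerna_integrity_error")
})

test_that("BED-6 circRNA annotation is accepted", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr6\t100\t900\tcircA|PIM1\t0\t+",
               "chr11\t50\t800\tcircB|CHEK1\t0\t-"), bed)
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("circ_id\tmirna_id\tn_sites\tp_value",
               "circB\thsa-miR-1-5p\t2\t1e-8"), sp)
  out <- read_sponge_tables(sp, bed)
  expect_equal(nrow(out$circs), 2)
  expect_equal(out$circs$host_gene[2], "CHEK1")
  expect_equal(out$circs$end[1] - out$circs$start[1], 800)
})

test_that("circRNA size prefers spliced length when flagged", {
  circs <- circ_records("hsa_circ_0000009", "PIM1", "chr6", 0, 1000,
                        spliced_length = 400)
  expect_equal(unname(circ_size(circs)), 400)
  expect_equal(unname(circ_size(circs, use_spliced = FALSE)), 1000)
})

test_that("expression reader aligns samples and validates levels", {
  mat <- withr::local_tempfile(fileext = ".tsv")
  ann <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "PIM1\t8.1\t8.4\t9.9\t10.2",
               "NF2\t7.0\t7.2\t6.1\t6.0",
               "CHEK1\t5.5\t5.6\t5.9\t6.2"), mat)
  writeLines(c("sample_id\twho_grade\trecurrent\tmeng_subtype",
               "s3\t2\tyes\tC", "s1\t1\tno\tA", "s2\t1\tno\tB",
               "s4\t2\tyes\tC"), ann)
  ds <- read_expression_dataset(mat, ann)
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(colnames(ds), c("s3", "s1", "s2", "s4"))  # annotation order
  expect_equal(unname(expr_matrix(ds)["PIM1", "s3"]), 9.9)

  writeLines(c("sample_id\twho_grade\trecurrent",
               "s1\t3\tno"), ann)
  expect_error(read_expression_dataset(mat, ann), regexp = "who_grade",
               class = "cerna_format_error")

  writeLines(c("sample_id\twho_grade\trecurrent",
               "s1\t1\tno", "s9\t1\tno"), ann)
  expect_error(read_expression_dataset(mat, ann), regexp = "s9",
               class = "cerna_integrity_error")

  writeLines(c("gene\ts1", "PIM1\toops"), mat)
  writeLines(c("sample_id\twho_grade\trecurrent", "s1\t1\tno"), ann)
  expect_error(read_expression_dataset(mat, ann), regexp = "PIM1.*s1",
               class = "cerna_format_error")
})

test_that("Ct and RBP tables validate their invariants", {
  m <- rbind(GAPDH = c(a = 18, b = 19), PIM1 = c(22, NA))
  ct <- ct_table(m)
  expect_s3_class(ct, "ct_table")
  expect_error(ct_table(m, reference = "ACTB"), class = "cerna_argument_error")
  m2 <- m; m2["PIM1", 1] <- 50
  expect_error(ct_table(m2), class = "cerna_format_error")

  counts <- matrix(1:6, 3, 2, dimnames = list(paste0("c", 1:3), c("AGO1", "HUR")))
  expect_error(rbp_site_table(counts, c("candidate", "candidate", "candidate")),
               class = "cerna_argument_error")
  tb <- rbp_site_table(counts, c("candidate", "background", "background"))
  expect_s3_class(tb, "rbp_site_table")
})

test_that("tables round-trip through TSV bit-exactly for the values used", {
  set.seed(21)
  sp <- sponge_records(sprintf("hsa_circ_%07d", 1:6),
                       sprintf("hsa-miR-%d-5p", 1:6),
                       n_sites = sample(1:9, 6, replace = TRUE),
                       agoclip_p_bound = signif(runif(6, 1e-12, 1), 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(sp, path)
  an <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(circ_records(sp$circ_id, "PIM1", "chr6",
                               start = 1:6 * 10, end = 1:6 * 10 + 500), an)
  back <- read_sponge_tables(path, an)
  expect_identical(back$sponges$n_sites, sp$n_sites)
  expect_equal(back$sponges$agoclip_p_bound, sp$agoclip_p_bound,
               tolerance = 1e-12)
  # referential integrity holds after any successful read
  expect_true(all(back$sponges$circ_id %in% back$circs$circ_id))
})
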