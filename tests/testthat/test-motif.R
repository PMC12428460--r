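# Tripartite graph assembly, feed-forward-loop enumeration and the RBP
# enrichment screen.

test_that("tripartite graph has the expected node classes and edges", {
  fx <- fixture_network()
  sig2 <- gene_signature(c("CHEK1", "PIM1"))   # genes of the bundled network
  cand <- select_candidate_mirnas(fx$mir_targets, sig2, 1)
  g <- build_tripartite(cand, fx$sponges, fx$circs, fx$mir_targets, sig2)
  tt <- table(igraph::V(g)$type)
  expect_equal(as.integer(tt[c("circRNA", "miRNA", "gene")]), c(7L, 4L, 2L))

  # no edge joins two nodes of the same class
  el <- igraph::as_edgelist(g)
  type_of <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_true(all(type_of[el[, 1]] != type_of[el[, 2]]))

  # empty candidate set: gene nodes only
  empty_cand <- select_candidate_mirnas(
    mir_target_records(character(), character()), sig2, 1)
  g0 <- build_tripartite(empty_cand, fx$sponges, fx$circs, fx$mir_targets,
                         sig2)
  expect_equal(unique(igraph::V(g0)$type), "gene")

  # sponge edges to non-candidate miRNAs never enter the graph
  cand_16 <- select_candidate_mirnas(
    fx$mir_targets[fx$mir_targets$mirna_id == "hsa-miR-16-5p", ], sig2, 1)
  g16 <- build_tripartite(cand_16, fx$sponges, fx$circs, fx$mir_targets, sig2)
  expect_equal(sum(igraph::E(g16)$kind == "sponge"), 7)  # miR-16-5p edges only
})

test_that("feed-forward loops match the published network", {
  fx <- fixture_network()
  cand <- select_candidate_mirnas(fx$mir_targets, fx$signature, 1)
  g <- build_tripartite(cand, fx$sponges, fx$circs, fx$mir_targets,
                        fx$signature)
  m <- enumerate_ffl(g)
  expect_setequal(unique(m$target_gene), c("CHEK1", "PIM1"))
  # miR-16-5p forms motifs with all four circPIM1 isoforms
  m16 <- m[m$mirna_id == "hsa-miR-16-5p" & m$target_gene == "PIM1", ]
  expect_setequal(m16$circ_id, sprintf("hsa_circ_%07d", 76213:76216))
  # deterministic (circ_id, mirna_id) order
  expect_false(is.unsorted(m$circ_id))
})

test_that("a graph whose circRNA hosts are never targets yields no motif", {
  sig <- gene_signature(c("H1", "H2"))
  circs <- circ_records("hsa_circ_0000001", "H1", "chr1", 0, 100)
  sponges <- sponge_records("hsa_circ_0000001", "hsa-miR-a-5p", 2)
  targets <- mir_target_records("hsa-miR-a-5p", "H2")  # targets H2, not host
  cand <- select_candidate_mirnas(targets, sig, 1)
  g <- build_tripartite(cand, sponges, circs, targets, sig)
  expect_equal(nrow(enumerate_ffl(g)), 0)
})

test_that("enumeration equals the brute-force triple loop on random graphs", {
  for (seed in 1:30) {
    inst <- random_cerna_instance(seed)
    g <- build_tripartite(inst$candidates, inst$sponges, inst$circs,
                          inst$targets, inst$signature)
    mine <- enumerate_ffl(g)
    ref <- oracle_ffl(inst$candidates, inst$sponges, inst$circs,
                      inst$targets, inst$signature)
    expect_equal(nrow(mine), nrow(ref))
    expect_equal(paste(mine$circ_id, mine$mirna_id, mine$target_gene),
                 paste(ref$circ_id, ref$mirna_id, ref$target_gene))
  }
})

test_that("motif set is monotone in sponge and target edges", {
  inst <- random_cerna_instance(101)
  g <- build_tripartite(inst$candidates, inst$sponges, inst$circs,
                        inst$targets, inst$signature)
  base_keys <- with(enumerate_ffl(g), paste(circ_id, mirna_id))

  # adding a sponge edge can only add motifs
  add <- sponge_records(inst$circs$circ_id[1],
                        inst$candidates$candidates$mirna_id[1], 2)
  sp2 <- rbind(inst$sponges[, names(add)], add)
  sp2 <- sp2[!duplicated(sp2[, c("circ_id", "mirna_id")]), ]
  g2 <- build_tripartite(inst$candidates, sp2, inst$circs, inst$targets,
                         inst$signature)
  keys2 <- with(enumerate_ffl(g2), paste(circ_id, mirna_id))
  expect_true(all(base_keys %in% keys2))

  # removing a target record can only remove motifs
  if (nrow(inst$targets) > 1) {
    tg2 <- inst$targets[-1, ]
    cand2 <- select_candidate_mirnas(tg2, inst$signature, 1)
    g3 <- build_tripartite(cand2, inst$sponges, inst$circs, tg2,
                           inst$signature)
    keys3 <- with(enumerate_ffl(g3), paste(circ_id, mirna_id))
    expect_true(all(keys3 %in% base_keys))
  }
})

make_rbp_fixture <- function() {
  # 20 RBPs; 2 candidate vs 10 background circRNAs; background counts all 1;
  # one RBP fully separated with candidate counts of 11
  counts <- matrix(1L, nrow = 12, ncol = 20,
                   dimnames = list(c(paste0("cand", 1:2), paste0("bg", 1:10)),
                                   paste0("RBP", 1:20)))
  counts[1:2, "RBP7"] <- 11L
  rbp_site_table(counts, c(rep("candidate", 2), rep("background", 10)))
}

test_that("RBP screen flags only the separated RBP at FDR 10%", {
  enr <- rbp_enrichment(make_rbp_fixture(), fdr_level = 0.10)
  expect_equal(nrow(enr), 20)
  expect_equal(enr$rbp[enr$enriched], "RBP7")
  expect_true(all(enr$p_adjusted >= enr$p_value - 1e-15))
})

test_that("identical candidate and background counts are never enriched", {
  counts <- matrix(rep(c(0L, 2L, 5L, 1L), 12), nrow = 8, ncol = 6,
                   dimnames = list(paste0("c", 1:8), paste0("RBP", 1:6)))
  tb <- rbp_site_table(counts, c(rep("candidate", 4), rep("background", 4)))
  enr <- rbp_enrichment(tb, fdr_level = 0.5)
  expect_false(any(enr$enriched))
  # one-sided greater on identical samples can never go below 1/2
  expect_true(all(enr$p_value >= 0.5))
})

test_that("enriched set is nested as the FDR level decreases", {
  set.seed(77)
  counts <- matrix(rpois(15 * 12, 2), nrow = 15,
                   dimnames = list(paste0("c", 1:15), paste0("RBP", 1:12)))
  counts[1:3, 1:2] <- counts[1:3, 1:2] + 15   # two truly enriched RBPs
  tb <- rbp_site_table(counts, c(rep("candidate", 3), rep("background", 12)))
  sets <- lapply(c(0.20, 0.10, 0.05, 0.01), function(q) {
    enr <- rbp_enrichment(tb, fdr_level = q)
    enr$rbp[enr$enriched]
  })
  for (i in 2:length(sets)) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("all-zero RBPs are excluded with a warning", {
  counts <- cbind(A = c(1L, 3L, 0L, 1L), B = c(0L, 0L, 0L, 0L))
  rownames(counts) <- paste0("c", 1:4)
  tb <- rbp_site_table(counts, c("candidate", "candidate",
                                 "background", "background"))
  expect_warning(enr <- rbp_enrichment(tb), class = "ceRNAfunnel_warning")
  expect_equal(enr$rbp, "A")
})

test_that("background sampling respects the size window", {
  set.seed(5)
  ids <- sprintf("hsa_circ_%07d", 1:50)
  circs <- circ_records(ids, "H1", "chr1", start = 0,
                        end = c(rep(1000, 2), sample(200:5000, 48)))
  bg <- sample_background_circs(circs, ids[1:2], n = 5, seed = 9,
                                tolerance = 0.2)
  sizes <- circ_size(circs)
  expect_true(all(abs(sizes[bg] - 1000) <= 200))
  expect_false(any(ids[1:2] %in% bg))
})
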