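# Independent oracles used to check the kernel and motif enumeration.
# Deliberately written as brute force, separate from the package internals.

# Mann-Whitney: enumerate all C(N, n1) equally likely rank subsets.
oracle_mw <- function(x, y, alternative = "two_sided") {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- combn(N, n1)
  u_all <- apply(subsets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_greater <- mean(u_all >= u_obs - 1e-9)
  p_less <- mean(u_all <= u_obs + 1e-9)
  switch(alternative,
         two_sided = min(1, 2 * min(p_greater, p_less)),
         greater = p_greater,
         less = p_less)
}

# normal approximation with tie and continuity correction, written from the
# formula (used to check the exact-vs-approximate agreement property)
oracle_mw_normal <- function(x, y, alternative = "two_sided") {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tt <- table(r)
  s2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  d <- u - n1 * n2 / 2
  if (alternative == "greater") {
    return(pnorm((d - 0.5) / sqrt(s2), lower.tail = FALSE))
  }
  z <- (d - sign(d) * 0.5) / sqrt(s2)
  min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
}

# Fisher: enumerate all admissible 2x2 tables with the observed margins,
# probabilities from products of binomial coefficients.
oracle_fisher <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  prob <- vapply(support, function(a) {
    choose(rs[1], a) * choose(rs[2], cs[1] - a) / choose(n, cs[1])
  }, numeric(1))
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# all permutations of 1..n by lexicographic next-permutation stepping
oracle_perms <- function(n) {
  p <- seq_len(n)
  out <- matrix(NA_integer_, factorial(n), n)
  for (row in seq_len(nrow(out))) {
    out[row, ] <- p
    i <- n - 1
    while (i >= 1 && p[i] >= p[i + 1]) i <- i - 1
    if (i < 1) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1):n] <- rev(p[(i + 1):n])
  }
  out
}

oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- oracle_perms(length(y))
  rho_all <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# brute-force feed-forward-loop enumeration: triple loop over all
# (circRNA, miRNA, gene) combinations
oracle_ffl <- function(candidates, sponges, circs, targets, signature) {
  cand_mirs <- candidates$candidates$mirna_id
  cand_circs <- circs[circs$host_gene %in% signature$genes &
                        circs$circ_id %in%
                          sponges$circ_id[sponges$mirna_id %in% cand_mirs], ]
  rows <- list()
  for (ci in cand_circs$circ_id) {
    host <- cand_circs$host_gene[cand_circs$circ_id == ci]
    for (m in cand_mirs) {
      for (g in signature$genes) {
        sponge_ok <- any(sponges$circ_id == ci & sponges$mirna_id == m)
        target_ok <- any(targets$mirna_id == m & targets$target_gene == g)
        if (sponge_ok && target_ok && g == host) {
          rows[[length(rows) + 1]] <- data.frame(circ_id = ci, mirna_id = m,
                                                 target_gene = g)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(circ_id = character(), mirna_id = character(),
                      target_gene = character()))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$circ_id, out$mirna_id), , drop = FALSE]
}

# random small ceRNA instance for oracle-equivalence tests
random_cerna_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:8, 1)
  genes <- sprintf("G%02d", seq_len(n_genes))
  sig <- gene_signature(genes)
  mirs <- sprintf("hsa-miR-t%d-5p", seq_len(sample(2:6, 1)))
  n_circ <- sample(3:10, 1)
  circ_ids <- sprintf("hsa_circ_%07d", seq_len(n_circ))
  circs <- circ_records(circ_ids,
                        host_gene = sample(c(genes, "OFF1"), n_circ,
                                           replace = TRUE),
                        chrom = "chr1",
                        start = seq_len(n_circ) * 1000,
                        end = seq_len(n_circ) * 1000 + 500)
  n_sp <- sample(3:15, 1)
  sponges <- sponge_records(sample(circ_ids, n_sp, replace = TRUE),
                            sample(mirs, n_sp, replace = TRUE),
                            n_sites = sample(1:5, n_sp, replace = TRUE))
  sponges <- sponges[!duplicated(sponges[, c("circ_id", "mirna_id")]), ]
  n_tg <- sample(3:15, 1)
  targets <- mir_target_records(sample(mirs, n_tg, replace = TRUE),
                                sample(genes, n_tg, replace = TRUE))
  candidates <- select_candidate_mirnas(targets, sig, min_targets = 1)
  list(signature = sig, circs = circs, sponges = sponges, targets = targets,
       candidates = candidates)
}

fixture_network <- function() chek1_pim1_network()
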