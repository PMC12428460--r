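# Tripartite ceRNA graph assembly, feed-forward-loop enumeration, and the
# RBP binding-site enrichment screen.

#' Build the tripartite ceRNA graph
#'
#' Assembles an [igraph::igraph] with three node classes — circRNA, miRNA
#' (candidates only) and gene (all signature genes) — and two edge kinds:
#' `sponge` (candidate circRNA to candidate miRNA, carrying `n_sites` and
#' `agoclip_p_bound`) and `target` (candidate miRNA to signature gene, from
#' validated interaction records). Sponge edges to non-candidate miRNAs are
#' excluded. No edge ever joins two nodes of the same class.
#'
#' @param candidates [select_candidate_mirnas()] result.
#' @param sponges sponge-edge tibble.
#' @param circs circRNA annotation tibble.
#' @param targets miRNA-target tibble.
#' @param signature [gene_signature()].
#' @return undirected `igraph` with vertex attributes `type`
#'   (`circRNA`/`miRNA`/`gene`) and `host_gene` (circRNA vertices), edge
#'   attributes `kind`, `n_sites`, `agoclip_p_bound`.
#' @export
build_tripartite <- function(candidates, sponges, circs, targets, signature) {
  check_sponge_integrity(sponges, circs)
  cand_mirs <- candidates$candidates$mirna_id
  cand_circs <- select_candidate_circs(sponges, circs, candidates, signature)

  g <- igraph::make_empty_graph(directed = FALSE)
  if (length(signature$genes) > 0) {
    g <- igraph::add_vertices(g, length(signature$genes),
                              name = signature$genes, type = "gene",
                              host_gene = NA_character_)
  }
  if (length(cand_mirs) > 0) {
    g <- igraph::add_vertices(g, length(cand_mirs), name = cand_mirs,
                              type = "miRNA", host_gene = NA_character_)
  }
  if (nrow(cand_circs) > 0) {
    g <- igraph::add_vertices(g, nrow(cand_circs), name = cand_circs$circ_id,
                              type = "circRNA",
                              host_gene = cand_circs$host_gene)
  }

  sp <- sponges[sponges$circ_id %in% cand_circs$circ_id &
                  sponges$mirna_id %in% cand_mirs, , drop = FALSE]
  if (nrow(sp) > 0) {
    g <- igraph::add_edges(
      g, as.vector(rbind(sp$circ_id, sp$mirna_id)),
      kind = "sponge", n_sites = sp$n_sites,
      agoclip_p_bound = sp$agoclip_p_bound)
  }
  tg <- targets[targets$mirna_id %in% cand_mirs &
                  targets$target_gene %in% signature$genes, , drop = FALSE]
  tg <- tg[!duplicated(tg[, c("mirna_id", "target_gene")]), , drop = FALSE]
  if (nrow(tg) > 0) {
    g <- igraph::add_edges(
      g, as.vector(rbind(tg$mirna_id, tg$target_gene)),
      kind = "target", n_sites = NA_real_, agoclip_p_bound = NA_real_)
  }
  g
}

#' Enumerate feed-forward-loop motifs
#'
#' A feed-forward loop is a (circRNA, miRNA, gene) triple in which the
#' circRNA sponges the miRNA, the miRNA targets the gene, and the gene is
#' the circRNA's own host — so the circRNA de-represses the transcript it
#' was spliced from. Results are ordered by (`circ_id`, `mirna_id`).
#'
#' @param graph tripartite graph from [build_tripartite()].
#' @return tibble with columns `circ_id`, `mirna_id`, `target_gene`,
#'   `n_sites`, `agoclip_p_bound`; zero rows when no motif exists.
#' @export
enumerate_ffl <- function(graph) {
  empty <- tibble::tibble(circ_id = character(), mirna_id = character(),
                          target_gene = character(), n_sites = numeric(),
                          agoclip_p_bound = numeric())
  if (igraph::vcount(graph) == 0) return(empty)
  vtype <- igraph::V(graph)$type
  vname <- igraph::V(graph)$name
  vhost <- igraph::V(graph)$host_gene
  circ_idx <- which(vtype == "circRNA")
  if (length(circ_idx) == 0) return(empty)

  ends <- igraph::as_edgelist(graph, names = TRUE)
  kind <- igraph::E(graph)$kind
  nsites <- igraph::E(graph)$n_sites
  pbound <- igraph::E(graph)$agoclip_p_bound
  target_keys <- c(paste(ends[kind == "target", 1],
                         ends[kind == "target", 2], sep = "\r"),
                   paste(ends[kind == "target", 2],
                         ends[kind == "target", 1], sep = "\r"))

  rows <- list()
  for (ci in circ_idx) {
    circ <- vname[ci]
    host <- vhost[ci]
    ei <- which(kind == "sponge" & (ends[, 1] == circ | ends[, 2] == circ))
    for (e in ei) {
      mir <- if (ends[e, 1] == circ) ends[e, 2] else ends[e, 1]
      if (paste(mir, host, sep = "\r") %in% target_keys) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          circ_id = circ, mirna_id = mir, target_gene = host,
          n_sites = nsites[e], agoclip_p_bound = pbound[e])
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$circ_id, out$mirna_id), , drop = FALSE]
}

#' RBP binding-site enrichment screen
#'
#' Per RNA-binding protein, a one-sided Mann-Whitney test of whether
#' candidate circRNAs carry more predicted binding sites than size-matched
#' background circRNAs, with Benjamini-Hochberg adjustment across RBPs.
#' RBPs with all-zero counts in both groups are excluded with a warning.
#'
#' @param table [rbp_site_table()] object.
#' @param fdr_level false-discovery-rate level in (0, 1); default 0.10.
#' @return tibble with one row per tested RBP: `rbp`, count summaries,
#'   list-columns `candidate_counts`/`background_counts`, `U`, `p_value`,
#'   `p_adjusted`, `enriched`.
#' @export
rbp_enrichment <- function(table, fdr_level = 0.10) {
  if (!inherits(table, "rbp_site_table")) {
    cf_abort("table must be an rbp_site_table", "cerna_argument_error")
  }
  if (!is.numeric(fdr_level) || fdr_level <= 0 || fdr_level >= 1) {
    cf_abort("fdr_level must lie in (0, 1)", "cerna_argument_error")
  }
  if (sum(table$role == "background") < 2) {
    cf_abort("rbp_enrichment needs >= 2 background circRNAs",
             "cerna_argument_error")
  }
  cand <- table$counts[table$role == "candidate", , drop = FALSE]
  bg <- table$counts[table$role == "background", , drop = FALSE]
  all_zero <- colSums(cand) + colSums(bg) == 0
  if (any(all_zero)) {
    cf_warn(paste0("RBP(s) with all-zero counts excluded: ",
                   paste(colnames(cand)[all_zero], collapse = ", ")))
  }
  rbps <- colnames(cand)[!all_zero]
  res <- lapply(rbps, function(r) {
    tst <- mann_whitney(cand[, r], bg[, r], alternative = "greater")
    tibble::tibble(
      rbp = r,
      median_candidate = median(cand[, r]),
      median_background = median(bg[, r]),
      candidate_counts = list(unname(cand[, r])),
      background_counts = list(unname(bg[, r])),
      U = tst$statistic, p_value = tst$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$enriched <- out$p_adjusted < fdr_level
  out
}

#' Sample size-matched background circRNAs
#'
#' Helper for building the enrichment screen's background set: samples
#' circRNAs whose size lies within `tolerance` (relative) of the mean
#' candidate size.
#'
#' @param circs circRNA annotation tibble.
#' @param candidate_ids ids of candidate circRNAs (excluded from sampling).
#' @param n number of background circRNAs to draw.
#' @param seed RNG seed.
#' @param tolerance relative size window (default 0.2 = within 20%).
#' @param use_spliced prefer spliced length for size.
#' @return character vector of background circ ids.
#' @export
sample_background_circs <- function(circs, candidate_ids, n, seed,
                                    tolerance = 0.2, use_spliced = TRUE) {
  sizes <- circ_size(circs, use_spliced = use_spliced)
  if (!all(candidate_ids %in% names(sizes))) {
    cf_abort("candidate circ id(s) absent from annotation",
             "cerna_integrity_error")
  }
  target <- mean(sizes[candidate_ids])
  pool <- setdiff(names(sizes)[abs(sizes - target) <= tolerance * target],
                  candidate_ids)
  if (length(pool) < n) {
    cf_abort(sprintf(
      "only %d size-matched background circRNAs available (need %d)",
      length(pool), n), "cerna_argument_error")
  }
  set.seed(seed)
  sample(pool, n)
}
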