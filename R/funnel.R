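# The candidate-selection funnel: miRNAs targeting enough signature genes,
# circRNAs from signature host genes sponging those miRNAs, binding-site
# totals (MBS) per circRNA, and the >= cohort-median MBS filter.

#' Select candidate miRNAs against a gene signature
#'
#' A miRNA is retained iff it has at least `min_targets` distinct signature
#' genes among its validated targets.
#'
#' @param targets tibble from [mir_target_records()] /
#'   [read_mir_target_table()].
#' @param signature [gene_signature()].
#' @param min_targets minimum distinct signature targets (default 4).
#' @return object of class `candidate_mir_set`: a list with `candidates`
#'   (tibble: `mirna_id`, `n_targets`, `targets` list-column) and
#'   `covered_genes` (signature genes hit by any retained miRNA).
#' @export
select_candidate_mirnas <- function(targets, signature, min_targets = 4) {
  if (!inherits(signature, "gene_signature")) {
    cf_abort("signature must be a gene_signature", "cerna_argument_error")
  }
  if (!is.numeric(min_targets) || min_targets < 1) {
    cf_abort("min_targets must be >= 1", "cerna_argument_error")
  }
  sig_hits <- targets[targets$target_gene %in% signature$genes, , drop = FALSE]
  if (nrow(sig_hits) == 0) {
    return(structure(list(
      candidates = tibble::tibble(mirna_id = character(),
                                  n_targets = integer(),
                                  targets = list()),
      covered_genes = character(),
      min_targets = min_targets
    ), class = "candidate_mir_set"))
  }
  per_mir <- split(sig_hits$target_gene, sig_hits$mirna_id)
  per_mir <- lapply(per_mir, function(g) sort(unique(g)))
  keep <- lengths(per_mir) >= min_targets
  per_mir <- per_mir[keep]
  ord <- order(names(per_mir))
  per_mir <- per_mir[ord]
  structure(list(
    candidates = tibble::tibble(
      mirna_id = names(per_mir),
      n_targets = unname(lengths(per_mir)),
      targets = unname(per_mir)
    ),
    covered_genes = sort(unique(unlist(per_mir, use.names = FALSE))),
    min_targets = min_targets
  ), class = "candidate_mir_set")
}

#' @export
print.candidate_mir_set <- function(x, ...) {
  cat("Candidate miRNA set:", nrow(x$candidates), "miRNA(s) with >=",
      x$min_targets, "signature targets, covering",
      length(x$covered_genes), "signature gene(s)\n")
  invisible(x)
}

#' Select candidate circRNAs
#'
#' Retains circRNAs whose host gene belongs to the signature AND which carry
#' at least one sponge edge to a candidate miRNA.
#'
#' @param sponges sponge-edge tibble.
#' @param circs circRNA annotation tibble.
#' @param candidates [select_candidate_mirnas()] result.
#' @param signature [gene_signature()].
#' @return subset of `circs` (tibble), one row per retained circRNA.
#' @export
select_candidate_circs <- function(sponges, circs, candidates, signature) {
  check_sponge_integrity(sponges, circs)
  cand_mirs <- candidates$candidates$mirna_id
  sponging <- unique(sponges$circ_id[sponges$mirna_id %in% cand_mirs])
  keep <- circs$host_gene %in% signature$genes & circs$circ_id %in% sponging
  circs[keep, , drop = FALSE]
}

#' Compute binding-site totals (MBS) per circRNA
#'
#' MBS of a circRNA is the sum of `n_sites` over its sponge edges to any
#' candidate miRNA — multiple sites for the same miRNA all count, so the
#' total covers sites "for the same or different" candidate miRNAs. The
#' cohort median (mean of the middle two for even counts) is computed once
#' over all retained circRNAs and frozen in the summary.
#'
#' @param sponges sponge-edge tibble.
#' @param retained_circs circRNA tibble from [select_candidate_circs()].
#' @param candidates [select_candidate_mirnas()] result.
#' @return object of class `mbs_summary`: list with `per_circ` (tibble:
#'   `circ_id`, `host_gene`, `mbs`) and `cohort_median`.
#' @export
compute_mbs <- function(sponges, retained_circs, candidates) {
  if (nrow(retained_circs) == 0) {
    cf_abort("compute_mbs: no retained circRNAs", "cerna_argument_error")
  }
  cand_mirs <- candidates$candidates$mirna_id
  rel <- sponges[sponges$circ_id %in% retained_circs$circ_id &
                   sponges$mirna_id %in% cand_mirs, , drop = FALSE]
  mbs <- vapply(retained_circs$circ_id, function(id) {
    sum(rel$n_sites[rel$circ_id == id])
  }, numeric(1))
  per_circ <- tibble::tibble(
    circ_id = retained_circs$circ_id,
    host_gene = retained_circs$host_gene,
    mbs = as.numeric(mbs)
  )
  structure(list(per_circ = per_circ,
                 cohort_median = median(per_circ$mbs)),
            class = "mbs_summary")
}

#' @export
print.mbs_summary <- function(x, ...) {
  cat("MBS summary:", nrow(x$per_circ), "circRNA(s); cohort median MBS =",
      x$cohort_median, "\n")
  invisible(x)
}

#' Filter circRNAs by the cohort-median MBS rule
#'
#' One-pass filter: keep a circRNA iff its MBS is greater than or equal to
#' the cohort median frozen in the summary (ties at the median retained).
#' The median is NOT re-derived after filtering.
#'
#' @param summary [compute_mbs()] result.
#' @return list with `retained` (circ ids), `n_retained`, `host_genes`
#'   (distinct host genes of retained circRNAs) and the `cohort_median`
#'   applied.
#' @export
filter_by_mbs <- function(summary) {
  if (!inherits(summary, "mbs_summary") || nrow(summary$per_circ) == 0) {
    cf_abort("filter_by_mbs needs a non-empty mbs_summary",
             "cerna_argument_error")
  }
  keep <- summary$per_circ$mbs >= summary$cohort_median
  retained <- summary$per_circ$circ_id[keep]
  list(
    retained = retained,
    n_retained = length(retained),
    host_genes = sort(unique(summary$per_circ$host_gene[keep])),
    cohort_median = summary$cohort_median
  )
}

#' Spearman correlation between circRNA size and MBS
#'
#' Tests the expectation that larger circRNAs expose more candidate-miRNA
#' binding sites.
#'
#' @param summary [compute_mbs()] result.
#' @param circs circRNA annotation tibble (for sizes).
#' @param use_spliced prefer spliced length over genomic span where present.
#' @return [cor_result()].
#' @export
correlate_size_mbs <- function(summary, circs, use_spliced = TRUE) {
  sizes <- circ_size(circs, use_spliced = use_spliced)
  ids <- intersect(summary$per_circ$circ_id, names(sizes))
  if (length(ids) < 3) {
    cf_abort("size-MBS correlation needs >= 3 circRNAs with defined size",
             "cerna_undefined_result_error")
  }
  mbs <- summary$per_circ$mbs[match(ids, summary$per_circ$circ_id)]
  spearman(unname(sizes[ids]), mbs)
}
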