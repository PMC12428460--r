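#' Bundled CHEK1/PIM1 ceRNA network example
#'
#' Loads the packaged worked example: the published feed-forward-loop ceRNA
#' network around the CHEK1 and PIM1 host genes — 15 sponge edges linking 7
#' circRNA isoforms (3 circCHEK1, 4 circPIM1) to 4 tumor-suppressor miRNAs
#' (miR-16-5p, miR-124-3p, miR-193b-3p, miR-195-5p), each miRNA a validated
#' repressor of its circRNAs' host transcript, with AGO-CLIP region p-value
#' bounds per edge.
#'
#' The interaction topology and p-value bounds are the published ones; the
#' per-edge binding-site counts and the genomic coordinates in the
#' annotation file are synthetic placeholders (the published table reports
#' neither), and the files say so in their names. The signature shipped
#' alongside holds the 11 signature host genes the circRNA funnel stage
#' reported.
#'
#' @return list with `signature` ([gene_signature()]), `mir_targets`,
#'   `sponges`, `circs` (tibbles), and `paths` (the underlying files).
#' @examples
#' fx <- chek1_pim1_network()
#' cand <- select_candidate_mirnas(fx$mir_targets, fx$signature,
#'                                 min_targets = 1)
#' graph <- build_tripartite(cand, fx$sponges, fx$circs, fx$mir_targets,
#'                           fx$signature)
#' enumerate_ffl(graph)
#' @export
chek1_pim1_network <- function() {
  dir <- system.file("extdata", "chek1_pim1", package = "ceRNAfunnel")
  paths <- list(
    signature = file.path(dir, "signature_host_genes.txt"),
    mir_targets = file.path(dir, "mir_targets.tsv"),
    sponges = file.path(dir, "sponges.tsv"),
    circs = file.path(dir, "circ_annotation_synthetic.tsv")
  )
  sp <- read_sponge_tables(paths$sponges, paths$circs)
  list(
    signature = read_signature_file(paths$signature, name = "host-genes"),
    mir_targets = read_mir_target_table(paths$mir_targets),
    sponges = sp$sponges,
    circs = sp$circs,
    paths = paths
  )
}

#' Demo pipeline configuration for the bundled network
#'
#' A ready-made [run_config()] pointing at the bundled CHEK1/PIM1 example.
#' `min_targets` is 1 here because the bundled interaction table is the
#' already-funneled endpoint of the published selection (each miRNA carries
#' only its in-network targets, not its full validated target list).
#'
#' @param out_dir output directory for stage artifacts.
#' @return `run_config` list usable with [run_pipeline()].
#' @export
demo_config <- function(out_dir = file.path(tempdir(), "cerna_demo")) {
  fx_dir <- system.file("extdata", "chek1_pim1", package = "ceRNAfunnel")
  run_config(list(
    signature_path = file.path(fx_dir, "signature_host_genes.txt"),
    mir_targets_path = file.path(fx_dir, "mir_targets.tsv"),
    sponge_path = file.path(fx_dir, "sponges.tsv"),
    circ_annotation_path = file.path(fx_dir, "circ_annotation_synthetic.tsv"),
    min_targets = 1,
    out_dir = out_dir
  ))
}
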