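# Domain types shared by all pipeline stages. Tabular interchange types are
# validated tibbles; the expression container is a SummarizedExperiment.

#' Gene signature
#'
#' An ordered set of gene symbols the funnel starts from, e.g. a prognostic
#' transcript biomarker. Symbols are upper-cased and must be unique and
#' non-empty after upper-casing.
#'
#' @param genes character vector of gene symbols.
#' @param name label for the signature.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(genes, name = "signature") {
  if (!is.character(genes) || length(genes) == 0) {
    cf_abort("a gene signature must contain at least one gene symbol",
             "cerna_argument_error")
  }
  genes <- toupper(trimws(genes))
  if (any(genes == "")) {
    cf_abort("empty gene symbol in signature", "cerna_argument_error")
  }
  if (anyDuplicated(genes)) {
    cf_abort("duplicate gene symbols in signature (after upper-casing)",
             "cerna_argument_error")
  }
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  cat(" ", paste(head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# miRNA ids are compared verbatim (arm suffixes are case-meaningful); the
# "hsa-" dialect is expected but other ids are accepted with a warning.
check_mirna_ids <- function(ids) {
  odd <- unique(ids[!grepl("^hsa-", ids)])
  if (length(odd) > 0) {
    cf_warn(paste0("miRNA ids not in the 'hsa-...' dialect accepted verbatim: ",
                   paste(head(odd, 5), collapse = ", ")))
  }
  invisible(ids)
}

#' miRNA-target interaction records
#'
#' Validated tibble of miRNA to target-gene records (miRTarBase-like).
#' Duplicate (miRNA, target) pairs are collapsed, gene symbols upper-cased,
#' miRNA ids kept verbatim.
#'
#' @param mirna_id character miRNA identifiers.
#' @param target_gene character gene symbols.
#' @param evidence free-text evidence class (recycled if scalar).
#' @return tibble with columns `mirna_id`, `target_gene`, `evidence`.
#' @export
mir_target_records <- function(mirna_id, target_gene, evidence = "NA") {
  tb <- tibble::tibble(
    mirna_id = as.character(mirna_id),
    target_gene = toupper(as.character(target_gene)),
    evidence = as.character(evidence)
  )
  if (nrow(tb) > 0) check_mirna_ids(tb$mirna_id)
  dup <- duplicated(tb[, c("mirna_id", "target_gene")])
  if (any(dup)) {
    message(sum(dup), " duplicate (miRNA, target) pair(s) collapsed")
    tb <- tb[!dup, ]
  }
  tb
}

#' circRNA annotation records
#'
#' circBase-style circRNA annotation: identifier, host gene, genomic span
#' (0-based half-open) and optional spliced length.
#'
#' @param circ_id circBase-style ids (`hsa_circ_` + digits).
#' @param host_gene host gene symbols (upper-cased).
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open coordinates, `end > start`.
#' @param spliced_length optional positive integer spliced lengths (NA allowed).
#' @return tibble with one row per circRNA.
#' @export
circ_records <- function(circ_id, host_gene, chrom, start, end,
                         spliced_length = NA_integer_) {
  tb <- tibble::tibble(
    circ_id = as.character(circ_id),
    host_gene = toupper(as.character(host_gene)),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    spliced_length = as.numeric(spliced_length)
  )
  if (any(tb$end <= tb$start)) {
    cf_abort("circRNA annotation: end must exceed start (0-based half-open)",
             "cerna_format_error")
  }
  if (any(!is.na(tb$spliced_length) & tb$spliced_length <= 0)) {
    cf_abort("spliced_length must be positive where present",
             "cerna_format_error")
  }
  if (anyDuplicated(tb$circ_id)) {
    cf_abort("duplicate circ_id in circRNA annotation", "cerna_format_error")
  }
  tb
}

#' circRNA size
#'
#' Spliced length when annotated, else the genomic span `end - start`.
#' Which of the two a sponge database's lists reflect is source-dependent,
#' so the preference is a flag.
#'
#' @param circs tibble from [circ_records()].
#' @param use_spliced prefer `spliced_length` where present (default `TRUE`).
#' @return numeric vector of sizes (nt), named by `circ_id`.
#' @export
circ_size <- function(circs, use_spliced = TRUE) {
  span <- circs$end - circs$start
  size <- if (use_spliced) {
    ifelse(!is.na(circs$spliced_length), circs$spliced_length, span)
  } else span
  setNames(size, circs$circ_id)
}

#' circRNA sponge records
#'
#' circRNA-miRNA sponge edges with AGO-CLIP-supported binding-site counts
#' and an upper bound on the AGO-CLIP region p-value.
#'
#' @param circ_id,mirna_id edge endpoints.
#' @param n_sites integer binding-site counts, `>= 1`.
#' @param agoclip_p_bound p-value upper bounds in `(0, 1]`.
#' @return tibble with one row per sponge edge.
#' @export
sponge_records <- function(circ_id, mirna_id, n_sites, agoclip_p_bound = 1) {
  tb <- tibble::tibble(
    circ_id = as.character(circ_id),
    mirna_id = as.character(mirna_id),
    n_sites = as.integer(n_sites),
    agoclip_p_bound = as.numeric(agoclip_p_bound)
  )
  if (any(is.na(tb$n_sites)) || any(tb$n_sites < 1)) {
    cf_abort("sponge records: n_sites must be integers >= 1",
             "cerna_format_error")
  }
  if (any(is.na(tb$agoclip_p_bound)) ||
      any(tb$agoclip_p_bound <= 0 | tb$agoclip_p_bound > 1)) {
    cf_abort("sponge records: agoclip_p_bound must lie in (0, 1]",
             "cerna_format_error")
  }
  tb
}

# Referential integrity: every sponge edge must point at an annotated circRNA.
check_sponge_integrity <- function(sponges, circs) {
  missing <- setdiff(unique(sponges$circ_id), circs$circ_id)
  if (length(missing) > 0) {
    cf_abort(paste0("sponge edges reference unannotated circRNA id(s): ",
                    paste(head(missing, 10), collapse = ", ")),
             "cerna_integrity_error")
  }
  invisible(TRUE)
}

#' Per-sample clinical annotation
#'
#' Validated tibble of per-sample clinical and molecular annotation for a
#' meningioma-style cohort: WHO grade (1/2 only), recurrence, molecular
#' subtype (MenG A/B/C), chromosome-arm losses, necrosis and Ki-67 index.
#' Categorical fields are restricted to their listed levels; `NA` encodes
#' missing where the field allows it.
#'
#' @param df data frame with columns `sample_id`, `who_grade`, `recurrent`
#'   and optionally `meng_subtype`, `chr1p_loss`, `chr22q_loss`, `necrosis`,
#'   `ki67_index`.
#' @return validated tibble.
#' @export
sample_annotation <- function(df) {
  need <- c("sample_id", "who_grade", "recurrent")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    cf_abort(paste0("annotation lacks required column(s): ",
                    paste(miss, collapse = ", ")), "cerna_format_error")
  }
  tb <- tibble::as_tibble(df)
  tb$sample_id <- as.character(tb$sample_id)
  if (anyDuplicated(tb$sample_id)) {
    cf_abort("duplicate sample ids in annotation", "cerna_format_error")
  }
  grade <- suppressWarnings(as.integer(tb$who_grade))
  if (any(is.na(grade)) || !all(grade %in% c(1L, 2L))) {
    cf_abort("who_grade restricted to levels {1, 2}", "cerna_format_error")
  }
  tb$who_grade <- grade
  check_level <- function(v, levels, field, allow_na = TRUE) {
    v <- as.character(v)
    bad <- !(v %in% levels) & !(allow_na & is.na(v))
    if (any(bad)) {
      cf_abort(sprintf("annotation field '%s' has unknown level(s): %s",
                       field, paste(unique(v[bad]), collapse = ", ")),
               "cerna_format_error")
    }
    v
  }
  tb$recurrent <- check_level(tb$recurrent, c("yes", "no"), "recurrent",
                              allow_na = FALSE)
  for (f in c("chr1p_loss", "chr22q_loss", "necrosis")) {
    if (is.null(tb[[f]])) tb[[f]] <- NA_character_
    tb[[f]] <- check_level(tb[[f]], c("yes", "no"), f)
  }
  if (is.null(tb[["meng_subtype"]])) tb$meng_subtype <- NA_character_
  tb$meng_subtype <- check_level(tb$meng_subtype, c("A", "B", "C"),
                                 "meng_subtype")
  if (is.null(tb[["ki67_index"]])) tb$ki67_index <- NA_real_
  tb$ki67_index <- as.numeric(tb$ki67_index)
  if (any(!is.na(tb$ki67_index) & tb$ki67_index < 0)) {
    cf_abort("ki67_index must be non-negative", "cerna_format_error")
  }
  tb
}

#' Expression dataset
#'
#' Bundles a genes x samples matrix of log2-scale normalized expression
#' (e.g. the log2 of a variance-stabilized RNA-seq matrix) with per-sample
#' clinical annotation, as a [SummarizedExperiment::SummarizedExperiment].
#' Columns are aligned to the annotation's sample order.
#'
#' @param values numeric matrix, rownames = gene symbols, colnames = sample
#'   ids; all values finite.
#' @param annotation data frame accepted by [sample_annotation()].
#' @return `SummarizedExperiment` with assay `"log2expr"`.
#' @export
expression_dataset <- function(values, annotation) {
  if (!is.matrix(values) || !is.numeric(values)) {
    cf_abort("expression values must be a numeric matrix",
             "cerna_argument_error")
  }
  if (any(!is.finite(values))) {
    cf_abort("expression values must be finite", "cerna_format_error")
  }
  ann <- sample_annotation(annotation)
  missing <- setdiff(ann$sample_id, colnames(values))
  if (length(missing) > 0) {
    cf_abort(paste0("annotated sample(s) absent from the matrix: ",
                    paste(head(missing, 10), collapse = ", ")),
             "cerna_integrity_error")
  }
  values <- values[, ann$sample_id, drop = FALSE]
  rownames(values) <- toupper(rownames(values))
  cd <- S4Vectors::DataFrame(ann[, setdiff(names(ann), "sample_id")],
                             row.names = ann$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values), colData = cd)
}

#' qPCR Ct table
#'
#' Matrix of raw Ct cycle values, assays in rows and tissues in columns; a
#' reference assay (e.g. GAPDH) must be present. Ct values must lie in
#' `(0, 45]` or be missing (`NA`).
#'
#' @param ct numeric matrix with assay rownames and tissue colnames.
#' @param reference name of the reference assay row.
#' @return object of class `ct_table`.
#' @export
ct_table <- function(ct, reference = "GAPDH") {
  if (!is.matrix(ct) || !is.numeric(ct) || is.null(rownames(ct)) ||
      is.null(colnames(ct))) {
    cf_abort("ct must be a numeric matrix with assay and tissue names",
             "cerna_argument_error")
  }
  if (!(reference %in% rownames(ct))) {
    cf_abort(sprintf("reference assay '%s' absent from Ct table", reference),
             "cerna_argument_error")
  }
  bad <- !is.na(ct) & (ct <= 0 | ct > 45)
  if (any(bad)) {
    cf_abort("Ct values must lie in (0, 45] or be missing",
             "cerna_format_error")
  }
  structure(list(ct = ct, reference = reference), class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("Ct table:", nrow(x$ct), "assays x", ncol(x$ct), "tissues; reference:",
      x$reference, "\n")
  invisible(x)
}

#' RBP binding-site count table
#'
#' Predicted RNA-binding-protein binding-site counts per circRNA, with each
#' circRNA flagged as a candidate or a size-matched background sequence.
#'
#' @param counts integer matrix (circRNAs x RBPs), counts `>= 0`.
#' @param role character vector over `{"candidate", "background"}`, one per
#'   circRNA (row).
#' @return object of class `rbp_site_table`.
#' @export
rbp_site_table <- function(counts, role) {
  if (!is.matrix(counts) || any(counts < 0) || any(counts != round(counts))) {
    cf_abort("RBP site counts must be a matrix of non-negative integers",
             "cerna_argument_error")
  }
  role <- as.character(role)
  if (length(role) != nrow(counts) ||
      !all(role %in% c("candidate", "background"))) {
    cf_abort("role must be one of {candidate, background} per circRNA row",
             "cerna_argument_error")
  }
  if (sum(role == "candidate") < 1 || sum(role == "background") < 1) {
    cf_abort("need at least one candidate and one background circRNA",
             "cerna_argument_error")
  }
  structure(list(counts = counts, role = role), class = "rbp_site_table")
}
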