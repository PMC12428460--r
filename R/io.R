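# Readers and writers for the tabular formats the pipeline touches: TSV with
# header everywhere, BED-6 accepted for circRNA coordinates, JSON for run
# reports. Missing values are "" or "NA" on disk.

read_tsv_base <- function(path) {
  if (!file.exists(path)) {
    cf_abort(paste0("input file not found: ", path), "cerna_format_error")
  }
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("", "NA"),
             fileEncoding = "UTF-8", quote = "")
}

#' Write a table as TSV
#'
#' Tab-separated, header, no quoting, missing values as "NA", UTF-8.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# pick the first column whose name matches any pattern; error (naming the
# role) when none does.
find_column <- function(df, patterns, role, path) {
  for (p in patterns) {
    hit <- grep(p, names(df), ignore.case = TRUE)
    if (length(hit) > 0) return(names(df)[hit[1]])
  }
  cf_abort(sprintf("%s: no column matching the %s role (looked for: %s)",
                   path, role, paste(patterns, collapse = ", ")),
           "cerna_format_error")
}

#' Read a miRNA-target interaction table
#'
#' Accepts a miRTarBase-like TSV with header. Column roles are located by
#' name (case-insensitive): the miRNA column must match `mirna|mir`, the
#' target column `target|gene|symbol`, an optional evidence column
#' `evidence|support|experiment`. Duplicate (miRNA, target) pairs are
#' collapsed with a message.
#'
#' @param path TSV path.
#' @return tibble of validated records (see [mir_target_records()]).
#' @export
read_mir_target_table <- function(path) {
  df <- read_tsv_base(path)
  mir_col <- find_column(df, c("^mirna", "mir"), "miRNA id", path)
  tgt_col <- find_column(df, c("^target", "gene", "symbol"), "target gene", path)
  ev <- grep("evidence|support|experiment", names(df), ignore.case = TRUE)
  if (nrow(df) == 0) {
    return(mir_target_records(character(), character(), character()))
  }
  mir_target_records(
    mirna_id = df[[mir_col]],
    target_gene = df[[tgt_col]],
    evidence = if (length(ev) > 0) df[[names(df)[ev[1]]]] else "NA"
  )
}

# "<=10^-12" / Unicode "≤ 10^−12" / "1e-6" / plain numbers -> float
parse_p_bound <- function(s) {
  out <- vapply(as.character(s), function(v) {
    v0 <- v
    v <- gsub("≤|<=|<", "", v)
    v <- gsub("−", "-", v)       # Unicode minus
    v <- gsub("\\s", "", v)
    v <- sub("^10\\^", "1e", v)       # 10^-12 -> 1e-12
    v <- sub("\\^", "e", v)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) {
      cf_abort(paste0("cannot parse AGO-CLIP p-value bound: '", v0, "'"),
               "cerna_format_error")
    }
    x
  }, numeric(1), USE.NAMES = FALSE)
  out
}

read_circ_annotation <- function(path, coords = c("bed", "one_based")) {
  coords <- match.arg(coords)
  first <- readLines(path, n = 1, encoding = "UTF-8")
  is_bed <- !grepl("circ_id|host", first, ignore.case = TRUE)
  if (is_bed) {
    # BED-6: chrom start end name score strand; name = "circ_id|HOST_GENE"
    df <- read.delim(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (ncol(df) < 4) {
      cf_abort(paste0(path, ": BED circRNA annotation needs >= 4 columns"),
               "cerna_format_error")
    }
    nm <- strsplit(as.character(df[[4]]), "|", fixed = TRUE)
    if (any(lengths(nm) < 2)) {
      cf_abort(paste0(path, ": BED name field must be 'circ_id|host_gene'"),
               "cerna_format_error")
    }
    return(circ_records(
      circ_id = vapply(nm, `[`, "", 1),
      host_gene = vapply(nm, `[`, "", 2),
      chrom = df[[1]], start = df[[2]], end = df[[3]]
    ))
  }
  df <- read_tsv_base(path)
  for (col in c("circ_id", "host_gene", "chrom", "start", "end")) {
    if (!(col %in% names(df))) {
      cf_abort(paste0(path, ": missing required column '", col, "'"),
               "cerna_format_error")
    }
  }
  start <- as.numeric(df$start)
  end <- as.numeric(df$end)
  if (coords == "one_based") start <- start - 1   # to 0-based half-open
  circ_records(
    circ_id = df$circ_id, host_gene = df$host_gene, chrom = df$chrom,
    start = start, end = end,
    spliced_length = if ("spliced_length" %in% names(df))
      df$spliced_length else NA_real_
  )
}

#' Read circRNA sponge tables
#'
#' Reads an ENCORI-like circRNA-miRNA interaction TSV (columns matching
#' `circ`, `mirna|mir`, `sites|n_sites|mbs`, and a p-value-bound column
#' matching `p_value|p-value|agoclip`) plus a circRNA annotation table (TSV
#' with `circ_id, host_gene, chrom, start, end[, spliced_length]`, or BED-6
#' with name `circ_id|host_gene`). P-value bounds written as inequalities
#' against powers of ten (e.g. a "less-than-or-equal 10^-12" cell) are
#' parsed to numeric bounds. Every sponge edge must reference an annotated
#' circRNA.
#'
#' @param interaction_path sponge-edge TSV path.
#' @param annotation_path circRNA annotation TSV or BED path.
#' @param coords coordinate dialect of a TSV annotation: `"bed"` (0-based
#'   half-open, default) or `"one_based"` (1-based inclusive, converted).
#' @return list with elements `sponges` and `circs` (tibbles).
#' @export
read_sponge_tables <- function(interaction_path, annotation_path,
                               coords = c("bed", "one_based")) {
  df <- read_tsv_base(interaction_path)
  circ_col <- find_column(df, "circ", "circRNA id", interaction_path)
  mir_col <- find_column(df, c("mirna", "mir"), "miRNA id", interaction_path)
  sites_col <- find_column(df, c("n_sites", "sites", "mbs"),
                           "binding-site count", interaction_path)
  p_col <- find_column(df, c("agoclip", "p.?value", "p_bound"),
                       "AGO-CLIP p-value bound", interaction_path)
  sponges <- sponge_records(
    circ_id = df[[circ_col]],
    mirna_id = df[[mir_col]],
    n_sites = df[[sites_col]],
    agoclip_p_bound = parse_p_bound(df[[p_col]])
  )
  circs <- read_circ_annotation(annotation_path, coords = coords)
  check_sponge_integrity(sponges, circs)
  list(sponges = sponges, circs = circs)
}

#' Read an expression dataset
#'
#' Reads a genes x samples TSV (first column = gene symbol) and a per-sample
#' annotation TSV keyed by `sample_id`, validates annotation levels, and
#' aligns matrix columns to the annotation order.
#'
#' @param matrix_path expression matrix TSV.
#' @param annotation_path annotation TSV.
#' @return `SummarizedExperiment` (see [expression_dataset()]).
#' @export
read_expression_dataset <- function(matrix_path, annotation_path) {
  df <- read_tsv_base(matrix_path)
  if (ncol(df) < 2) {
    cf_abort(paste0(matrix_path, ": expected gene column plus >= 1 sample"),
             "cerna_format_error")
  }
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0) {
      cf_abort(sprintf("%s: non-numeric value at gene '%s', sample '%s'",
                       matrix_path, genes[bad[1]], names(vals)[j]),
               "cerna_format_error")
    }
    if (any(is.na(v))) {
      cf_abort(sprintf("%s: missing expression value at gene '%s', sample '%s'",
                       matrix_path, genes[which(is.na(v))[1]], names(vals)[j]),
               "cerna_format_error")
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  ann <- read_tsv_base(annotation_path)
  expression_dataset(m, ann)
}

#' Read a qPCR Ct table
#'
#' TSV with assays in rows (first column = assay name) and tissues in
#' columns; empty/"NA" cells are missing Ct values.
#'
#' @param path TSV path.
#' @param reference reference assay name (default "GAPDH").
#' @return [ct_table()] object.
#' @export
read_ct_table <- function(path, reference = "GAPDH") {
  df <- read_tsv_base(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  ct_table(m, reference = reference)
}

#' Read an RBP binding-site count table
#'
#' TSV with columns `circ_id`, `role` (candidate/background) and one column
#' per RBP holding non-negative integer site counts.
#'
#' @param path TSV path.
#' @return [rbp_site_table()] object.
#' @export
read_rbp_site_table <- function(path) {
  df <- read_tsv_base(path)
  for (col in c("circ_id", "role")) {
    if (!(col %in% names(df))) {
      cf_abort(paste0(path, ": missing required column '", col, "'"),
               "cerna_format_error")
    }
  }
  m <- as.matrix(df[, setdiff(names(df), c("circ_id", "role")), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$circ_id
  rbp_site_table(m, role = df$role)
}
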