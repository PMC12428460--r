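# Expression-association battery: gene-vs-annotation group comparisons,
# subtype analyses, prevalence tables, feature correlations, and qPCR
# delta-Ct operations. All statistics go through the nonparametric kernel.

#' Extract the log2 expression matrix
#' @param ds expression dataset from [expression_dataset()].
#' @return numeric matrix, genes x samples.
#' @export
expr_matrix <- function(ds) {
  SummarizedExperiment::assay(ds, "log2expr")
}

#' Extract the per-sample annotation as a tibble
#' @param ds expression dataset from [expression_dataset()].
#' @return tibble with a `sample_id` column plus the annotation fields.
#' @export
ann_table <- function(ds) {
  cd <- SummarizedExperiment::colData(ds)
  tb <- tibble::as_tibble(as.data.frame(cd))
  tb$sample_id <- rownames(cd)
  tb
}

# strata filter: named list, e.g. list(who_grade = 2); samples with NA in a
# filtered field are dropped.
filter_samples <- function(ann, strata) {
  keep <- rep(TRUE, nrow(ann))
  for (f in names(strata)) {
    if (!(f %in% names(ann))) {
      cf_abort(sprintf("stratification field '%s' absent from annotation", f),
               "cerna_stratification_error")
    }
    keep <- keep & !is.na(ann[[f]]) & ann[[f]] == strata[[f]]
  }
  ann[keep, , drop = FALSE]
}

get_gene_values <- function(ds, gene, sample_ids) {
  m <- expr_matrix(ds)
  gene <- toupper(gene)
  if (!(gene %in% rownames(m))) {
    cf_abort(sprintf("gene '%s' absent from the expression matrix", gene),
             "cerna_argument_error")
  }
  m[gene, sample_ids]
}

strata_label <- function(strata) {
  if (length(strata) == 0) return("all samples")
  paste(names(strata), unlist(strata), sep = "=", collapse = ", ")
}

#' Compare a gene's expression between two annotation groups
#'
#' Optionally restricts the cohort first (e.g. to WHO grade 2), then splits
#' the remaining samples by an annotation field and compares log2 expression
#' with a Mann-Whitney test. The fold-change is the linear-scale ratio
#' implied by the difference of group medians.
#'
#' @param ds expression dataset ([expression_dataset()]).
#' @param gene gene symbol (matrix row).
#' @param grouping annotation field to split on (e.g. `"recurrent"`).
#' @param case,reference levels of `grouping` defining the case and
#'   reference groups.
#' @param strata named list cohort filter applied before grouping, e.g.
#'   `list(who_grade = 2)`.
#' @param alternative passed to [mann_whitney()] (default two-sided).
#' @return object of class `comparison_result`: gene, grouping, per-group n
#'   and median (log2), `fc` (linear) and `test` ([test_result()]).
#' @export
compare_groups <- function(ds, gene, grouping, case, reference,
                           strata = list(), alternative = "two_sided") {
  ann <- filter_samples(ann_table(ds), strata)
  if (!(grouping %in% names(ann))) {
    cf_abort(sprintf("grouping field '%s' absent from annotation", grouping),
             "cerna_stratification_error")
  }
  ann <- ann[!is.na(ann[[grouping]]), , drop = FALSE]
  ids_case <- ann$sample_id[ann[[grouping]] == case]
  ids_ref <- ann$sample_id[ann[[grouping]] == reference]
  if (length(ids_case) == 0 || length(ids_ref) == 0) {
    cf_abort(sprintf(
      "empty group for %s = %s under filter [%s]", grouping,
      if (length(ids_case) == 0) case else reference, strata_label(strata)),
      "cerna_stratification_error")
  }
  x <- get_gene_values(ds, gene, ids_case)
  y <- get_gene_values(ds, gene, ids_ref)
  structure(list(
    gene = toupper(gene), grouping = grouping,
    case = as.character(case), reference = as.character(reference),
    strata = strata_label(strata),
    n = c(case = length(x), reference = length(y)),
    median_log2 = c(case = median(x), reference = median(y)),
    fc = fc_between_medians(x, y),
    test = mann_whitney(x, y, alternative = alternative)
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s %s vs %s [%s]\n", x$gene, x$grouping, x$case,
              x$reference, x$strata))
  cat(sprintf("  n = %d vs %d; medians (log2) = %.3f vs %.3f; FC = %.3g; p = %s\n",
              x$n[1], x$n[2], x$median_log2[1], x$median_log2[2], x$fc,
              format_p(x$test$p_value)))
  invisible(x)
}

#' Compare a gene's expression across molecular subtypes
#'
#' Kruskal-Wallis test across MenG subtypes (A/B/C) with Dunn's post-hoc
#' pairwise comparisons. Samples without a subtype call are excluded with a
#' message.
#'
#' @param ds expression dataset.
#' @param gene gene symbol.
#' @param strata named list cohort filter (e.g. `list(who_grade = 2)`).
#' @param adjust Dunn adjustment, `"bonferroni"` (default) or `"bh"`.
#' @return list with `gene`, `global` ([test_result()]), `pairwise` (Dunn
#'   tibble augmented with per-pair fold-changes between medians) and
#'   `n_excluded` (unsubtyped samples dropped).
#' @export
compare_subtypes <- function(ds, gene, strata = list(),
                             adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  ann <- filter_samples(ann_table(ds), strata)
  n_excl <- sum(is.na(ann$meng_subtype))
  if (n_excl > 0) message(n_excl, " unsubtyped sample(s) excluded")
  ann <- ann[!is.na(ann$meng_subtype), , drop = FALSE]
  groups <- split(ann$sample_id, ann$meng_subtype)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 3) {
    cf_abort(sprintf("need >= 3 non-empty subtype groups under filter [%s]",
                     strata_label(strata)), "cerna_stratification_error")
  }
  vals <- lapply(groups, function(ids) get_gene_values(ds, gene, ids))
  pw <- dunn_posthoc(vals, adjust = adjust)
  pw$fc <- mapply(function(i, j) fc_between_medians(vals[[i]], vals[[j]]),
                  pw$group_i, pw$group_j)
  list(gene = toupper(gene), strata = strata_label(strata),
       global = kruskal_wallis(vals), pairwise = pw, n_excluded = n_excl)
}

#' Subtype prevalence across strata
#'
#' Tabulates molecular-subtype counts and percentages per stratum (e.g.
#' recurrent vs not recurrent) and runs all pairwise subtype Fisher exact
#' tests on 2x2 tables (subtype i vs j, stratum 1 vs stratum 2).
#' Unsubtyped samples are excluded with a message.
#'
#' @param annotation annotation tibble (from [sample_annotation()] or
#'   `ann_table`-style extraction) with `meng_subtype` and the strata field.
#' @param strata_field annotation field defining the two strata (default
#'   `"recurrent"`).
#' @param cohort named list filter applied first (e.g. `list(who_grade = 2)`).
#' @return object of class `prevalence_result`: `counts` (stratum x subtype
#'   matrix), `percentages` (rows sum to 100), `fisher` (pairwise tibble),
#'   `n_excluded`.
#' @export
subtype_prevalence <- function(annotation, strata_field = "recurrent",
                               cohort = list()) {
  ann <- filter_samples(tibble::as_tibble(annotation), cohort)
  n_excl <- sum(is.na(ann$meng_subtype))
  if (n_excl > 0) message(n_excl, " unsubtyped sample(s) excluded")
  ann <- ann[!is.na(ann$meng_subtype), , drop = FALSE]
  ann <- ann[!is.na(ann[[strata_field]]), , drop = FALSE]
  strata_levels <- sort(unique(as.character(ann[[strata_field]])),
                        decreasing = TRUE)
  if (length(strata_levels) != 2) {
    cf_abort(sprintf("strata field '%s' must have exactly 2 observed levels",
                     strata_field), "cerna_stratification_error")
  }
  subtypes <- c("A", "B", "C")
  counts <- matrix(0L, 2, 3, dimnames = list(strata_levels, subtypes))
  for (s in strata_levels) for (k in subtypes) {
    counts[s, k] <- sum(ann[[strata_field]] == s & ann$meng_subtype == k)
  }
  if (any(rowSums(counts) == 0)) {
    cf_abort("a stratum has no subtyped samples", "cerna_stratification_error")
  }
  pct <- sweep(counts, 1, rowSums(counts), "/") * 100
  pairs <- combn(subtypes, 2)
  fisher <- lapply(seq_len(ncol(pairs)), function(m) {
    i <- pairs[1, m]; j <- pairs[2, m]
    tab <- counts[, c(i, j)]
    res <- tryCatch(fisher_exact(tab),
                    cerna_degenerate_table_error = function(e) NULL)
    tibble::tibble(
      subtype_i = i, subtype_j = j,
      odds_ratio = if (is.null(res)) NA_real_ else res$statistic,
      p_value = if (is.null(res)) NA_real_ else res$p_value)
  })
  structure(list(counts = counts, percentages = pct,
                 fisher = do.call(rbind, fisher), n_excluded = n_excl,
                 strata_field = strata_field),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat("Subtype prevalence by", x$strata_field, "(%):\n")
  print(round(x$percentages, 1))
  invisible(x)
}

#' Correlate a gene with another gene or a numeric annotation field
#'
#' Spearman correlation between a gene's expression and either another
#' gene's expression or a numeric per-sample annotation field (e.g. the
#' Ki-67 proliferation index), over samples passing the cohort filter with
#' both values present.
#'
#' @param ds expression dataset.
#' @param gene_x gene symbol.
#' @param feature_y gene symbol or numeric annotation field name.
#' @param strata named list cohort filter.
#' @return [cor_result()].
#' @export
correlate_features <- function(ds, gene_x, feature_y, strata = list()) {
  ann <- filter_samples(ann_table(ds), strata)
  x <- get_gene_values(ds, gene_x, ann$sample_id)
  m <- expr_matrix(ds)
  if (toupper(feature_y) %in% rownames(m)) {
    y <- get_gene_values(ds, feature_y, ann$sample_id)
  } else if (feature_y %in% names(ann)) {
    y <- ann[[feature_y]]
    if (!is.numeric(y)) {
      cf_abort(sprintf("annotation field '%s' is not numeric", feature_y),
               "cerna_argument_error")
    }
  } else {
    cf_abort(sprintf("'%s' is neither a gene nor an annotation field",
                     feature_y), "cerna_argument_error")
  }
  ok <- is.finite(x) & !is.na(y) & is.finite(y)
  if (sum(ok) < 3) {
    cf_abort("correlation needs >= 3 complete pairs",
             "cerna_undefined_result_error")
  }
  spearman(unname(x[ok]), unname(y[ok]))
}

#' Per-tissue delta-Ct profile
#'
#' `deltaCt = Ct(assay) - Ct(reference)` per tissue; lower delta-Ct means
#' higher expression. Tissues missing either Ct are dropped (never imputed)
#' with a message.
#'
#' @param ct [ct_table()] object.
#' @param assay assay row name.
#' @param reference reference row name; defaults to the table's reference.
#' @return object of class `delta_ct_profile` with the per-tissue values.
#' @export
delta_ct <- function(ct, assay, reference = NULL) {
  if (!inherits(ct, "ct_table")) {
    cf_abort("ct must be a ct_table", "cerna_argument_error")
  }
  if (is.null(reference)) reference <- ct$reference
  if (!(reference %in% rownames(ct$ct))) {
    cf_abort(sprintf("reference assay '%s' absent", reference),
             "cerna_argument_error")
  }
  if (!(assay %in% rownames(ct$ct))) {
    cf_abort(sprintf("assay '%s' absent", assay), "cerna_argument_error")
  }
  a <- ct$ct[assay, ]
  r <- ct$ct[reference, ]
  ok <- !is.na(a) & !is.na(r)
  if (any(!ok)) {
    message(sum(!ok), " tissue(s) dropped for missing Ct values")
  }
  structure(list(assay = assay, reference = reference,
                 dct = (a - r)[ok]),
            class = "delta_ct_profile")
}

#' @export
print.delta_ct_profile <- function(x, ...) {
  cat("deltaCt profile for", x$assay, "(reference:", paste0(x$reference, "):"),
      length(x$dct), "tissues\n")
  invisible(x)
}

#' Correlate two delta-Ct profiles across shared tissues
#'
#' Spearman correlation over tissues present in both profiles. Because both
#' profiles are on the delta-Ct scale (which decreases as expression
#' increases), the sign of the correlation equals the sign of the
#' underlying expression-expression correlation.
#'
#' @param p1,p2 [delta_ct()] profiles.
#' @return [cor_result()].
#' @export
correlate_assays <- function(p1, p2) {
  shared <- intersect(names(p1$dct), names(p2$dct))
  if (length(shared) < 3) {
    cf_abort("correlate_assays needs >= 3 shared tissues",
             "cerna_undefined_result_error")
  }
  spearman(unname(p1$dct[shared]), unname(p2$dct[shared]))
}
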