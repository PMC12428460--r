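# One driver chaining the stages reproducibly from a single YAML config.
# Each stage writes TSV/JSON artifacts; "all" chains
# simulate-or-read -> funnel -> motifs -> express -> qpcr -> report.

#' Load a run configuration
#'
#' Reads a YAML key-value file and fills in the pipeline defaults:
#' `min_targets = 4`, `mbs_rule = "ge_median"`, `fdr_level = 0.10`,
#' two-sided tests, Bonferroni Dunn adjustment, `seed = 1`.
#'
#' @param config path to a YAML file, or a named list.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      cf_abort(paste0("config file not found: ", config), "cerna_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    simulate = FALSE,
    min_targets = 4,
    mbs_rule = "ge_median",
    fdr_level = 0.10,
    alternative = "two_sided",
    dunn_adjust = "bonferroni",
    use_spliced = TRUE,
    seed = 1,
    out_dir = "cerna_out"
  )
  cfg <- utils::modifyList(defaults, config)
  if (!identical(cfg$mbs_rule, "ge_median")) {
    cf_abort("only mbs_rule = 'ge_median' is supported", "cerna_config_error")
  }
  structure(cfg, class = "run_config")
}

read_signature_file <- function(path, name = "signature") {
  if (!file.exists(path)) {
    cf_abort(paste0("signature file not found: ", path), "cerna_format_error")
  }
  genes <- readLines(path, encoding = "UTF-8")
  genes <- trimws(genes[trimws(genes) != ""])
  gene_signature(genes, name = name)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the ceRNA pipeline
#'
#' Executes one stage or the whole chain from a [run_config()]. Inputs are
#' either simulated (when `simulate: true`, from the config's `sim` section
#' passed to [sim_config()]) or read from the configured paths
#' (`signature_path`, `mir_targets_path`, `sponge_path`,
#' `circ_annotation_path`, `expression_path`, `annotation_path`, `ct_path`,
#' `rbp_path`). Every stage writes TSV artifacts plus a JSON summary into
#' `out_dir`; the run log records package version, seed and the full config.
#'
#' @param config path to a YAML config, a named list, or a `run_config`.
#' @param stage one of `"simulate"`, `"funnel"`, `"motifs"`, `"express"`,
#'   `"qpcr"`, `"all"`.
#' @return (invisibly) a list of stage results.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "funnel",
                                           "motifs", "express", "qpcr")) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  log <- list(
    package = "ceRNAfunnel",
    version = as.character(utils::packageVersion("ceRNAfunnel")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = unclass(cfg)
  )

  # --- inputs: simulate or read -------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim_args <- cfg[["sim"]] %||% list()
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    gi <- gen_interactions(scfg)
    signature <- gene_signature(scfg$signature_genes, name = "simulated")
    mir_targets <- gi$mir_targets
    sponges <- gi$sponges
    circs <- gi$circs
    write_tsv_table(mir_targets, file.path(cfg$out_dir, "sim_mir_targets.tsv"))
    write_tsv_table(sponges, file.path(cfg$out_dir, "sim_sponges.tsv"))
    write_tsv_table(circs, file.path(cfg$out_dir, "sim_circ_annotation.tsv"))
    write_json_report(gi$truth, file.path(cfg$out_dir, "sim_ground_truth.json"))
    results$simulate <- gi
    if (stage == "simulate") {
      write_json_report(log, file.path(cfg$out_dir, "run_log.json"))
      return(invisible(results))
    }
  } else {
    signature <- read_signature_file(cfg$signature_path)
    mir_targets <- read_mir_target_table(cfg$mir_targets_path)
    sp <- read_sponge_tables(cfg$sponge_path, cfg$circ_annotation_path)
    sponges <- sp$sponges
    circs <- sp$circs
  }

  # --- funnel --------------------------------------------------------------
  if (stage %in% c("all", "funnel", "motifs")) {
    candidates <- select_candidate_mirnas(mir_targets, signature,
                                          min_targets = cfg$min_targets)
    cand_tbl <- candidates$candidates
    cand_out <- tibble::tibble(
      mirna_id = cand_tbl$mirna_id,
      n_targets = cand_tbl$n_targets,
      targets = vapply(cand_tbl$targets, paste, "", collapse = ","))
    write_tsv_table(cand_out, file.path(cfg$out_dir, "candidate_mirnas.tsv"))

    funnel_summary <- list(n_candidate_mirnas = nrow(cand_tbl),
                           covered_signature_genes =
                             length(candidates$covered_genes))
    results$funnel <- list(candidates = candidates)
    if (nrow(cand_tbl) > 0) {
      cand_circs <- select_candidate_circs(sponges, circs, candidates,
                                           signature)
      if (nrow(cand_circs) > 0) {
        mbs <- compute_mbs(sponges, cand_circs, candidates)
        filt <- filter_by_mbs(mbs)
        circ_out <- mbs$per_circ
        circ_out$retained <- circ_out$circ_id %in% filt$retained
        write_tsv_table(circ_out, file.path(cfg$out_dir, "candidate_circs.tsv"))
        size_cor <- tryCatch(
          correlate_size_mbs(mbs, circs, use_spliced = cfg$use_spliced),
          cerna_undefined_result_error = function(e) NULL)
        funnel_summary <- c(funnel_summary, list(
          n_candidate_circs = nrow(cand_circs),
          cohort_median_mbs = mbs$cohort_median,
          n_retained_circs = filt$n_retained,
          retained_host_genes = filt$host_genes,
          size_mbs_rho = if (is.null(size_cor)) NA else size_cor$rho,
          size_mbs_p = if (is.null(size_cor)) NA
                       else format_p(size_cor$p_value)))
        results$funnel$mbs <- mbs
        results$funnel$filtered <- filt
      }
    }
    write_json_report(funnel_summary,
                      file.path(cfg$out_dir, "funnel_summary.json"))
    if (stage == "funnel") {
      write_json_report(log, file.path(cfg$out_dir, "run_log.json"))
      return(invisible(results))
    }
  }

  # --- motifs --------------------------------------------------------------
  if (stage %in% c("all", "motifs")) {
    retained_ids <- if (!is.null(results$funnel$filtered)) {
      results$funnel$filtered$retained
    } else character()
    graph <- build_tripartite(results$funnel$candidates,
                              sponges[sponges$circ_id %in% retained_ids, ],
                              circs, mir_targets, signature)
    motifs <- enumerate_ffl(graph)
    write_tsv_table(motifs, file.path(cfg$out_dir, "ffl_motifs.tsv"))
    motif_summary <- list(
      n_motifs = nrow(motifs),
      motif_target_genes = sort(unique(motifs$target_gene)),
      n_motif_circs = length(unique(motifs$circ_id)),
      n_motif_mirnas = length(unique(motifs$mirna_id)))
    results$motifs <- list(graph = graph, motifs = motifs)

    if (!is.null(cfg$rbp_path)) {
      rbp <- read_rbp_site_table(cfg$rbp_path)
      enr <- rbp_enrichment(rbp, fdr_level = cfg$fdr_level)
      write_tsv_table(
        enr[, c("rbp", "median_candidate", "median_background", "U",
                "p_value", "p_adjusted", "enriched")],
        file.path(cfg$out_dir, "rbp_enrichment.tsv"))
      motif_summary$enriched_rbps <- enr$rbp[enr$enriched]
      results$motifs$rbp <- enr
    }
    write_json_report(motif_summary,
                      file.path(cfg$out_dir, "motif_summary.json"))
    if (stage == "motifs") {
      write_json_report(log, file.path(cfg$out_dir, "run_log.json"))
      return(invisible(results))
    }
  }

  # --- expression-association battery -------------------------------------
  if (stage %in% c("all", "express")) {
    ds <- NULL
    if (isTRUE(cfg$simulate)) {
      ge <- gen_expression(scfg)
      ds <- ge$dataset
    } else if (!is.null(cfg$expression_path)) {
      ds <- read_expression_dataset(cfg$expression_path, cfg$annotation_path)
    }
    if (!is.null(ds)) {
      gene <- cfg$focus_gene %||% rownames(expr_matrix(ds))[1]
      panels <- list()
      run_panel <- function(id, expr) {
        tryCatch(expr, ceRNAfunnel_error = function(e) {
          list(skipped = conditionMessage(e))
        })
      }
      cmp_json <- function(cmp) list(
        gene = cmp$gene, n = as.list(cmp$n),
        median_log2 = as.list(cmp$median_log2),
        fc = cmp$fc, p_value = cmp$test$p_value)
      panels$grade2_vs_grade1 <- run_panel("g2v1", cmp_json(
        compare_groups(ds, gene, "who_grade", 2, 1,
                       alternative = cfg$alternative)))
      panels$recurrent_vs_not_grade1 <- run_panel("rg1", cmp_json(
        compare_groups(ds, gene, "recurrent", "yes", "no",
                       strata = list(who_grade = 1),
                       alternative = cfg$alternative)))
      panels$recurrent_vs_not_grade2 <- run_panel("rg2", cmp_json(
        compare_groups(ds, gene, "recurrent", "yes", "no",
                       strata = list(who_grade = 2),
                       alternative = cfg$alternative)))
      panels$subtypes_grade2 <- run_panel("sub", {
        st <- compare_subtypes(ds, gene, strata = list(who_grade = 2),
                               adjust = cfg$dunn_adjust)
        list(global_p = st$global$p_value,
             pairwise = as.data.frame(
               st$pairwise[, c("group_i", "group_j", "fc", "p_adjusted")]))
      })
      panels$subtype_prevalence <- run_panel("prev", {
        pr <- subtype_prevalence(ann_table(ds))
        list(percentages = as.data.frame(round(pr$percentages, 1)),
             fisher = as.data.frame(pr$fisher))
      })
      write_json_report(panels,
                        file.path(cfg$out_dir, "expression_report.json"))
      results$express <- panels
    }
    if (stage == "express") {
      write_json_report(log, file.path(cfg$out_dir, "run_log.json"))
      return(invisible(results))
    }
  }

  # --- qPCR ----------------------------------------------------------------
  if (stage %in% c("all", "qpcr")) {
    ct <- NULL
    if (isTRUE(cfg$simulate)) {
      ct <- gen_ct_table(scfg)$ct
    } else if (!is.null(cfg$ct_path)) {
      ct <- read_ct_table(cfg$ct_path, reference = cfg$ct_reference %||% "GAPDH")
    }
    if (!is.null(ct)) {
      assays <- setdiff(rownames(ct$ct), ct$reference)
      profiles <- lapply(assays, function(a) delta_ct(ct, a))
      names(profiles) <- assays
      pairs <- if (length(assays) >= 2) combn(assays, 2) else NULL
      qpcr <- list()
      if (!is.null(pairs)) {
        for (m in seq_len(ncol(pairs))) {
          a <- pairs[1, m]; b <- pairs[2, m]
          cr <- correlate_assays(profiles[[a]], profiles[[b]])
          qpcr[[paste(a, b, sep = "_vs_")]] <-
            list(rho = cr$rho, p_value = cr$p_value, n = cr$n)
        }
      }
      write_json_report(qpcr, file.path(cfg$out_dir, "qpcr_report.json"))
      results$qpcr <- qpcr
    }
  }

  write_json_report(log, file.path(cfg$out_dir, "run_log.json"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
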