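# Seeded generators producing every input the pipeline consumes, with
# planted ground truth: interaction tables with planted feed-forward loops
# and decoys that each fail exactly one funnel criterion; a log2-scale
# expression cohort with planted group shifts, subtype prevalences and
# copula-planted rank correlations; and qPCR Ct tables with planted
# cross-assay Spearman correlation.

default_ffls <- function() {
  list(
    SIG01 = c("hsa-miR-sim1-5p", "hsa-miR-sim2-5p"),
    SIG02 = c("hsa-miR-sim1-5p", "hsa-miR-sim3-3p", "hsa-miR-sim4-5p")
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with defaults that
#' emulate the meningioma study conditions: a two-host feed-forward-loop
#' network with four planted miRNAs; binding-site counts centred on a
#' cohort median of five; a 109-sample cohort split 89/20 between WHO
#' grades 1 and 2 with 7 of 20 grade-2 tumours recurrent; a planted
#' grade-2-vs-1 shift of log2(2.3) and recurrent-within-grade-2 shift of
#' log2(2.95) for PIM1; MenG subtype prevalences (A, B, C) of
#' (0.333, 0.417, 0.25) in not-recurrent and (0, 0.143, 0.857) in recurrent
#' tumours; planted Spearman targets of -0.47 (PIM1 vs NF2) and 0.42 (PIM1
#' vs Ki-67); and a 19-tissue qPCR panel with planted cross-assay rank
#' correlations 0.87 / 0.58 / 0.68.
#'
#' @param seed integer RNG seed; every generator call is fully determined
#'   by its config (same config, same tables, byte-identical).
#' @param signature_genes signature gene symbols.
#' @param planted_ffls named list: host gene -> planted sponging miRNA ids.
#' @param min_targets candidate-miRNA threshold the planted miRNAs must meet.
#' @param n_circ_per_host planted circRNA isoforms per host gene.
#' @param sites_distribution list(min_sites, lambda): planted per-edge
#'   binding-site counts are `min_sites + Poisson(lambda)` (support >= 1).
#' @param n_decoy_mirnas decoy miRNAs with one-too-few signature targets.
#' @param n_offsig_circs decoy circRNAs whose host lies outside the signature.
#' @param n_lowmbs_circs decoy circRNAs with a single 1-site edge (fail only
#'   the median-MBS filter); kept as numerous as the planted circRNAs so the
#'   cohort median always separates the two by construction.
#' @param n_samples named integer vector of cohort cell sizes
#'   (`g1_nr`, `g1_r`, `g2_nr`, `g2_r`).
#' @param expr_genes named genes carried by the expression matrix.
#' @param n_null_genes extra genes with no planted effect (null calibration).
#' @param baseline_log2,expr_sd per-gene baseline and within-group spread of
#'   log2 expression.
#' @param planted_log2_shifts data.frame(gene, stratum, shift) with stratum
#'   in `{"grade2", "recurrent_grade2"}`.
#' @param subtype_prevalences 2x3 matrix (rows `no`/`yes` recurrence,
#'   columns A/B/C) of subtype probabilities; rows must sum to 1.
#' @param subtype_missing_rate fraction of samples left unsubtyped.
#' @param planted_correlations data.frame(x, y, rho) of target Spearman
#'   correlations; `x`/`y` name expression genes or `"ki67_index"`.
#' @param ct_assays assay labels of the Ct table (reference added).
#' @param ct_rho matrix of pairwise target Spearman correlations between
#'   assay delta-Ct profiles.
#' @param n_tissues tissues in the qPCR panel.
#' @param ct_noise_sd per-assay technical noise on the Ct scale (cycles).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       signature_genes = sprintf("SIG%02d", 1:12),
                       planted_ffls = default_ffls(),
                       min_targets = 4,
                       n_circ_per_host = 3,
                       sites_distribution = list(min_sites = 2, lambda = 3),
                       n_decoy_mirnas = 2,
                       n_offsig_circs = 2,
                       n_lowmbs_circs = NULL,
                       n_samples = c(g1_nr = 79, g1_r = 10,
                                     g2_nr = 13, g2_r = 7),
                       expr_genes = c("PIM1", "NF2", "CHEK1"),
                       n_null_genes = 0,
                       baseline_log2 = 8,
                       expr_sd = 0.25,
                       planted_log2_shifts = data.frame(
                         gene = c("PIM1", "PIM1"),
                         stratum = c("grade2", "recurrent_grade2"),
                         shift = c(log2(2.3), log2(2.95))),
                       subtype_prevalences = rbind(
                         no = c(A = 1 / 3, B = 5 / 12, C = 1 / 4),
                         yes = c(A = 0, B = 1 / 7, C = 6 / 7)),
                       subtype_missing_rate = 10 / 109,
                       planted_correlations = data.frame(
                         x = c("PIM1", "PIM1"),
                         y = c("NF2", "ki67_index"),
                         rho = c(-0.47, 0.42)),
                       ct_assays = c("hsa_circ_0076215", "hsa_circ_0076216",
                                     "PIM1"),
                       ct_rho = NULL,
                       n_tissues = 19,
                       ct_noise_sd = 0.25) {
  if (is.null(n_lowmbs_circs)) {
    n_lowmbs_circs <- length(planted_ffls) * n_circ_per_host
  }
  if (is.null(ct_rho)) {
    ct_rho <- matrix(c(1, 0.87, 0.58,
                       0.87, 1, 0.68,
                       0.58, 0.68, 1), 3, 3,
                     dimnames = list(ct_assays, ct_assays))
  }
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  sig <- toupper(cfg$signature_genes)
  hosts <- toupper(names(cfg$planted_ffls))
  if (length(hosts) > 0 && !all(hosts %in% sig)) {
    cf_abort("planted FFL host gene(s) outside the signature",
             "cerna_config_error")
  }
  if (any(cfg$n_samples < 0) ||
      !all(c("g1_nr", "g1_r", "g2_nr", "g2_r") %in% names(cfg$n_samples))) {
    cf_abort("n_samples must name cells g1_nr, g1_r, g2_nr, g2_r",
             "cerna_config_error")
  }
  if (any(abs(rowSums(cfg$subtype_prevalences) - 1) > 1e-6)) {
    cf_abort("subtype prevalence rows must sum to 1", "cerna_config_error")
  }
  if (nrow(cfg$planted_correlations) > 0 &&
      any(abs(cfg$planted_correlations$rho) >= 1)) {
    cf_abort("planted expression correlations must satisfy |rho| < 1",
             "cerna_config_error")
  }
  if (any(abs(cfg$ct_rho) > 1) || any(diag(cfg$ct_rho) != 1)) {
    cf_abort("ct_rho must be a correlation matrix", "cerna_config_error")
  }
  if (cfg$sites_distribution$min_sites < 1) {
    cf_abort("sites_distribution must have support >= 1", "cerna_config_error")
  }
  invisible(cfg)
}

# Spearman target -> latent Pearson correlation under a Gaussian copula
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

# square root of a PSD matrix (tolerates singular, e.g. planted rho = 1)
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    cf_abort("planted correlation matrix is not positive semi-definite",
             "cerna_config_error")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m))
}

draw_sites <- function(n, dist) {
  dist$min_sites + rpois(n, dist$lambda)
}

#' Generate interaction, annotation and sponge tables with planted FFLs
#'
#' Emulates database extracts for the funnel: each planted miRNA receives at
#' least `min_targets` signature targets (including its host gene(s), with
#' filler targets drawn only from non-host signature genes so no accidental
#' motifs arise), each planted host gene receives `n_circ_per_host` circRNA
#' isoforms sponging that host's planted miRNAs. Decoys each fail exactly
#' one funnel criterion: decoy miRNAs have one-too-few signature targets;
#' off-signature circRNAs have a host gene outside the signature; low-MBS
#' circRNAs carry a single 1-site edge and fall below the cohort median.
#'
#' @param cfg [sim_config()].
#' @return list with `mir_targets`, `circs`, `sponges` (tibbles) and
#'   `truth` (planted motifs, candidate miRNAs, decoy ids).
#' @export
gen_interactions <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  sig <- toupper(cfg$signature_genes)
  hosts <- toupper(names(cfg$planted_ffls))
  planted_mirs <- sort(unique(unlist(cfg$planted_ffls, use.names = FALSE)))
  filler_pool <- setdiff(sig, hosts)

  # miRNA -> target records
  mt_mir <- character(); mt_gene <- character()
  for (m in planted_mirs) {
    own_hosts <- hosts[vapply(cfg$planted_ffls,
                              function(v) m %in% v, logical(1))]
    n_fill <- max(0, cfg$min_targets - length(own_hosts))
    fill <- if (n_fill > 0) sample(filler_pool, n_fill) else character()
    tg <- c(own_hosts, fill)
    mt_mir <- c(mt_mir, rep(m, length(tg)))
    mt_gene <- c(mt_gene, tg)
  }
  decoy_mirs <- if (cfg$n_decoy_mirnas > 0) {
    sprintf("hsa-miR-dec%d-3p", seq_len(cfg$n_decoy_mirnas))
  } else character()
  for (m in decoy_mirs) {
    n_tg <- max(1, cfg$min_targets - 1)   # one short of the threshold
    tg <- sample(sig, n_tg)
    mt_mir <- c(mt_mir, rep(m, length(tg)))
    mt_gene <- c(mt_gene, tg)
  }
  mir_targets <- mir_target_records(mt_mir, mt_gene, evidence = "simulated")

  # circRNAs and sponge edges
  circ_id <- host <- character()
  sp_circ <- sp_mir <- character(); sp_sites <- integer()
  truth_rows <- list()
  next_id <- 1000001L
  new_circ <- function() {
    id <- sprintf("hsa_circ_%07d", next_id)
    next_id <<- next_id + 1L
    id
  }
  for (h in hosts) {
    mirs <- cfg$planted_ffls[[h]]
    for (k in seq_len(cfg$n_circ_per_host)) {
      id <- new_circ()
      circ_id <- c(circ_id, id); host <- c(host, h)
      for (m in mirs) {
        sp_circ <- c(sp_circ, id); sp_mir <- c(sp_mir, m)
        sp_sites <- c(sp_sites, draw_sites(1, cfg$sites_distribution))
        truth_rows[[length(truth_rows) + 1]] <-
          tibble::tibble(circ_id = id, mirna_id = m, target_gene = h)
      }
    }
  }
  offsig_ids <- character()
  mir_pool <- if (length(planted_mirs) > 0) planted_mirs else decoy_mirs
  for (k in seq_len(cfg$n_offsig_circs)) {
    id <- new_circ()
    offsig_ids <- c(offsig_ids, id)
    circ_id <- c(circ_id, id)
    host <- c(host, sprintf("OFFSIG%d", k))  # host outside the signature
    if (length(mir_pool) > 0) {
      m <- sample(mir_pool, 1)
      sp_circ <- c(sp_circ, id); sp_mir <- c(sp_mir, m)
      sp_sites <- c(sp_sites, draw_sites(1, cfg$sites_distribution))
    }
  }
  lowmbs_ids <- character()
  if (length(hosts) == 0 && cfg$n_lowmbs_circs > 0) {
    cf_abort("low-MBS decoys need at least one planted host gene",
             "cerna_config_error")
  }
  for (k in seq_len(cfg$n_lowmbs_circs)) {
    id <- new_circ()
    lowmbs_ids <- c(lowmbs_ids, id)
    h <- hosts[1 + (k - 1) %% length(hosts)]
    circ_id <- c(circ_id, id); host <- c(host, h)
    sp_circ <- c(sp_circ, id)
    sp_mir <- c(sp_mir, cfg$planted_ffls[[h]][1])
    sp_sites <- c(sp_sites, 1L)   # below any planted MBS
  }
  # decoy miRNAs also sponge circRNAs (excluded as non-candidates)
  for (m in decoy_mirs) {
    pool <- circ_id[host %in% hosts]
    if (length(pool) == 0) pool <- circ_id
    if (length(pool) == 0) break
    id <- if (length(pool) == 1) pool else sample(pool, 1)
    sp_circ <- c(sp_circ, id); sp_mir <- c(sp_mir, m)
    sp_sites <- c(sp_sites, draw_sites(1, cfg$sites_distribution))
  }

  span <- round(exp(rnorm(length(circ_id), log(1500), 0.5)))
  start <- sample.int(1e8, length(circ_id))
  circs <- circ_records(circ_id = circ_id, host_gene = host,
                        chrom = "chr1", start = start, end = start + span)
  sponges <- sponge_records(sp_circ, sp_mir, sp_sites,
                            agoclip_p_bound = 1e-6)
  truth_motifs <- if (length(truth_rows) > 0) {
    tm <- do.call(rbind, truth_rows)
    tm[order(tm$circ_id, tm$mirna_id), ]
  } else {
    tibble::tibble(circ_id = character(), mirna_id = character(),
                   target_gene = character())
  }
  list(mir_targets = mir_targets, circs = circs, sponges = sponges,
       truth = list(motifs = truth_motifs,
                    candidate_mirnas = planted_mirs,
                    decoy_mirnas = decoy_mirs,
                    offsig_circs = offsig_ids,
                    lowmbs_circs = lowmbs_ids))
}

#' Generate an annotated expression cohort with planted effects
#'
#' Log2-scale expression is drawn directly as
#' `Normal(baseline + planted shifts, expr_sd)` per gene; the normalization
#' step is deliberately skipped because the pipeline contract consumes an
#' already-normalized matrix. MenG subtype labels are drawn from the
#' per-recurrence prevalence rows; Ki-67 and correlated genes share latent
#' Gaussian-copula variables whose Pearson correlation `2 sin(pi rho / 6)`
#' targets the planted Spearman `rho`. Note that planted stratum shifts add
#' mean structure on top of the copula, so cohort-wide rank correlations
#' for shifted genes are attenuated relative to their targets.
#'
#' @param cfg [sim_config()].
#' @return list with `dataset` (a `SummarizedExperiment`, see
#'   [expression_dataset()]) and `truth`.
#' @export
gen_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  ns <- cfg$n_samples
  if (sum(ns) == 0) cf_abort("empty cohort requested", "cerna_config_error")
  grade <- rep(c(1L, 1L, 2L, 2L), ns[c("g1_nr", "g1_r", "g2_nr", "g2_r")])
  recur <- rep(c("no", "yes", "no", "yes"),
               ns[c("g1_nr", "g1_r", "g2_nr", "g2_r")])
  N <- length(grade)
  sample_id <- sprintf("S%03d", seq_len(N))

  genes <- unique(toupper(c(cfg$expr_genes,
                            if (cfg$n_null_genes > 0)
                              sprintf("NULL%04d", seq_len(cfg$n_null_genes)))))

  # latent copula variables for planted correlations
  pc <- cfg$planted_correlations
  vars <- unique(c(pc$x, pc$y))
  Z <- NULL
  if (length(vars) > 0) {
    R <- diag(length(vars))
    dimnames(R) <- list(vars, vars)
    for (i in seq_len(nrow(pc))) {
      r <- spearman_to_pearson(pc$rho[i])
      R[pc$x[i], pc$y[i]] <- R[pc$y[i], pc$x[i]] <- r
    }
    L <- psd_sqrt(R)
    Z <- matrix(rnorm(N * length(vars)), N) %*% t(L)
    colnames(Z) <- vars
  }

  m <- matrix(NA_real_, length(genes), N,
              dimnames = list(genes, sample_id))
  sh <- cfg$planted_log2_shifts
  for (g in genes) {
    z <- if (!is.null(Z) && g %in% colnames(Z)) Z[, g] else rnorm(N)
    mu <- rep(cfg$baseline_log2, N)
    rows <- which(toupper(sh$gene) == g)
    for (i in rows) {
      idx <- switch(sh$stratum[i],
        grade2 = grade == 2L,
        recurrent_grade2 = grade == 2L & recur == "yes",
        grade1 = grade == 1L,
        cf_abort(paste0("unknown shift stratum: ", sh$stratum[i]),
                 "cerna_config_error"))
      mu[idx] <- mu[idx] + sh$shift[i]
    }
    m[g, ] <- mu + cfg$expr_sd * z
  }

  subtype <- character(N)
  for (i in seq_len(N)) {
    p <- cfg$subtype_prevalences[recur[i], ]
    subtype[i] <- sample(c("A", "B", "C"), 1, prob = p)
  }
  n_miss <- round(cfg$subtype_missing_rate * N)
  if (n_miss > 0) subtype[sample.int(N, n_miss)] <- NA_character_

  ki67 <- if (!is.null(Z) && "ki67_index" %in% colnames(Z)) {
    round(exp(1.5 + 0.8 * Z[, "ki67_index"]), 1)  # lognormal %, monotone in z
  } else round(exp(1.5 + 0.8 * rnorm(N)), 1)

  ann <- tibble::tibble(
    sample_id = sample_id,
    who_grade = grade,
    recurrent = recur,
    meng_subtype = subtype,
    chr1p_loss = ifelse(runif(N) < 0.2, "yes", "no"),
    chr22q_loss = ifelse(runif(N) < 0.25, "yes", "no"),
    necrosis = ifelse(runif(N) < 0.15, "yes", "no"),
    ki67_index = ki67
  )
  list(dataset = expression_dataset(m, ann),
       truth = list(shifts = sh, correlations = pc,
                    prevalences = cfg$subtype_prevalences))
}

#' Generate a qPCR Ct table with planted cross-assay correlation
#'
#' The reference assay's Ct is `Normal(18, 1)` per tissue. Assay delta-Ct
#' values are drawn from a Gaussian copula targeting the planted pairwise
#' Spearman correlations (latent Pearson `2 sin(pi rho / 6)`), scaled to a
#' biologically plausible spread, plus `Normal(0, ct_noise_sd)` technical
#' noise; assay Ct is then reference Ct plus delta-Ct, clamped to the
#' instrument range.
#'
#' @param cfg [sim_config()].
#' @return list with `ct` ([ct_table()]) and `truth` (planted rho matrix).
#' @export
gen_ct_table <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_tissues < 3) {
    cf_abort("n_tissues must be >= 3", "cerna_config_error")
  }
  set.seed(cfg$seed + 2L)
  n <- cfg$n_tissues
  assays <- cfg$ct_assays
  R <- spearman_to_pearson(cfg$ct_rho)
  diag(R) <- 1
  L <- psd_sqrt(R)
  Z <- matrix(rnorm(n * length(assays)), n) %*% t(L)
  colnames(Z) <- assays

  tissues <- sprintf("tissue%02d", seq_len(n))
  ref <- rnorm(n, 18, 1)
  dct_mu <- setNames(rep(c(10, 4), length.out = length(assays)), assays)
  ct <- matrix(NA_real_, length(assays) + 1, n,
               dimnames = list(c(assays, "GAPDH"), tissues))
  for (a in assays) {
    dct <- dct_mu[a] + 2 * Z[, a] + rnorm(n, 0, cfg$ct_noise_sd)
    ct[a, ] <- pmin(45, pmax(1e-6, ref + dct))
  }
  ct["GAPDH", ] <- pmin(45, pmax(1e-6, ref))
  list(ct = ct_table(ct, reference = "GAPDH"),
       truth = list(rho = cfg$ct_rho))
}
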