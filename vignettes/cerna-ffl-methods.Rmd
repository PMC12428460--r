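---
title: "Methods: funnel-style ceRNA feed-forward-loop discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: funnel-style ceRNA feed-forward-loop discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAfunnel)
```

## The model

A circRNA is produced by back-splicing of a host gene. If it carries
binding sites for a miRNA that itself represses the host transcript, the
circRNA acts as a competing endogenous RNA (ceRNA) and forms a
*feed-forward loop* (FFL): more circRNA means more miRNA sequestration and
hence less repression of the host. `ceRNAfunnel` searches for such loops
around a user-supplied gene signature by composing three binary relations:

- *targets(m, g)*: miRNA *m* has a validated interaction with gene *g*
  (miRTarBase-like evidence);
- *sponges(c, m, k)*: circRNA *c* carries *k* AGO-CLIP-supported binding
  sites for miRNA *m* (ENCORI-like evidence, with an upper bound on the
  AGO-CLIP region p-value per edge);
- *host(c) = g*: circRNA *c* is spliced from gene *g*.

An FFL is a triple (*c*, *m*, *g*) with *sponges(c, m)*, *targets(m, g)*
and *host(c) = g*, *g* in the signature. Enumeration is exact (it is
checked against a brute-force triple loop in the test suite), so the
scientific content lies entirely in the funnel that decides which nodes
enter the graph.

## The funnel and its parameters

1. **Candidate miRNAs** need at least `min_targets` *distinct* signature
   genes among their validated targets. Default 4 (dimensionless count);
   raising it monotonically shrinks the candidate set.
2. **Candidate circRNAs** must have a signature host gene *and* at least
   one sponge edge to a candidate miRNA.
3. **MBS filter.** The miRNA-binding-site total of a circRNA (MBS) is the
   sum of `n_sites` over its edges to candidate miRNAs. Sites for the
   *same* miRNA count as much as sites for different miRNAs: the
   sponge-capacity reading of the evidence is per site, not per partner,
   and this choice is deliberate (the alternative — counting distinct
   miRNA partners — discards the multiplicity that makes a sponge
   effective). The cohort median of MBS is computed **once**, over all
   candidate circRNAs, and frozen; circRNAs with MBS greater than or equal
   to that median are retained, ties included. The median is not
   re-derived after filtering, so applying the stored filter twice is a
   no-op.
4. **Size–MBS correlation.** Spearman correlation of circRNA size against
   MBS quantifies the expectation that longer molecules expose more
   sites. "Size" prefers the annotated spliced length (nt) and falls back
   to the genomic span `end − start`; which of the two a sponge database's
   site lists reflect is source-dependent, so the preference is an
   explicit flag (`use_spliced`) rather than a hidden assumption.

Coordinates are 0-based half-open internally (the BED convention);
1-based inclusive TSV input is converted on read. Gene symbols are
compared case-insensitively after upper-casing; miRNA identifiers are
compared verbatim because arm and family suffixes are case-meaningful.

## The statistics kernel

Every test in the package runs through one kernel so the statistical
behaviour is auditable and swappable in one place.

- **Mann–Whitney U**: rank sums with average ranks for ties. The p-value
  is exact (enumeration-based null distribution of U) when the pooled
  sample has at most 12 tie-free observations; otherwise a normal
  approximation with tie correction and continuity correction is used.
  The continuity correction can be disabled for cross-checks against
  other implementations. Across all tie-free inputs with pooled n ≤ 10
  the approximate one-sided p stays within 0.05 of the exact value; the
  two-sided gap can reach 0.09 at pooled n of 4–5, which is one reason
  the exact path exists.
- **Kruskal–Wallis** with the standard tie correction; an input in which
  every value is identical returns H = 0, p = 1 rather than 0/0.
- **Dunn's post-hoc** pairwise z-tests on mean ranks with the
  tie-corrected pooled variance. The multiplicity adjustment defaults to
  Bonferroni — the conservative choice commonly paired with Dunn's test in
  point-and-click statistics software — with Benjamini–Hochberg available
  by flag, since the appropriate adjustment is genuinely a user decision.
- **Fisher's exact test** on 2×2 tables: two-sided p by the
  minimum-likelihood rule (sum of hypergeometric probabilities not
  exceeding that of the observed table). The reported statistic is the
  *sample* odds ratio, with 0 and infinity allowed; a zero margin is a
  degenerate-table error rather than a silent p = 1.
- **Spearman correlation** is the Pearson correlation of average ranks.
  For n ≤ 8 without ties the two-sided p is the exact fraction of all n!
  pairings with |rho| at least as large as observed; otherwise the t
  approximation on n − 2 degrees of freedom.
- **Fold-change between medians**: for log2-scale expression,
  `FC = 2^(median(x) − median(y))`. FC is always reported on the linear
  scale; since the input matrix is itself log2 of normalized data, the
  difference-of-medians back-transforms to a ratio of (median)
  expression levels, which is the interpretable quantity.
- Reported p-values are clamped at 1e-300 and rendered `< 1e-300` in
  reports; a literal zero would misrepresent an enumeration or a normal
  tail.

Group comparisons are two-sided by default. Directional claims (e.g. a
case group being *up*-regulated) are post-hoc descriptions of where the
medians fell, not one-sided tests — with one exception: the RBP enrichment
screen is one-sided (candidate counts greater), because the screened
hypothesis is explicitly directional. There, p-values are
Benjamini–Hochberg-adjusted across RBPs and flagged at FDR 10% by default.
Background circRNAs for that screen should be size-matched; the bundled
helper samples them within ±20% of the mean candidate size under a fixed
seed.

The expression battery always filters the cohort first (e.g. restrict to
WHO grade 2) and then splits by the grouping variable, mirroring the
panel structure of stratified clinical analyses. Samples with missing
annotation are dropped per comparison with logged counts, never imputed.
A correlation against a constant feature (zero rank variance) is an
explicit undefined-result error. Correlations with p-values at or above
0.05 are reported as raw numbers without any significance label.

## What the synthetic-data generators emulate

`sim_config()` defaults encode the motivating study conditions:

- a two-host FFL network with four planted miRNAs, three circRNA isoforms
  per host, and per-edge binding-site counts `2 + Poisson(3)` (support
  ≥ 2, median near five — matching a cohort whose median MBS is five);
- decoys that each violate **exactly one** funnel rule — a miRNA with
  one-too-few signature targets, a circRNA hosted outside the signature,
  and a circRNA with a single 1-site edge. The low-MBS decoys are kept as
  numerous as the planted circRNAs so the cohort median always falls
  between the 1-site decoys and the planted isoforms, making planted-motif
  recovery exact by construction (precision = recall = 1);
- a 109-sample cohort: 89 WHO grade 1 (10 recurrent) and 20 grade 2 (7
  recurrent), with roughly 9% of samples unsubtyped;
- log2 expression drawn directly as Normal(8, 0.25) per gene — the
  normalization step is skipped on purpose, because the pipeline contract
  consumes an already-normalized matrix and generating on the final scale
  keeps recovery tests analytic and fast. A within-group spread of 0.25
  on the log2 scale is a realistic figure for a moderately expressed gene
  after variance-stabilizing normalization;
- planted shifts log2(2.3) (grade 2 vs 1) and log2(2.95) (recurrent
  within grade 2) on PIM1; MenG subtype prevalences (A, B, C) of
  (1/3, 5/12, 1/4) in not-recurrent and (0, 1/7, 6/7) in recurrent
  tumours;
- rank correlations planted through a Gaussian copula: a target Spearman
  rho is converted to the latent Pearson correlation 2·sin(π·rho/6), and
  monotone marginal transforms (e.g. the lognormal Ki-67 index) preserve
  it. Defaults: −0.47 (PIM1 vs NF2) and 0.42 (PIM1 vs Ki-67) in the
  cohort, and 0.87 / 0.58 / 0.68 among the ΔCt profiles of a 19-tissue
  qPCR panel with 0.25 cycles of technical noise.

Two caveats the tests make explicit. First, planted stratum shifts add
mean structure on top of the copula, so cohort-wide rank correlations for
shifted genes come out attenuated relative to their targets; correlation
recovery is therefore validated on configurations without shifts. Second,
the sample Spearman coefficient is biased slightly toward zero at n = 19
(median recovered rho ≈ 0.85 for a planted 0.87), so recovery within
±0.15 of the planted value succeeds in about 90% of replicates, not
essentially always — the recovery criterion sits deliberately at that
boundary.

What the generators do **not** emulate: realistic genomic coordinates or
sequence content, count-level RNA-seq noise (and hence normalization
artifacts), confounding between clinical covariates, batch structure, or
missing expression values. Passing recovery tests therefore demonstrates
that the pipeline's logic and statistics are correct under the stated
model, not that the model captures every property of real cohorts.

## Numerical and degenerate-input choices

- Exactness thresholds (Mann–Whitney pooled n ≤ 12; Spearman n ≤ 8) trade
  enumeration cost against approximation error and are fixed, not
  data-driven.
- The copula square root uses an eigen decomposition with negative
  eigenvalues clamped at zero, so a planted correlation of exactly 1
  (a singular but valid PSD matrix) is accepted; an indefinite matrix is
  a config error.
- Ct values are validated into (0, 45] (cycles); ΔCt is computed only
  where both assay and reference Ct are present.
- All randomness flows from a single integer seed per config; identical
  configs produce byte-identical tables.

## Validation problem sizes

The test suite validates: the bundled CHEK1/PIM1 network end to end;
motif-enumeration equivalence to brute force on random graphs of up to 30
nodes; exact-enumeration equivalence for Mann–Whitney (all tie-free
configurations with pooled n ≤ 10), Fisher (random tables with margins
≤ 15) and Spearman (n ≤ 8); a 10,000-replicate null calibration of the
two-sided Mann–Whitney test at the 5% level; planted-FFL recovery over
100 simulated databases; fold-change-2.95 recovery over 200 simulated
cohorts at n = 7 vs 12; and Spearman-0.87 recovery over 500 simulated
19-tissue panels. These sizes keep the whole suite at about a minute on a
single CPU while leaving Monte-Carlo error well inside the asserted
bounds.

## Known limitations

- The funnel consumes database extracts as given; it neither predicts
  binding sites from sequence nor re-scores AGO-CLIP evidence.
- Headline counts obtained against live interaction databases depend on
  database versions and are not reproducible offline; the bundled network
  is the fixed worked example used for verification.
- The RBP screen's background set is the caller's responsibility; the
  size-matching helper implements one reasonable convention (±20% of mean
  candidate size), not a canonical definition.
- The expression battery covers group comparisons, subtype prevalence and
  correlations; survival modelling and mutation-flag associations are out
  of scope.
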