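# Self-contained nonparametric test kernel. Every downstream stage calls
# through these functions so the pipeline's statistics are auditable in one
# place. Exact small-sample paths use enumeration-based null distributions;
# large-sample paths use the standard tie-corrected approximations.

#' Hypothesis-test result
#'
#' Container returned by the nonparametric test kernel.
#'
#' @param statistic test statistic.
#' @param p_value p-value, clamped to `[1e-300, 1]`.
#' @param method label describing the test.
#' @param n_per_group integer vector of group sizes.
#' @param exact `TRUE` only when the p-value comes from enumeration of the
#'   exact null distribution.
#' @return an object of class `cerna_test`.
#' @export
test_result <- function(statistic, p_value, method, n_per_group, exact) {
  structure(
    list(statistic = unname(statistic), p_value = p_clamp(p_value),
         method = method, n_per_group = as.integer(n_per_group),
         exact = isTRUE(exact)),
    class = "cerna_test"
  )
}

#' @export
print.cerna_test <- function(x, ...) {
  cat(x$method, if (x$exact) "(exact)" else "(approximate)", "\n")
  cat("  statistic =", signif(x$statistic, 6),
      " p =", format_p(x$p_value),
      " n =", paste(x$n_per_group, collapse = "/"), "\n")
  invisible(x)
}

#' Correlation result
#'
#' @param rho Spearman rank-correlation coefficient in `[-1, 1]`.
#' @param p_value p-value.
#' @param n number of paired observations.
#' @param exact whether `p_value` comes from exact permutation enumeration.
#' @return object of class `cerna_cor`.
#' @export
cor_result <- function(rho, p_value, n, exact = FALSE) {
  stopifnot(abs(rho) <= 1 + 1e-12)
  structure(
    list(rho = unname(min(max(rho, -1), 1)), p_value = p_clamp(p_value),
         n = as.integer(n), exact = isTRUE(exact)),
    class = "cerna_cor"
  )
}

#' @export
print.cerna_cor <- function(x, ...) {
  cat("Spearman correlation: rho =", signif(x$rho, 4),
      " p =", format_p(x$p_value), " n =", x$n,
      if (x$exact) "(exact permutation p)" else "", "\n")
  invisible(x)
}

check_sample <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1) {
    cf_abort(sprintf("'%s' must be a non-empty numeric vector", name),
             "cerna_argument_error")
  }
  if (any(!is.finite(x))) {
    cf_abort(sprintf("'%s' contains non-finite values", name),
             "cerna_argument_error")
  }
}

tie_sum <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' The U statistic is computed from rank sums with average ranks for ties.
#' When the pooled sample is small (`n1 + n2 <= 12`) and tie-free, the
#' p-value is exact (enumeration-based null distribution of U); otherwise a
#' normal approximation with tie correction and (by default) continuity
#' correction is used. The reported statistic is U for the `x` sample.
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger),
#'   or `"less"`.
#' @param continuity apply the continuity correction on the approximate path.
#' @return [test_result()].
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two_sided", "greater", "less"),
                         continuity = TRUE) {
  alternative <- match.arg(alternative)
  check_sample(x, "x"); check_sample(y, "y")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0

  if (!has_ties && N <= 12) {
    # exact null distribution of U (all rank assignments equally likely)
    p_greater <- pwilcox(u1 - 1, n1, n2, lower.tail = FALSE)
    p_less <- pwilcox(u1, n1, n2)
    p <- switch(alternative,
      two_sided = min(1, 2 * min(p_greater, p_less)),
      greater = p_greater,
      less = p_less)
    return(test_result(u1, p, "Mann-Whitney U test", c(n1, n2), exact = TRUE))
  }

  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_sum(r) / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all pooled values identical: no evidence against the null
    return(test_result(u1, 1, "Mann-Whitney U test", c(n1, n2), exact = FALSE))
  }
  d <- u1 - mu
  cc <- if (continuity) {
    switch(alternative,
      two_sided = sign(d) * 0.5,
      greater = 0.5,
      less = -0.5)
  } else 0
  z <- (d - cc) / sqrt(sigma2)
  p <- switch(alternative,
    two_sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z))
  test_result(u1, min(1, p), "Mann-Whitney U test", c(n1, n2), exact = FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic over three or more groups with a chi-square
#' reference distribution on `k - 1` degrees of freedom. A degenerate input
#' in which every pooled value is identical returns `H = 0`, `p = 1`.
#'
#' @param groups list of (at least 3) non-empty numeric vectors.
#' @return [test_result()].
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    cf_abort("kruskal_wallis needs >= 3 groups (use mann_whitney for 2)",
             "cerna_argument_error")
  }
  for (i in seq_along(groups)) check_sample(groups[[i]], paste0("groups[[", i, "]]"))
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups, use.names = FALSE))
  idx <- rep(seq_along(groups), n)
  Ri <- tapply(r, idx, sum)
  h_raw <- 12 / (N * (N + 1)) * sum(Ri^2 / n) - 3 * (N + 1)
  corr <- 1 - tie_sum(r) / (N^3 - N)
  if (corr <= 0) {
    return(test_result(0, 1, "Kruskal-Wallis test", n, exact = FALSE))
  }
  h <- h_raw / corr
  p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  test_result(h, p, "Kruskal-Wallis test", n, exact = FALSE)
}

#' Dunn's post-hoc test
#'
#' Pairwise z comparisons of mean ranks following a Kruskal-Wallis test,
#' using the tie-corrected pooled rank variance
#' `N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values are
#' adjusted across all pairs (Bonferroni by default, Benjamini-Hochberg by
#' flag).
#'
#' @param groups list of (>= 3) non-empty numeric vectors, optionally named.
#' @param adjust `"bonferroni"` (default) or `"bh"`.
#' @return a [tibble::tibble] with one row per group pair: `group_i`,
#'   `group_j`, mean ranks, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 3) {
    cf_abort("dunn_posthoc needs >= 3 groups", "cerna_argument_error")
  }
  for (i in seq_along(groups)) check_sample(groups[[i]], paste0("groups[[", i, "]]"))
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups, use.names = FALSE))
  idx <- rep(seq_len(k), n)
  rbar <- tapply(r, idx, mean)
  sigma2 <- N * (N + 1) / 12 - tie_sum(r) / (12 * (N - 1))
  pairs <- combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    z[m] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[m] <- 2 * pnorm(-abs(z[m]))
  }
  p_adj <- p.adjust(p, method = if (adjust == "bh") "BH" else "bonferroni")
  tibble::tibble(
    group_i = labels[pairs[1, ]],
    group_j = labels[pairs[2, ]],
    mean_rank_i = unname(rbar[pairs[1, ]]),
    mean_rank_j = unname(rbar[pairs[2, ]]),
    z = z,
    p_value = p_clamp(p),
    p_adjusted = p_clamp(p_adj)
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table. The reported
#' statistic is the sample odds ratio (`Inf` and `0` allowed).
#'
#' @param tab 2x2 matrix (or coercible) of non-negative integer counts.
#' @return [test_result()] with `statistic` = sample odds ratio.
#' @examples
#' fisher_exact(matrix(c(3, 0, 0, 3), 2))  # p = 0.1
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    cf_abort("fisher_exact needs a 2x2 table of non-negative integers",
             "cerna_argument_error")
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    cf_abort("fisher_exact: a table margin is zero (degenerate table)",
             "cerna_degenerate_table_error")
  }
  a <- tab[1, 1]
  support <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  probs <- dhyper(support, cs[1], cs[2], rs[1])
  p_obs <- dhyper(a, cs[1], cs[2], rs[1])
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  test_result(or, min(1, p), "Fisher exact test",
              n_per_group = rs, exact = TRUE)
}

# all permutations of a vector, one row each (n! x n); used for the exact
# Spearman null. n is capped upstream at 8 (40320 rows).
perm_matrix <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- perm_matrix(v[-i])
    out[[i]] <- cbind(v[i], sub)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average (tie-aware) ranks. For `n <= 8`
#' with no ties in either vector the two-sided p-value is exact: the
#' fraction of all `n!` pairings with `|rho|` at least as large as observed.
#' Otherwise the t approximation on `n - 2` degrees of freedom is used.
#'
#' @param x,y paired numeric vectors, `length >= 3`, finite.
#' @return [cor_result()].
#' @export
spearman <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  if (length(x) != length(y)) {
    cf_abort("x and y must have equal length", "cerna_argument_error")
  }
  n <- length(x)
  if (n < 3) cf_abort("spearman needs n >= 3 pairs", "cerna_argument_error")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    cf_abort("spearman undefined: zero variance in a vector",
             "cerna_undefined_result_error")
  }
  rho <- stats::cor(rx, ry)
  no_ties <- anyDuplicated(x) == 0 && anyDuplicated(y) == 0
  if (n <= 8 && no_ties) {
    perms <- perm_matrix(ry)
    s <- perms %*% rx
    mu <- mean(rx); s2 <- (n - 1) * stats::sd(rx)^2  # rx, ry share moments (1..n)
    rho_all <- (s - n * mu * mu) / s2
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    return(cor_result(rho, p, n, exact = TRUE))
  }
  if (abs(rho) >= 1) {
    return(cor_result(rho, 1e-300, n, exact = FALSE))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  cor_result(rho, p, n, exact = FALSE)
}

#' Fold-change between group medians
#'
#' For log2-scale expression values, the linear-scale ratio implied by the
#' difference of group medians: `2^(median(x) - median(y))`, with `x` the
#' case group and `y` the reference group.
#'
#' @param x_log2,y_log2 numeric vectors on the log2 scale.
#' @return positive scalar fold-change.
#' @export
fc_between_medians <- function(x_log2, y_log2) {
  check_sample(x_log2, "x_log2"); check_sample(y_log2, "y_log2")
  2^(median(x_log2) - median(y_log2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' adjusted values are never below the raw ones.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    cf_abort("bh_adjust: p-values must be numeric in [0, 1]",
             "cerna_argument_error")
  }
  p.adjust(p, method = "BH")
}
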