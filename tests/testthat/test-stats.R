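# Nonparametric test kernel: frozen worked examples plus cross-checks
# against base R and brute-force enumeration oracles.

test_that("mann_whitney matches hand-computed exact examples", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(res$exact)

  # identical multisets: maximal overlap, no evidence
  res2 <- mann_whitney(c(5, 7, 9), c(5, 7, 9))
  expect_equal(res2$p_value, 1)

  # one-sided directions are complementary around the same U
  lo <- mann_whitney(c(1, 2), c(3, 4), alternative = "less")
  hi <- mann_whitney(c(1, 2), c(3, 4), alternative = "greater")
  expect_lt(lo$p_value, hi$p_value)
})

test_that("U_x + U_y = n1 * n2 on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    ux <- mann_whitney(x, y)$statistic
    uy <- mann_whitney(y, x)$statistic
    expect_equal(ux + uy, length(x) * length(y))
  }
})

test_that("mann_whitney agrees with wilcox.test on both paths", {
  set.seed(7)
  # exact path (tie-free, small)
  for (i in 1:10) {
    x <- sample(1:50, 4); y <- sample(setdiff(1:50, x), 5)
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # approximate path (larger, with ties)
  for (i in 1:10) {
    x <- sample(1:8, 15, replace = TRUE); y <- sample(1:8, 18, replace = TRUE)
    expect_equal(
      mann_whitney(x, y)$p_value,
      suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value),
      tolerance = 1e-12)
  }
})

test_that("mann_whitney rejects degenerate input", {
  expect_error(mann_whitney(numeric(0), 1:3), class = "cerna_argument_error")
  expect_error(mann_whitney(c(1, NA), 1:3), class = "cerna_argument_error")
})

test_that("kruskal_wallis matches the rank formula and base R", {
  # three equal groups: H = 0, p = 1
  eq <- kruskal_wallis(list(c(7, 7), c(7, 7), c(7, 7)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # frozen oracle value for [1,2],[3,4],[5,6]:
  # 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 with N = 6 gives 32/7
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(res$statistic, unname(kruskal.test(g)$statistic),
               tolerance = 1e-12)

  # rank invariance under adding a constant
  shifted <- lapply(g, `+`, 100)
  expect_equal(kruskal_wallis(shifted)$statistic, res$statistic)

  # tie-corrected path agrees with base R
  set.seed(11)
  gt <- replicate(3, sample(1:4, 6, replace = TRUE), simplify = FALSE)
  expect_equal(kruskal_wallis(gt)$statistic,
               unname(kruskal.test(gt)$statistic), tolerance = 1e-12)

  expect_error(kruskal_wallis(list(1:3, 4:6)), class = "cerna_argument_error")
})

test_that("dunn_posthoc has C(k,2) rows, adjusted >= raw, identity on ties", {
  same <- dunn_posthoc(list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1)))
  expect_equal(nrow(same), 3)
  expect_true(all(same$p_adjusted == 1))

  set.seed(3)
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2), d = rnorm(6))
  pw <- dunn_posthoc(g)
  expect_equal(nrow(pw), choose(4, 2))
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-15))

  # hand check of one z against the tie-corrected pooled-variance formula
  r <- rank(unlist(g)); n <- lengths(g); N <- sum(n)
  rbar <- tapply(r, rep(seq_along(g), n), mean)
  s2 <- N * (N + 1) / 12
  z_ab <- (rbar[1] - rbar[2]) / sqrt(s2 * (1 / n[1] + 1 / n[2]))
  expect_equal(pw$z[pw$group_i == "a" & pw$group_j == "b"], unname(z_ab),
               tolerance = 1e-12)
})

test_that("fisher_exact matches enumeration and base R on small margins", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  res <- fisher_exact(matrix(c(3, 0, 0, 3), 2))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$statistic, Inf)

  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(sample(0:7, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_exact(tab)
    expect_equal(mine$p_value, oracle_fisher(tab), tolerance = 1e-10)
    expect_equal(mine$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 2, 3), 2)),
               class = "cerna_degenerate_table_error")
})

test_that("hypergeometric table probabilities sum to one", {
  tab <- matrix(c(4, 2, 3, 6), 2)
  rs <- rowSums(tab); cs <- colSums(tab)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  expect_equal(sum(dhyper(support, cs[1], cs[2], rs[1])), 1, tolerance = 1e-12)
})

test_that("spearman matches frozen examples and symmetries", {
  res <- spearman(1:5, 2 * (1:5) + 3)
  expect_equal(res$rho, 1)

  # tie-aware rho: y-ranks (1,2,3.5,5,3.5), rho = 8/sqrt(95)
  res2 <- spearman(c(1, 2, 3, 4, 5), c(5, 6, 7, 8, 7))
  expect_equal(res2$rho, 8 / sqrt(95), tolerance = 1e-12)
  expect_equal(round(res2$rho, 4), 0.8208)

  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(spearman(x, y)$rho, spearman(y, x)$rho)
    expect_equal(spearman(x, -y)$rho, -spearman(x, y)$rho)
  }
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)),
               class = "cerna_undefined_result_error")
  expect_error(spearman(1:2, 1:2), class = "cerna_argument_error")
})

test_that("spearman exact p agrees with cor.test on tie-free samples", {
  set.seed(13)
  for (n in c(5, 6, 7)) {
    for (i in 1:5) {
      x <- sample(100, n); y <- sample(100, n)
      mine <- spearman(x, y)
      expect_true(mine$exact)
      ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                       exact = TRUE)$p.value)
      expect_equal(mine$p_value, min(1, ref), tolerance = 1e-9)
    }
  }
})

test_that("fold-change between medians follows its definition", {
  expect_equal(fc_between_medians(c(3, 3, 3), c(1, 1, 1)), 4)
  expect_equal(fc_between_medians(1:5, 1:5), 1)
  x <- c(2, 2 + log2(2.95), 2 + 2 * log2(2.95))
  expect_equal(fc_between_medians(x, rep(2, 3)), 2.95, tolerance = 1e-12)
  expect_error(fc_between_medians(numeric(0), 1), class = "cerna_argument_error")
})

test_that("bh_adjust applies the step-up rule", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "cerna_argument_error")
})
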