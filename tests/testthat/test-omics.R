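sig10 <- gene_signature(paste0("E", 1:10), paste0("M", 1:10))

sample_vec <- function(e_vals, m_vals) {
  setNames(c(e_vals, m_vals), c(paste0("E", seq_along(e_vals)),
                                paste0("M", seq_along(m_vals))))
}

test_that("signature construction enforces disjoint lists of >= 2 genes", {
  expect_error(gene_signature(c("A", "B"), c("B", "C")), "disjoint")
  expect_error(gene_signature("A", c("B", "C")), ">= 2")
  sig <- read_signature()
  expect_true(length(sig$epithelial) >= 2 && length(sig$mesenchymal) >= 2)
})

test_that("KS score anchors: identical distributions score 0, full separation 1", {
  sig5 <- gene_signature(paste0("E", 1:5), paste0("M", 1:5))
  x <- sample_vec(1:5, 1:5)
  s0 <- ks_emt_score(x, sig5)
  expect_equal(s0$score, 0)
  expect_equal(s0$hypothesis, "null")
  up <- ks_emt_score(sample_vec(rnorm(10), rnorm(10) + 50), sig10)
  expect_equal(up$score, 1)            # all M genes above all E genes
  expect_equal(up$hypothesis, "M-dominant")
  dn <- ks_emt_score(sample_vec(rnorm(10) + 50, rnorm(10)), sig10)
  expect_equal(dn$score, -1)
  expect_equal(dn$hypothesis, "E-dominant")
  expect_error(ks_emt_score(sample_vec(1:9, 1:10)[-1], sig10), "absent")
})

test_that("signed score equals the brute-force CDF-gap oracle on small vectors", {
  e <- c(1, 2, 3); m <- c(4, 5, 6)
  grid <- sort(unique(c(e, m)))
  gap <- max(vapply(grid, function(g) mean(e <= g) - mean(m <= g), numeric(1)))
  sig3 <- gene_signature(c("E1", "E2", "E3"), c("M1", "M2", "M3"))
  s <- ks_emt_score(setNames(c(e, m), c("E1", "E2", "E3", "M1", "M2", "M3")),
                    sig3, alpha = 1)
  expect_equal(s$score, gap)
  expect_equal(s$score, 1)
})

test_that("score magnitude matches the reference two-sample KS statistic", {
  set.seed(23)
  for (i in 1:100) {
    e <- rnorm(sample(5:30, 1))
    m <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2))
    sig <- gene_signature(paste0("E", seq_along(e)), paste0("M", seq_along(m)))
    x <- setNames(c(e, m), c(paste0("E", seq_along(e)), paste0("M", seq_along(m))))
    s <- ks_emt_score(x, sig, alpha = 1)  # always pick a side: magnitude check
    D <- suppressWarnings(ks.test(e, m)$statistic)
    expect_equal(abs(s$score), unname(D), tolerance = 1e-12)
  }
})

test_that("scores are bounded and invariant to constant shifts and gene order", {
  set.seed(5)
  for (i in 1:50) {
    x <- sample_vec(rnorm(10), rnorm(10, sd = 2))
    s <- ks_emt_score(x, sig10)
    expect_true(abs(s$score) <= 1)
    expect_equal(ks_emt_score(x + 7.3, sig10)$score, s$score)
    expect_equal(ks_emt_score(x[sample(names(x))], sig10)$score, s$score)
  }
})

test_that("matrix scoring separates synthetic phenotype blocks", {
  co <- generate_expression(cohort_spec(n_epithelial = 30, n_hybrid = 30,
                                        n_mesenchymal = 30, separation = 3,
                                        seed = 12))
  sig <- gene_signature(co$spec$epithelial_genes, co$spec$mesenchymal_genes)
  st <- score_matrix(co$expression, sig, groups = co$labels)
  by_class <- split(st$scores$score, co$labels)
  expect_lt(mean(by_class$epithelial), 0)
  expect_gt(mean(by_class$mesenchymal), 0)
  expect_lt(max(by_class$epithelial), min(by_class$mesenchymal))
  # permuting gene columns leaves all scores unchanged
  perm <- sample(ncol(co$expression))
  st2 <- score_matrix(co$expression[, perm], sig)
  expect_equal(st2$scores$score, st$scores$score)
  # EMT-induced (mesenchymal-shifted) group scores higher than control
  cmp <- st$group_comparisons
  em <- cmp[cmp$group_1 == "epithelial" & cmp$group_2 == "mesenchymal", ]
  expect_gt(em$mean_2, em$mean_1)
  expect_lt(em$p_value, 1e-6)
})

test_that("gene-level beta is the arithmetic CpG mean with validation", {
  expect_equal(mean_beta(c(1, 1, 1)), 1)
  expect_equal(mean_beta(c(0, 1)), 0.5)
  set.seed(3)
  b <- runif(17)
  expect_equal(mean_beta(b), sum(b) / length(b))
  expect_true(mean_beta(b) >= 0 && mean_beta(b) <= 1)
  expect_equal(mean_beta(rev(b)), mean_beta(b))
  expect_error(mean_beta(numeric(0)), "empty")
  expect_error(mean_beta(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("expression-methylation correlation recovers known relations", {
  x <- seq(-3, 3, length.out = 50)
  r <- expression_methylation_correlation(x, -x)
  expect_equal(r$r, -1)
  set.seed(8)
  ind <- expression_methylation_correlation(rnorm(500), runif(500))
  expect_lt(abs(ind$r), 0.1)
  flat <- expression_methylation_correlation(x, rep(0.5, 50))
  expect_true(flat$undefined)
  expect_error(expression_methylation_correlation(1:5, 1:4), "unpaired")
})
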