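test_that("parameter sampling is reproducible and respects its ranges", {
  topo <- racipe_topology("klf4")
  p1 <- sample_parameters(topo, seed = 11)
  p2 <- sample_parameters(topo, seed = 11)
  expect_identical(p1, p2)
  r <- default_sampling_ranges()
  draws <- lapply(1:300, function(s) sample_parameters(topo, r, seed = s))
  g <- unlist(lapply(draws, `[[`, "g"))
  k <- unlist(lapply(draws, `[[`, "k"))
  hills <- unlist(lapply(draws, function(p) p$edges$hill))
  lams <- unlist(lapply(draws, function(p) p$edges$lambda))
  types <- rep(topo$edges$type, length(draws))
  expect_true(all(g >= 1 & g <= 100) && all(k >= 0.1 & k <= 1))
  expect_true(all(hills %in% 1:6))
  expect_true(all(lams[types == 2] > 0 & lams[types == 2] <= 1))
  expect_true(all(lams[types == 1] >= 1 & lams[types == 1] <= 100))
  expect_error(sample_parameters(topo, ranges = list(production = c(1, 100))),
               "missing")
})

test_that("half-functional rule centres thresholds on the regulator median level", {
  topo <- racipe_topology("klf4")
  draws <- lapply(1:400, function(s) sample_parameters(topo, seed = 1000 + s))
  med_unreg <- median(unlist(lapply(draws, function(p) p$g / p$k)))
  thr_centre <- median(unlist(lapply(draws, function(p) p$edges$threshold)))
  expect_lt(abs(thr_centre - med_unreg) / med_unreg, 0.2)
})

test_that("over/down-expression perturbations act only on the production rate", {
  topo <- racipe_topology("klf4")
  p <- sample_parameters(topo, seed = 3)
  expect_equal(perturb_production(p, "KLF4", 1, "OE"), p)  # fold 1 is identity
  oe <- perturb_production(p, "KLF4", 10, "OE")
  expect_equal(oe$g[["KLF4"]], 10 * p$g[["KLF4"]])
  expect_equal(oe$k, p$k); expect_equal(oe$edges, p$edges)
  back <- perturb_production(oe, "KLF4", 10, "DE")
  expect_equal(back, p)
  expect_error(perturb_production(p, "NOSUCH", 10, "OE"), "unknown node")
  expect_error(perturb_production(p, "KLF4", 0.5, "OE"), "fold")
})

test_that("small ensembles are reproducible fixed-point collections", {
  topo <- racipe_topology("klf4")
  e1 <- collect_ensemble(topo, n_params = 40, n_init = 10, seed = 5,
                         t_max = 150, dt = 0.04)
  e2 <- collect_ensemble(topo, n_params = 40, n_init = 10, seed = 5,
                         t_max = 150, dt = 0.04)
  expect_identical(e1$states, e2$states)
  expect_lt(verify_ensemble(e1, fraction = 0.25), 1e-6)
  expect_equal(colnames(e1$states), topo$nodes)
  # single decaying node: one state at g/k
  tiny <- structure(list(kind = "custom", nodes = "X",
                         edges = data.frame(source = character(0), target = character(0),
                                            type = integer(0))),
                    class = "emt_topology")
  et <- collect_ensemble(tiny, n_params = 1, n_init = 5, seed = 2)
  p <- et$params[[1]]
  expect_equal(nrow(et$states), 1)
  expect_equal(unname(et$states[1, "X"]), unname(p$g / p$k), tolerance = 1e-5)
})

test_that("z-normalisation matches the hand formula and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 8))
  z <- znormalize(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  expect_equal(unname(znormalize(z)), unname(z), tolerance = 1e-12)
  const <- cbind(a = c(1, 2, 3), flat = c(4, 4, 4))
  expect_error(znormalize(const), "flat")
  expect_error(znormalize(m[1, , drop = FALSE]), ">= 2")
})

test_that("clustering separates constructed blobs and ignores row order", {
  set.seed(9)
  blob <- rbind(
    matrix(rnorm(50 * 4, mean = -5, sd = 0.5), ncol = 4),
    matrix(rnorm(50 * 4, mean = +5, sd = 0.5), ncol = 4)
  )
  colnames(blob) <- c("ZEB1", "SLUG", "KLF4", "miR200")
  truth <- rep(c("epithelial", "mesenchymal"), each = 50)
  cl <- cluster_states(blob, exclude = character(0))
  expect_equal(as.character(cl$labels), truth)
  perm <- sample(nrow(blob))
  cl2 <- cluster_states(blob[perm, ], exclude = character(0))
  expect_equal(as.character(cl2$labels), truth[perm])
  expect_error(cluster_states(blob[1, , drop = FALSE]), ">= 2")
})

test_that("ensemble clusters carry the epithelial/mesenchymal signature pattern", {
  topo <- racipe_topology("klf4")
  ens <- collect_ensemble(topo, n_params = 150, n_init = 15, seed = 8,
                          t_max = 150, dt = 0.04)
  z <- znormalize(ens$states, log2 = TRUE)
  cl <- cluster_states(z)
  epi <- cl$labels == "epithelial"
  expect_lt(mean(z[epi, "ZEB1"]), mean(z[!epi, "ZEB1"]))
  expect_lt(mean(z[epi, "SLUG"]), mean(z[!epi, "SLUG"]))
  expect_gt(mean(z[epi, "miR200"]), mean(z[!epi, "miR200"]))
  expect_gt(mean(z[epi, "KLF4"]), mean(z[!epi, "KLF4"]))
})

test_that("EMT score arithmetic and trimodal decomposition behave", {
  z <- matrix(0, 4, 4, dimnames = list(NULL, c("ZEB1", "SLUG", "miR200", "CDH1")))
  z[2, ] <- c(1, 1, -1, -1)
  sc <- z[, "ZEB1"] + z[, "SLUG"] - z[, "miR200"] - z[, "CDH1"]
  expect_equal(sc[1], 0)
  expect_equal(sc[2], 4)
  expect_error(emt_score_states(z[, 1:3, drop = FALSE]), "absent")
})

test_that("3-Gaussian decomposition recovers synthetic mixture weights", {
  set.seed(31)
  n <- 10000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  x <- rnorm(n, mean = c(-3, 0, 3)[comp], sd = 0.5)
  fit <- fit_gaussian_mixture(x, 3)
  fit <- fit[order(fit$mean), ]
  expect_equal(fit$weight, c(0.2, 0.5, 0.3), tolerance = 0.03)
  expect_equal(fit$mean, c(-3, 0, 3), tolerance = 0.1)
  # mixture areas agree with hard gating at the density crossings
  zs <- cbind(ZEB1 = x, SLUG = rnorm(n, sd = 1e-8), miR200 = rnorm(n, sd = 1e-8),
              CDH1 = rnorm(n, sd = 1e-8))
  dist <- emt_score_states(zs)
  expect_true(all(abs(dist$phenotype_areas - dist$gated_fractions) < 0.05))
})

test_that("fraction comparison reproduces the textbook t-test", {
  a <- rbind(c(0.2, 0.5, 0.3), c(0.21, 0.49, 0.3), c(0.19, 0.51, 0.3))
  b <- rbind(c(0.5, 0.2, 0.3), c(0.51, 0.19, 0.3), c(0.49, 0.21, 0.3))
  colnames(a) <- colnames(b) <- c("epithelial", "hybrid", "mesenchymal")
  res <- compare_phenotype_fractions(list(base = a, oe = b))
  expect_equal(res$p_value[res$phenotype == "epithelial"],
               t.test(a[, 1], b[, 1])$p.value)
  expect_lt(res$p_value[res$phenotype == "epithelial"], 0.01)
  expect_true(res$degenerate[res$phenotype == "mesenchymal"])
  expect_error(compare_phenotype_fractions(list(a = a[1:2, ], b = b)), "replicates")
  expect_error(compare_phenotype_fractions(list(a)), "two conditions")
})

test_that("correlation matrix flags significance and handles exact relations", {
  x <- seq(1, 20)
  m <- cbind(x = x, double_x = 2 * x, neg_x = -x)
  cm <- correlation_matrix(m)
  expect_equal(cm$r["x", "double_x"], 1)
  expect_equal(cm$r["x", "neg_x"], -1)
  expect_equal(unname(diag(cm$r)), c(1, 1, 1))
  set.seed(2)
  m2 <- cbind(a = rnorm(10), b = rnorm(10), flat = rep(1, 10))
  cm2 <- correlation_matrix(m2)
  expect_true(cm2$undefined[["flat"]])
  expect_true(is.na(cm2$r["a", "flat"]))
  expect_error(correlation_matrix(m2[1:2, ]), ">= 3")
})
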