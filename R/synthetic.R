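# Synthetic cohort generators. Real cohorts in this field show two
# anti-correlated "teams" of genes - epithelial and mesenchymal - plus
# promoter methylation anti-correlated with expression; the generators
# emulate exactly that correlation-sign structure (and nothing more) through
# a single latent EMT axis with signed loadings, which guarantees a valid
# (positive-definite) covariance by construction.

#' Specification for a synthetic expression cohort
#'
#' Samples carry a latent EMT-axis value whose mean depends on the phenotype
#' class (epithelial at `-separation`, hybrid at 0, mesenchymal at
#' `+separation`, in noise-sd units); epithelial-team genes load negatively
#' and mesenchymal-team genes positively on the axis, plus i.i.d. Gaussian
#' noise. When `target_r_within` is given, the noise sd is derived from it;
#' otherwise `noise_sd` is used directly.
#'
#' @param n_epithelial,n_hybrid,n_mesenchymal samples per class (>= 3 each).
#' @param epithelial_genes,mesenchymal_genes gene names per team.
#' @param separation class separation on the latent axis, in noise-sd units
#'   (default 5, i.e. adjacent classes 5 sd apart, E and M 10 sd apart,
#'   giving complete separation of the signed KS scores by construction).
#' @param noise_sd per-gene Gaussian noise sd.
#' @param target_r_within optional target within-team correlation in (0, 1);
#'   overrides `noise_sd`.
#' @param baseline mean log-expression added to every gene.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_epithelial = 100, n_hybrid = 100, n_mesenchymal = 100,
                        epithelial_genes = paste0("EPI", 1:10),
                        mesenchymal_genes = paste0("MES", 1:10),
                        separation = 5, noise_sd = 1,
                        target_r_within = NULL, baseline = 8, seed = 1) {
  if (min(n_epithelial, n_hybrid, n_mesenchymal) < 3) {
    stop("need >= 3 samples per phenotype class")
  }
  if (length(intersect(epithelial_genes, mesenchymal_genes))) {
    stop("team gene lists must be disjoint")
  }
  if (!is.null(target_r_within)) {
    if (target_r_within <= 0 || target_r_within >= 1) {
      stop("target_r_within must lie in (0, 1)")
    }
    # latent variance for equal thirds at means -s, 0, +s is 2 s^2 / 3
    lat_var <- 2 * separation^2 / 3
    noise_sd <- sqrt(lat_var * (1 - target_r_within) / target_r_within)
  }
  structure(list(n = c(epithelial = n_epithelial, hybrid = n_hybrid,
                       mesenchymal = n_mesenchymal),
                 epithelial_genes = epithelial_genes,
                 mesenchymal_genes = mesenchymal_genes,
                 separation = separation, noise_sd = noise_sd,
                 baseline = baseline, seed = seed), class = "cohort_spec")
}

#' Generate a synthetic expression cohort
#'
#' @param spec a `cohort_spec`.
#' @return list of class `synthetic_cohort`: `expression` (samples x genes),
#'   `labels` (factor of true phenotype classes), `latent` (per-sample axis
#'   values), `spec`.
#' @export
generate_expression <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    classes <- rep(names(spec$n), times = spec$n)
    mu <- c(epithelial = -spec$separation, hybrid = 0,
            mesenchymal = spec$separation)[classes]
    latent <- rnorm(length(classes), mean = mu, sd = 1)
    genes <- c(spec$epithelial_genes, spec$mesenchymal_genes)
    loading <- c(rep(-1, length(spec$epithelial_genes)),
                 rep(+1, length(spec$mesenchymal_genes)))
    expr <- outer(latent, loading) +
      matrix(rnorm(length(latent) * length(genes), sd = spec$noise_sd),
             nrow = length(latent)) + spec$baseline
    dimnames(expr) <- list(sprintf("S%03d", seq_along(latent)), genes)
    structure(list(expression = expr,
                   labels = factor(classes, levels = names(spec$n)),
                   latent = latent, spec = spec), class = "synthetic_cohort")
  })
}

#' Generate per-CpG methylation beta values matched to expression
#'
#' For each requested gene, per-sample gene-level methylation is drawn so
#' that the mean beta correlates with that gene's expression at `target_r`
#' (non-positive, as promoter methylation silences expression); per-CpG
#' betas scatter tightly around the gene-level value and are clipped to
#' [0, 1] (clipping is counted and reported).
#'
#' @param expression samples x genes matrix (or `synthetic_cohort`).
#' @param genes genes to profile (default: all columns).
#' @param target_r target expression-methylation correlation in (-1, 0].
#' @param cpg_counts integer vector (recycled) of CpG sites per gene; e.g.
#'   KLF4-like promoters carry about 10 sites.
#' @param cpg_sd per-CpG scatter around the gene-level beta.
#' @param seed RNG seed.
#' @return list of class `methylation_profile`: `beta` (samples x genes mean
#'   beta), `cpg_counts`, `clipped` (count of clipped CpG values),
#'   `achieved_r` (per-gene realised correlation).
#' @export
generate_methylation <- function(expression, genes = NULL, target_r = -0.6,
                                 cpg_counts = 10L, cpg_sd = 0.02, seed = 1) {
  if (inherits(expression, "synthetic_cohort")) expression <- expression$expression
  if (target_r > 0 || target_r <= -1) stop("target_r must lie in (-1, 0]")
  if (is.null(genes)) genes <- colnames(expression)
  cpg_counts <- rep_len(as.integer(cpg_counts), length(genes))
  with_seed(seed, {
    n <- nrow(expression)
    beta <- matrix(NA_real_, n, length(genes),
                   dimnames = list(rownames(expression), genes))
    clipped <- 0L
    achieved <- setNames(numeric(length(genes)), genes)
    for (j in seq_along(genes)) {
      z <- as.numeric(scale(expression[, genes[j]]))
      target_component <- target_r * z + sqrt(1 - target_r^2) * rnorm(n)
      gene_beta <- 0.5 + 0.12 * target_component
      cpgs <- matrix(rnorm(n * cpg_counts[j], mean = gene_beta, sd = cpg_sd),
                     nrow = n)
      clipped <- clipped + sum(cpgs < 0 | cpgs > 1)
      cpgs <- pmin(pmax(cpgs, 0), 1)
      beta[, j] <- rowMeans(cpgs)
      achieved[j] <- if (sd(beta[, j]) == 0) NA_real_ else cor(expression[, genes[j]], beta[, j])
    }
    if (clipped > 0) {
      message("generate_methylation: clipped ", clipped, " CpG values to [0, 1]")
    }
    structure(list(beta = beta, cpg_counts = setNames(cpg_counts, genes),
                   clipped = clipped, achieved_r = achieved),
              class = "methylation_profile")
  })
}

#' Toy and shipped circuit fixtures
#'
#' `"toggle_switch"` builds a symmetric two-node mutual-inhibition switch that
#' is bistable by construction (three fixed points: two stable, one unstable
#' at the symmetric level). `"control_emt"` and `"full_klf4"` load the shipped
#' calibrated circuit configurations.
#'
#' @param kind which fixture.
#' @return an `emt_circuit`.
#' @export
generate_toy_circuit <- function(kind = c("toggle_switch", "control_emt", "full_klf4")) {
  kind <- match.arg(kind)
  if (kind == "control_emt") return(emt_circuit("control"))
  if (kind == "full_klf4") return(emt_circuit("klf4"))
  nodes <- data.frame(
    name = c("A", "B", "Iext"), kind = c("protein", "protein", "protein"),
    g = c(50, 50, 0), k = c(0.1, 0.1, 1), clamped = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    source = c("A", "B"), target = c("B", "A"),
    sign = c("inhibition", "inhibition"),
    mode = c("transcriptional", "transcriptional"),
    threshold = c(150, 150), hill = c(4, 4), lambda = c(0.02, 0.02),
    stringsAsFactors = FALSE
  )
  circ <- structure(list(nodes = nodes, edges = edges, mirna = NULL,
                         signal = list(node = "Iext", value = 0),
                         variant = "toggle_switch"), class = "emt_circuit")
  validate_circuit(circ)
  circ
}
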