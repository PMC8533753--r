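# Transcriptomic and methylation scoring: the signed two-sample
# Kolmogorov-Smirnov EMT score, per-sample scoring of expression matrices,
# gene-level methylation summaries, and expression-methylation correlation.

#' Epithelial/mesenchymal gene signature
#'
#' @param epithelial,mesenchymal disjoint character vectors of gene names,
#'   each with >= 2 genes.
#' @return list of class `gene_signature`.
#' @export
gene_signature <- function(epithelial, mesenchymal) {
  if (length(intersect(epithelial, mesenchymal))) {
    stop("epithelial and mesenchymal signatures must be disjoint")
  }
  if (length(epithelial) < 2 || length(mesenchymal) < 2) {
    stop("each signature needs >= 2 genes")
  }
  structure(list(epithelial = unique(epithelial),
                 mesenchymal = unique(mesenchymal)), class = "gene_signature")
}

#' Read a signature from two one-gene-per-line text files
#' @param epithelial_file,mesenchymal_file file paths; defaults are the
#'   editable lists shipped with the package.
#' @return a `gene_signature`.
#' @export
read_signature <- function(
    epithelial_file = system.file("extdata", "signature_epithelial.txt", package = "emtdyn"),
    mesenchymal_file = system.file("extdata", "signature_mesenchymal.txt", package = "emtdyn")) {
  gene_signature(readLines(epithelial_file), readLines(mesenchymal_file))
}

# One-sided two-sample KS statistics between the E- and M-signature values:
# d_m = max(F_E - F_M): evidence that M genes are expressed higher;
# d_e = max(F_M - F_E): evidence that E genes are expressed higher.
# Right-continuous step CDFs; ties share a step.
ks_onesided <- function(e_vals, m_vals) {
  grid <- sort(unique(c(e_vals, m_vals)))
  Fe <- vapply(grid, function(g) mean(e_vals <= g), numeric(1))
  Fm <- vapply(grid, function(g) mean(m_vals <= g), numeric(1))
  c(d_m = max(Fe - Fm), d_e = max(Fm - Fe))
}

# asymptotic one-sided two-sample KS p-value
ks_onesided_p <- function(d, n1, n2) {
  exp(-2 * d^2 * n1 * n2 / (n1 + n2))
}

#' Signed Kolmogorov-Smirnov EMT score of one sample
#'
#' The empirical CDFs of the sample's epithelial-signature and mesenchymal-
#' signature expression values are compared. The score magnitude is the
#' maximum CDF distance (the two-sample KS statistic); the sign comes from
#' hypothesis testing between the two one-sided alternatives: positive when
#' the mesenchymal genes are expressed higher (mesenchymal sample), negative
#' when the epithelial genes dominate, and exactly 0 (null retained) when
#' neither one-sided test rejects at `alpha`.
#'
#' @param expression named numeric vector of one sample's expression values.
#' @param signature a `gene_signature`; all genes must be present.
#' @param alpha significance level for the one-sided tests (default 0.05).
#' @return list of class `emt_ks_score`: `score` in [-1, 1], `hypothesis`
#'   (`"M-dominant"`, `"E-dominant"` or `"null"`), `ks_distance`, `p_value`.
#' @export
ks_emt_score <- function(expression, signature, alpha = 0.05) {
  stopifnot(inherits(signature, "gene_signature"))
  missing <- setdiff(c(signature$epithelial, signature$mesenchymal),
                     names(expression))
  if (length(missing)) {
    stop("signature genes absent from the sample: ", paste(missing, collapse = ", "))
  }
  e_vals <- as.numeric(expression[signature$epithelial])
  m_vals <- as.numeric(expression[signature$mesenchymal])
  d <- ks_onesided(e_vals, m_vals)
  p_m <- ks_onesided_p(d[["d_m"]], length(e_vals), length(m_vals))
  p_e <- ks_onesided_p(d[["d_e"]], length(e_vals), length(m_vals))
  if (p_m < alpha && (p_m <= p_e || p_e >= alpha)) {
    out <- list(score = d[["d_m"]], hypothesis = "M-dominant",
                ks_distance = d[["d_m"]], p_value = p_m)
  } else if (p_e < alpha) {
    out <- list(score = -d[["d_e"]], hypothesis = "E-dominant",
                ks_distance = d[["d_e"]], p_value = p_e)
  } else {
    out <- list(score = 0, hypothesis = "null",
                ks_distance = max(d), p_value = min(p_m, p_e))
  }
  structure(out, class = "emt_ks_score")
}

#' KS EMT scores for every sample of an expression matrix
#'
#' @param matrix numeric matrix, samples x genes (finite values; gene names
#'   as column names). Use `orientation = "genes_by_samples"` for the
#'   transposed layout.
#' @param signature a `gene_signature`.
#' @param groups optional factor of per-sample group labels; when given, all
#'   pairwise group comparisons of the scores are run with Welch's two-tailed
#'   t-test.
#' @param orientation matrix layout.
#' @param alpha one-sided test level passed to [ks_emt_score()].
#' @return list of class `emt_score_table`: `scores` (data.frame sample,
#'   score, hypothesis), `group_comparisons` (data.frame or NULL).
#' @export
score_matrix <- function(matrix, signature, groups = NULL,
                         orientation = c("samples_by_genes", "genes_by_samples"),
                         alpha = 0.05) {
  orientation <- match.arg(orientation)
  m <- as.matrix(matrix)
  if (orientation == "genes_by_samples") m <- t(m)
  if (any(!is.finite(m))) stop("expression values must be finite")
  if (anyDuplicated(colnames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(rownames(m))) stop("duplicate sample identifiers")
  res <- lapply(seq_len(nrow(m)), function(i) ks_emt_score(m[i, ], signature, alpha))
  scores <- data.frame(
    sample = if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m),
    score = vapply(res, `[[`, numeric(1), "score"),
    hypothesis = vapply(res, `[[`, character(1), "hypothesis"),
    stringsAsFactors = FALSE
  )
  comparisons <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != nrow(m)) stop("groups length must match sample count")
    pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(pr) {
      x <- scores$score[groups == pr[1]]; y <- scores$score[groups == pr[2]]
      # Welch two-tailed; degenerate (constant) groups are flagged with NA
      p <- tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
      data.frame(group_1 = pr[1], group_2 = pr[2],
                 mean_1 = mean(x), mean_2 = mean(y), p_value = p)
    }))
  }
  structure(list(scores = scores, group_comparisons = comparisons),
            class = "emt_score_table")
}

#' @export
print.emt_score_table <- function(x, ...) {
  cat("<emt_score_table>", nrow(x$scores), "samples; mean score",
      round(mean(x$scores$score), 3), "\n")
  invisible(x)
}

#' Gene-level methylation from per-CpG beta values
#'
#' Arithmetic mean of the beta values over a gene's CpG sites.
#'
#' @param cpg_betas non-empty numeric vector of per-CpG beta values in [0, 1].
#' @return the mean beta.
#' @export
mean_beta <- function(cpg_betas) {
  if (!length(cpg_betas)) stop("empty CpG beta vector")
  if (any(!is.finite(cpg_betas)) || any(cpg_betas < 0) || any(cpg_betas > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  mean(cpg_betas)
}

#' Correlation between expression and promoter methylation
#'
#' Pearson correlation with a two-sided p-value over paired per-sample (or
#' per-group) observations, as used to relate KLF4 expression to its promoter
#' methylation.
#'
#' @param expression,methylation paired numeric vectors (n >= 3).
#' @return list of class `expr_meth_cor`: `r`, `p_value`, `n`, `undefined`
#'   (TRUE when either vector has zero variance), and the paired `data`.
#' @export
expression_methylation_correlation <- function(expression, methylation) {
  if (length(expression) != length(methylation)) stop("unpaired observations")
  ok <- is.finite(expression) & is.finite(methylation)
  expression <- expression[ok]; methylation <- methylation[ok]
  if (length(expression) < 3) stop("need >= 3 paired observations")
  if (sd(expression) == 0 || sd(methylation) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_,
                          n = length(expression), undefined = TRUE,
                          data = data.frame(expression, methylation)),
                     class = "expr_meth_cor"))
  }
  ct <- cor.test(expression, methylation)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(expression), undefined = FALSE,
                 data = data.frame(expression, methylation)),
            class = "expr_meth_cor")
}

#' @export
print.expr_meth_cor <- function(x, ...) {
  if (x$undefined) cat("<expr_meth_cor> undefined (zero variance), n =", x$n, "\n")
  else cat(sprintf("<expr_meth_cor> r = %.3f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}
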