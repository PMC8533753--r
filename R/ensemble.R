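# Random-parameterisation (RACIPE-style) ensembles: a fixed topology is
# converted to shifted-Hill ODEs, kinetic parameters are sampled over broad
# biologically plausible ranges, and the steady states reached from many
# random initial conditions form the phenotypic ensemble.

TOPOLOGY_FILES <- c(
  klf4       = "topology_klf4.topo",
  klf4_cdh1  = "topology_klf4_cdh1.topo",
  control    = "topology_control.topo",
  grhl2_cdh1 = "topology_grhl2_cdh1.topo"
)

# run code with a temporary RNG state seeded at `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Load a shipped regulatory-network topology
#'
#' Topology files are RACIPE-compatible: one edge per line with columns
#' `Source Target Type` (1 = activation, 2 = inhibition).
#'
#' @param kind which circuit: the KLF4-EMT network, its CDH1 extension, the
#'   control core without KLF4, or the GRHL2 variant.
#' @param file optional path to a custom `.topo` file.
#' @return object of class `emt_topology` with `nodes` and `edges`.
#' @export
racipe_topology <- function(kind = c("klf4", "klf4_cdh1", "control", "grhl2_cdh1"),
                            file = NULL) {
  if (is.null(file)) {
    kind <- match.arg(kind)
    file <- system.file("extdata", TOPOLOGY_FILES[[kind]], package = "emtdyn")
  } else {
    kind <- "custom"
  }
  tab <- read.table(file, header = TRUE, stringsAsFactors = FALSE)
  names(tab) <- c("source", "target", "type")
  if (!all(tab$type %in% 1:2)) stop("edge type must be 1 (activation) or 2 (inhibition)")
  nodes <- unique(c(tab$source, tab$target))
  structure(list(kind = kind, nodes = nodes, edges = tab), class = "emt_topology")
}

#' @export
print.emt_topology <- function(x, ...) {
  cat("<emt_topology>", x$kind, "-", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Default RACIPE sampling ranges
#'
#' Production uniform on 1-100 molecules/h, degradation uniform on 0.1-1 /h,
#' Hill coefficients integer 1-6, activating fold-change uniform on 1-100,
#' inhibitory fold-change reciprocal-uniform in (0, 1], and shifted-Hill
#' thresholds drawn by the half-functional rule: uniform on (0.02, 1.98) times
#' the median unregulated level (median g / median k) of the regulator.
#'
#' @return list of class `sampling_ranges`.
#' @export
default_sampling_ranges <- function() {
  structure(list(
    production = c(1, 100),
    degradation = c(0.1, 1),
    hill = c(1L, 6L),
    fold_change = c(1, 100),
    threshold_span = c(0.02, 1.98)
  ), class = "sampling_ranges")
}

#' Sample one kinetic parameter set for a topology
#'
#' @param topology an `emt_topology`.
#' @param ranges a `sampling_ranges` list.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return list with named vectors `g`, `k` and an `edges` data.frame carrying
#'   `threshold`, `hill`, `lambda` per edge.
#' @export
sample_parameters <- function(topology, ranges = default_sampling_ranges(),
                              seed = NULL) {
  need <- c("production", "degradation", "hill", "fold_change", "threshold_span")
  missing <- setdiff(need, names(ranges))
  if (length(missing)) stop("sampling ranges missing class(es): ",
                            paste(missing, collapse = ", "))
  with_seed(seed, {
    nn <- length(topology$nodes)
    ne <- nrow(topology$edges)
    g <- setNames(runif(nn, ranges$production[1], ranges$production[2]), topology$nodes)
    k <- setNames(runif(nn, ranges$degradation[1], ranges$degradation[2]), topology$nodes)
    hill <- sample(seq(ranges$hill[1], ranges$hill[2]), ne, replace = TRUE)
    lam <- runif(ne, ranges$fold_change[1], ranges$fold_change[2])
    inh <- topology$edges$type == 2
    lam[inh] <- 1 / lam[inh]
    # half-functional rule: thresholds drawn around the regulator's unregulated
    # level g/k, so each interaction is functional for roughly half the draws;
    # over the ensemble the threshold distribution centres on the median g/k
    m_src <- (g / k)[topology$edges$source]
    thr <- runif(ne, ranges$threshold_span[1], ranges$threshold_span[2]) * m_src
    ed <- topology$edges
    ed$threshold <- thr; ed$hill <- as.numeric(hill); ed$lambda <- lam
    list(g = g, k = k, edges = ed)
  })
}

#' In-silico over- or down-expression of one node
#'
#' Over-expression (OE) multiplies the node's sampled production rate by
#' `fold`; down-expression (DE) divides it. All other parameters are
#' untouched, matching the RACIPE fold-change semantics.
#'
#' @param params a parameter set from [sample_parameters()].
#' @param node node name.
#' @param fold fold change, >= 1.
#' @param direction `"OE"` or `"DE"`.
#' @return the modified parameter set.
#' @export
perturb_production <- function(params, node, fold, direction = c("OE", "DE")) {
  direction <- match.arg(direction)
  if (!node %in% names(params$g)) stop("unknown node: ", node)
  if (!is.finite(fold) || fold < 1) stop("fold must be >= 1")
  params$g[node] <- if (direction == "OE") params$g[node] * fold else params$g[node] / fold
  params
}

# C++ model encoding for a sampled RACIPE system
racipe_model <- function(topology, params) {
  idx <- function(nm) match(nm, topology$nodes) - 1L
  list(
    g = unname(params$g), k = unname(params$k),
    clamped = integer(length(topology$nodes)),
    esrc = idx(params$edges$source), etgt = idx(params$edges$target),
    thr = params$edges$threshold, hill = params$edges$hill, lam = params$edges$lambda,
    has_mirna = FALSE, node_names = topology$nodes
  )
}

#' Collect a steady-state ensemble over random parameter sets
#'
#' For each sampled parameter set, the ODEs are relaxed from `n_init` random
#' (log-uniform) initial conditions; converged endpoints are deduplicated at
#' relative L-infinity distance 1e-3 on log-levels. Parameter sets with no
#' convergent state are logged and skipped.
#'
#' @param topology an `emt_topology`.
#' @param n_params number of random parameter sets.
#' @param n_init initial conditions per parameter set.
#' @param seed master seed; per-set seeds are derived deterministically.
#' @param ranges a `sampling_ranges` list.
#' @param perturb optional list(node, fold, direction) applied to every
#'   sampled set via [perturb_production()].
#' @param t_max,dt,tol settling horizon (h), step (h) and convergence
#'   tolerance for the relaxation.
#' @param replicate_id label stored with the result.
#' @return list of class `emt_ensemble`: `states` (steady states x nodes),
#'   `param_id`, `params`, `topology`, `skipped`, `seed`, `replicate_id`.
#' @export
collect_ensemble <- function(topology, n_params = 1000, n_init = 100,
                             seed = 1, ranges = default_sampling_ranges(),
                             perturb = NULL, t_max = 300, dt = 0.02,
                             tol = 1e-8, replicate_id = 1L) {
  if (n_params < 1 || n_init < 1) stop("n_params and n_init must be >= 1")
  set_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_params))
  states <- list(); pid <- list(); plist <- vector("list", n_params)
  skipped <- 0L
  for (p in seq_len(n_params)) {
    pars <- sample_parameters(topology, ranges, seed = set_seeds[p])
    if (!is.null(perturb)) {
      pars <- perturb_production(pars, perturb$node, perturb$fold, perturb$direction)
    }
    plist[[p]] <- pars
    m <- racipe_model(topology, pars)
    hi <- node_scales_racipe(m)
    X0 <- with_seed(set_seeds[p] + 1L, {
      lo <- pmax(hi * 1e-4, 1e-2)
      u <- matrix(runif(n_init * length(hi)), n_init)
      matrix(lo, n_init, length(hi), byrow = TRUE) *
        (matrix(hi / lo, n_init, length(hi), byrow = TRUE))^u
    })
    res <- .settle_cpp(X0, m, t_max, dt, tol, 50L)
    S <- res$states[res$converged, , drop = FALSE]
    if (!nrow(S)) { skipped <- skipped + 1L; next }
    S <- dedupe_log(S, 1e-3)
    states[[length(states) + 1]] <- S
    pid[[length(pid) + 1]] <- rep(p, nrow(S))
  }
  if (!length(states)) stop("no parameter set produced a convergent steady state")
  st <- do.call(rbind, states)
  colnames(st) <- topology$nodes
  structure(list(states = st, param_id = unlist(pid), params = plist,
                 topology = topology, skipped = skipped, seed = seed,
                 n_params = n_params, n_init = n_init,
                 replicate_id = replicate_id), class = "emt_ensemble")
}

node_scales_racipe <- function(m) {
  hi <- m$g / m$k
  for (e in seq_along(m$esrc)) {
    t <- m$etgt[e] + 1L
    hi[t] <- hi[t] * max(1, m$lam[e])
  }
  hi
}

dedupe_log <- function(S, tol) {
  if (nrow(S) < 2) return(S)
  L <- log10(S + 1e-12)
  keep <- !logical(nrow(S))
  for (i in seq_len(nrow(S) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(S)) {
      if (keep[j] && max(abs(L[i, ] - L[j, ])) < tol) keep[j] <- FALSE
    }
  }
  S[keep, , drop = FALSE]
}

#' @export
print.emt_ensemble <- function(x, ...) {
  cat("<emt_ensemble>", nrow(x$states), "steady states from", x$n_params,
      "parameter sets (", x$skipped, "skipped )\n")
  invisible(x)
}

#' Re-verify a subsample of ensemble states as fixed points
#' @param ensemble an `emt_ensemble`.
#' @param fraction fraction of states re-checked (at least 5 states).
#' @return max relative residual `|dx| / (|x| + 1)` over the subsample.
#' @export
verify_ensemble <- function(ensemble, fraction = 0.01) {
  n <- nrow(ensemble$states)
  idx <- unique(round(seq(1, n, length.out = max(5, ceiling(fraction * n)))))
  worst <- 0
  for (i in idx) {
    m <- racipe_model(ensemble$topology, ensemble$params[[ensemble$param_id[i]]])
    dx <- .rhs_cpp(ensemble$states[i, ], m)
    worst <- max(worst, max(abs(dx) / (abs(ensemble$states[i, ]) + 1)))
  }
  worst
}

#' Z-normalise steady-state levels per gene
#'
#' Each column (gene) is centred to mean 0 and scaled to standard deviation 1
#' over all steady-state values. With `log2 = TRUE` the levels are
#' log2-transformed first (floored at 1e-9 molecules), the working scale of
#' random-parameterisation ensembles whose levels span several decades.
#'
#' @param states numeric matrix, steady states x genes, >= 2 rows.
#' @param log2 transform to log2 scale before normalising.
#' @return the z-normalised matrix.
#' @export
znormalize <- function(states, log2 = FALSE) {
  states <- as.matrix(states)
  if (log2) states <- base::log2(pmax(states, 1e-9))
  if (nrow(states) < 2) stop("znormalize needs >= 2 states")
  sds <- apply(states, 2, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance gene(s): ", paste(colnames(states)[zero], collapse = ", "))
  }
  scale(states)[, , drop = FALSE]
}

#' Hierarchical clustering of z-normalised states into E and M groups
#'
#' Agglomerative (Ward) clustering cut at two clusters; the cluster with the
#' higher mean ZEB z-score is labelled mesenchymal. SNAIL, whose ensemble
#' distribution is unimodal, is excluded from the clustering features by
#' default.
#'
#' @param zstates z-normalised matrix (states x genes).
#' @param exclude genes excluded from the clustering features.
#' @param zeb_gene gene used to orient cluster labels.
#' @return list: `labels` (factor `epithelial`/`mesenchymal` per state),
#'   `tree` (hclust object), `features`.
#' @export
cluster_states <- function(zstates, exclude = "SNAIL", zeb_gene = "ZEB1") {
  zstates <- as.matrix(zstates)
  if (nrow(zstates) < 2) stop("clustering needs >= 2 states")
  feats <- setdiff(colnames(zstates), exclude)
  if (!zeb_gene %in% feats) stop("zeb_gene not among clustering features")
  hc <- hclust(dist(zstates[, feats, drop = FALSE]), method = "ward.D2")
  grp <- cutree(hc, k = 2)
  mean_zeb <- tapply(zstates[, zeb_gene], grp, mean)
  mes <- as.integer(names(which.max(mean_zeb)))
  labels <- factor(ifelse(grp == mes, "mesenchymal", "epithelial"),
                   levels = c("epithelial", "mesenchymal"))
  list(labels = labels, tree = hc, features = feats)
}

#' EMT score distribution of an ensemble with trimodal decomposition
#'
#' Per-state EMT score `ZEB1 + SLUG - miR200 - CDH1` on z-normalised levels,
#' fitted with a 3-component univariate Gaussian mixture (unequal variances).
#' Components ordered by mean map to epithelial (lowest), hybrid, mesenchymal
#' (highest); phenotype fractions are the component weights (areas), with
#' hard-gated fractions at the fitted density crossings also reported.
#'
#' @param zstates z-normalised matrix containing the four score genes.
#' @param genes named character vector mapping `zeb`, `slug`, `mir`, `cdh` to
#'   column names.
#' @return list of class `emt_score_distribution`: `scores`, `fit`
#'   (mean/sd/weight per component), `phenotype_areas`, `gated_fractions`,
#'   `cut_points`.
#' @export
emt_score_states <- function(zstates,
                             genes = c(zeb = "ZEB1", slug = "SLUG",
                                       mir = "miR200", cdh = "CDH1")) {
  zstates <- as.matrix(zstates)
  missing <- setdiff(genes, colnames(zstates))
  if (length(missing)) stop("score genes absent: ", paste(missing, collapse = ", "))
  scores <- zstates[, genes[["zeb"]]] + zstates[, genes[["slug"]]] -
    zstates[, genes[["mir"]]] - zstates[, genes[["cdh"]]]
  fit <- fit_gaussian_mixture(scores, 3)
  ord <- order(fit$mean)
  fit <- fit[ord, ]
  rownames(fit) <- c("epithelial", "hybrid", "mesenchymal")
  cuts <- c(component_crossing(fit[1, ], fit[2, ]),
            component_crossing(fit[2, ], fit[3, ]))
  gated <- c(mean(scores <= cuts[1]),
             mean(scores > cuts[1] & scores <= cuts[2]),
             mean(scores > cuts[2]))
  names(gated) <- rownames(fit)
  structure(list(scores = scores, fit = fit,
                 phenotype_areas = setNames(fit$weight, rownames(fit)),
                 gated_fractions = gated, cut_points = cuts),
            class = "emt_score_distribution")
}

#' Univariate Gaussian mixture with free variances
#'
#' Fits a `G`-component 1-D Gaussian mixture by EM (`mclust`, model "V")
#' started from quantile-based component means with 10 deterministic
#' restarts, keeping the best log-likelihood solution. Used for the trimodal
#' decomposition of ensemble EMT scores.
#'
#' @param x numeric vector.
#' @param G number of components.
#' @param restarts number of jittered restarts.
#' @return data.frame with one row per component: `mean`, `sd`, `weight`.
#' @export
fit_gaussian_mixture <- function(x, G, restarts = 10) {
  q0 <- as.numeric(quantile(x, (2 * seq_len(G) - 1) / (2 * G)))
  jitters <- with_seed(42, matrix(rnorm((restarts - 1) * G, sd = sd(x) / 4),
                                  ncol = G))
  best <- NULL
  for (r in seq_len(restarts)) {
    mu0 <- if (r == 1) q0 else q0 + jitters[r - 1, ]
    start <- list(pro = rep(1 / G, G), mean = mu0,
                  variance = list(modelName = "V", d = 1, G = G,
                                  sigmasq = rep(var(x) / G^2, G)))
    fit <- tryCatch(mclust::em(data = x, modelName = "V", parameters = start),
                    error = function(e) NULL)
    if (is.null(fit) || is.null(fit$parameters) || !is.finite(fit$loglik)) next
    if (any(fit$parameters$variance$sigmasq <= 0)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("Gaussian mixture fit failed to converge (n = ", length(x),
         ", G = ", G, ")")
  }
  data.frame(mean = as.numeric(best$parameters$mean),
             sd = sqrt(as.numeric(best$parameters$variance$sigmasq)),
             weight = as.numeric(best$parameters$pro))
}

# score value where two weighted Gaussian densities cross, between the means
component_crossing <- function(a, b) {
  f <- function(x) a$weight * dnorm(x, a$mean, a$sd) - b$weight * dnorm(x, b$mean, b$sd)
  lo <- a$mean; hi <- b$mean
  if (f(lo) * f(hi) > 0) return((lo + hi) / 2)  # overlapping components
  uniroot(f, c(lo, hi))$root
}

#' @export
print.emt_score_distribution <- function(x, ...) {
  cat("<emt_score_distribution>", length(x$scores), "states\n")
  print(round(x$fit, 3))
  invisible(x)
}

#' Phenotype fractions of one ensemble replicate
#'
#' `method = "cluster"` uses two-way hierarchical clustering membership
#' (E and M fractions); `method = "score"` uses the areas of the 3-Gaussian
#' EMT-score decomposition (E, hybrid and M fractions). Both are reported by
#' the ensemble analyses because either gating is defensible.
#'
#' @param ensemble an `emt_ensemble` (its states are z-normalised internally).
#' @param method `"cluster"` or `"score"`.
#' @param ... passed to [cluster_states()] or [emt_score_states()].
#' @return named numeric vector of fractions summing to 1.
#' @export
phenotype_fractions <- function(ensemble, method = c("cluster", "score"), ...) {
  method <- match.arg(method)
  z <- znormalize(ensemble$states, log2 = TRUE)
  if (method == "cluster") {
    cl <- cluster_states(z, ...)
    tab <- table(cl$labels)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  } else {
    emt_score_states(z, ...)$phenotype_areas
  }
}

#' Compare phenotype fractions between conditions over replicates
#'
#' Two-sample Student's t-test per phenotype between two conditions, each
#' summarised by >= 3 replicate fraction vectors.
#'
#' @param fractions named list of exactly two conditions, each a matrix or
#'   data.frame with replicates in rows and phenotypes in columns (identical
#'   column sets).
#' @return data.frame: `phenotype`, per-condition mean and standard error,
#'   `p_value` (NA, flagged, when both sides are constant and identical).
#' @export
compare_phenotype_fractions <- function(fractions) {
  if (!is.list(fractions) || length(fractions) != 2) {
    stop("fractions must be a named list of two conditions")
  }
  a <- as.matrix(fractions[[1]]); b <- as.matrix(fractions[[2]])
  if (!identical(colnames(a), colnames(b))) stop("conditions have unequal replicate structure")
  if (nrow(a) < 3 || nrow(b) < 3) stop("need >= 3 replicates per condition")
  out <- lapply(colnames(a), function(ph) {
    x <- a[, ph]; y <- b[, ph]
    p <- if (sd(x) == 0 && sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) NA_real_ else 0
    } else t.test(x, y)$p.value
    data.frame(phenotype = ph,
               mean_1 = mean(x), se_1 = sd(x) / sqrt(length(x)),
               mean_2 = mean(y), se_2 = sd(y) / sqrt(length(y)),
               p_value = p, degenerate = sd(x) == 0 && sd(y) == 0)
  })
  res <- do.call(rbind, out)
  names(res)[c(2, 3, 4, 5)] <- paste0(c("mean_", "se_", "mean_", "se_"),
                                      rep(names(fractions), each = 2))
  res
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' @param mat numeric matrix, observations x variables (>= 3 rows).
#' @param p_cutoff entries with p above this are flagged non-significant.
#' @return list of class `emt_corr`: `r`, `p`, `n`, `not_significant`
#'   (logical matrix), `undefined` (constant columns).
#' @export
correlation_matrix <- function(mat, p_cutoff = 0.01) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 3) stop("correlation_matrix needs >= 3 observations")
  const <- apply(mat, 2, sd) == 0
  r <- suppressWarnings(cor(mat))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  r[const, ] <- NA; r[, const] <- NA; diag(r) <- 1
  structure(list(r = r, p = p, n = n, not_significant = p > p_cutoff,
                 undefined = const, p_cutoff = p_cutoff), class = "emt_corr")
}

#' @export
print.emt_corr <- function(x, ...) {
  cat("<emt_corr> n =", x$n, "; entries with p >", x$p_cutoff, "flagged\n")
  print(round(x$r, 3))
  invisible(x)
}
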