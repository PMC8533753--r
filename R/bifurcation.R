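#' Classify an EMT phenotype from the ZEB mRNA level
#'
#' Epithelial below 100 molecules, hybrid E/M between 100 and 600, mesenchymal
#' above 600. Boundary values are assigned to the lower phenotype (<= 100 is
#' epithelial, <= 600 hybrid).
#'
#' @param zeb_mrna ZEB mRNA level(s), molecules, >= 0; vectorised.
#' @return factor with levels `epithelial`, `hybrid`, `mesenchymal`.
#' @export
classify_phenotype <- function(zeb_mrna) {
  if (any(!is.finite(zeb_mrna)) || any(zeb_mrna < 0)) {
    stop("classify_phenotype: ZEB mRNA levels must be finite and >= 0")
  }
  cut(zeb_mrna, breaks = c(-Inf, 100, 600, Inf),
      labels = c("epithelial", "hybrid", "mesenchymal"), right = TRUE)
}

#' Steady-state branches of the circuit along an external-signal sweep
#'
#' Continuation by warm-started multi-start root finding: at each grid point
#' the fixed points from the previous point seed the Newton iterations,
#' supplemented by fresh settled starts so branches that appear mid-sweep are
#' picked up. Branches are linked by nearest-neighbour matching in log-level
#' space; saddle-node signal values are recorded where a branch terminates
#' inside the sweep.
#'
#' @param circuit an `emt_circuit`.
#' @param I_range length-2 numeric, increasing, signal range (molecules).
#' @param n_points number of grid points (>= 2; 400 resolves the folds well).
#' @param zeb_node node used as phenotype readout (ZEB mRNA).
#' @param n_starts,settle_starts multi-start budget per grid point.
#' @return list of class `emt_bifurcation`: `states` (one row per fixed point
#'   per grid value, with `branch`, `phenotype`), `saddle_nodes` (data.frame of
#'   fold locations), `zeb_node`, `I_grid`.
#' @export
bifurcation_scan <- function(circuit, I_range, n_points = 400,
                             zeb_node = "ZEBm", n_starts = 16, settle_starts = 6) {
  if (length(I_range) != 2 || diff(I_range) <= 0 || any(I_range < 0)) {
    stop("I_range must be increasing, non-negative, length 2")
  }
  if (n_points < 2) stop("n_points must be >= 2")
  I_grid <- seq(I_range[1], I_range[2], length.out = n_points)
  free_names <- circuit$nodes$name[!circuit$nodes$clamped]
  prev <- NULL
  rows <- vector("list", n_points)
  for (i in seq_along(I_grid)) {
    ss <- find_steady_states(circuit, I_ext = I_grid[i], n_starts = n_starts,
                             settle_starts = settle_starts, extra_starts = prev)
    if (nrow(ss)) prev <- as.matrix(ss[free_names])
    rows[[i]] <- ss
  }
  states <- do.call(rbind, rows)
  states$phenotype <- classify_phenotype(states[[zeb_node]])
  states <- link_branches(states, free_names)
  sn <- saddle_nodes_from_branches(states, I_grid)
  structure(list(states = states, saddle_nodes = sn, zeb_node = zeb_node,
                 I_grid = I_grid), class = "emt_bifurcation")
}

# Nearest-neighbour branch linking in log10 level space.
link_branches <- function(states, free_names) {
  states$branch <- NA_integer_
  Ivals <- sort(unique(states$I_ext))
  nxt <- 1L
  prev_idx <- integer(0)
  logmat <- log10(as.matrix(states[free_names]) + 1)
  for (I in Ivals) {
    cur_idx <- which(states$I_ext == I)
    for (ci in cur_idx) {
      best <- NA_integer_; bestd <- Inf
      for (pi in prev_idx) {
        if (states$stable[pi] != states$stable[ci]) next
        d <- max(abs(logmat[ci, ] - logmat[pi, ]))
        if (d < bestd) { bestd <- d; best <- pi }
      }
      taken <- states$branch[cur_idx[!is.na(states$branch[cur_idx])]]
      if (!is.na(best) && bestd < 0.35 && !(states$branch[best] %in% taken)) {
        states$branch[ci] <- states$branch[best]
      } else {
        states$branch[ci] <- nxt; nxt <- nxt + 1L
      }
    }
    prev_idx <- cur_idx
  }
  states
}

saddle_nodes_from_branches <- function(states, I_grid) {
  out <- list()
  dI <- if (length(I_grid) > 1) diff(I_grid[1:2]) else 0
  for (b in unique(states$branch)) {
    sb <- states[states$branch == b, ]
    lo <- min(sb$I_ext); hi <- max(sb$I_ext)
    if (hi < max(I_grid) - dI / 2) {
      out[[length(out) + 1]] <- data.frame(branch = b, I_ext = hi + dI / 2,
                                           end = "upper", stable = sb$stable[1])
    }
    if (lo > min(I_grid) + dI / 2) {
      out[[length(out) + 1]] <- data.frame(branch = b, I_ext = lo - dI / 2,
                                           end = "lower", stable = sb$stable[1])
    }
  }
  if (!length(out)) {
    return(data.frame(branch = integer(0), I_ext = numeric(0),
                      end = character(0), stable = logical(0)))
  }
  do.call(rbind, out)
}

#' Signal windows over which each stable phenotype exists
#' @param scan an `emt_bifurcation` from [bifurcation_scan()].
#' @return data.frame with `phenotype`, `I_min`, `I_max`, `width`.
#' @export
phenotype_windows <- function(scan) {
  st <- scan$states[scan$states$stable, ]
  out <- lapply(levels(st$phenotype), function(ph) {
    I <- st$I_ext[st$phenotype == ph]
    if (!length(I)) return(data.frame(phenotype = ph, I_min = NA_real_,
                                      I_max = NA_real_, width = 0))
    data.frame(phenotype = ph, I_min = min(I), I_max = max(I),
               width = max(I) - min(I))
  })
  do.call(rbind, out)
}

#' Signal level at which the stable epithelial branch disappears
#' @param scan an `emt_bifurcation`.
#' @return largest grid I_ext carrying a stable epithelial state (`NA` if none).
#' @export
epithelial_exit <- function(scan) {
  st <- scan$states[scan$states$stable & scan$states$phenotype == "epithelial", ]
  if (!nrow(st)) return(NA_real_)
  max(st$I_ext)
}

#' Phase diagram over one kinetic parameter and the external signal
#'
#' For each (parameter value, I_ext) cell, records the set of coexisting
#' stable phenotypes; region boundaries are loci of saddle-node bifurcations.
#'
#' @param circuit an `emt_circuit`.
#' @param vary_param named kinetic parameter (see [circuit_parameters()]),
#'   e.g. `"lam:KLF4->SNAIL"`.
#' @param param_values numeric vector of values for the varied parameter.
#' @param I_range,n_points signal sweep passed to [bifurcation_scan()].
#' @param ... further arguments to [bifurcation_scan()].
#' @return data.frame: `param_value`, `I_ext`, `phenotypes` (collapsed label,
#'   e.g. `"E+H"`), `epithelial_exit` per parameter value.
#' @export
phase_diagram <- function(circuit, vary_param, param_values, I_range,
                          n_points = 150, ...) {
  get_parameter(circuit, vary_param)  # errors early on unknown names
  out <- lapply(param_values, function(v) {
    ci <- set_parameter(circuit, vary_param, v)
    sc <- bifurcation_scan(ci, I_range, n_points = n_points, ...)
    st <- sc$states[sc$states$stable, ]
    ph_by_I <- vapply(sc$I_grid, function(I) {
      ph <- sort(unique(substr(as.character(st$phenotype[st$I_ext == I]), 1, 1)))
      if (!length(ph)) "none" else paste(toupper(ph), collapse = "+")
    }, character(1))
    data.frame(param = vary_param, param_value = v, I_ext = sc$I_grid,
               phenotypes = ph_by_I, epithelial_exit = epithelial_exit(sc))
  })
  do.call(rbind, out)
}

#' Hybrid-state signal window by lower-branch tracking
#'
#' Sweeps the external signal upward while following the lower steady-state
#' branch by warm-started relaxation, and returns the signal window over
#' which the tracked branch classifies as hybrid E/M (ZEB mRNA in
#' (100, 600]): from the crossing out of the epithelial range up to the
#' saddle-node fold where the branch jumps to the mesenchymal state. This is
#' the window metric used by the sensitivity analysis; it resolves the
#' boundaries to one grid cell without multi-start noise.
#'
#' @param circuit an `emt_circuit`.
#' @param I_range upward sweep range (must start in the epithelial regime).
#' @param n_points sweep resolution (>= 400 resolves folds to ~0.1%).
#' @param zeb_node phenotype readout node.
#' @return list: `I_enter` (first hybrid grid point), `I_exit` (last),
#'   `width`, `zeb` (tracked branch levels).
#' @export
hybrid_window <- function(circuit, I_range, n_points = 400, zeb_node = "ZEBm") {
  I_grid <- seq(I_range[1], I_range[2], length.out = n_points)
  m0 <- compile_model(circuit)
  iclamp <- which(circuit$nodes$clamped)
  state <- epithelial_anchor(set_signal(circuit, I_grid[1]), zeb_node)
  zeb <- numeric(n_points)
  for (i in seq_along(I_grid)) {
    x0 <- matrix(state, 1)
    x0[1, iclamp] <- I_grid[i]
    state <- setNames(as.numeric(
      .settle_cpp(x0, m0, 300, 0.02, 1e-9, 100L)$states[1, ]), circuit$nodes$name)
    zeb[i] <- state[[zeb_node]]
  }
  hyb <- zeb > 100 & zeb <= 600
  if (!any(hyb)) {
    return(list(I_enter = NA_real_, I_exit = NA_real_, width = 0, zeb = zeb))
  }
  list(I_enter = I_grid[which(hyb)[1]], I_exit = I_grid[max(which(hyb))],
       width = I_grid[max(which(hyb))] - I_grid[which(hyb)[1]], zeb = zeb)
}

#' Parameter sensitivity of the hybrid-state signal window
#'
#' Perturbs each kinetic parameter by +/- `delta` (one at a time) and reports
#' the percent change in the width of the I_ext window over which a stable
#' hybrid E/M state exists, relative to the unperturbed width.
#'
#' @param circuit an `emt_circuit`.
#' @param delta relative perturbation (0.10 reproduces a +/-10% analysis).
#' @param params named parameters to perturb; default all `g`, `k`,
#'   thresholds and fold-changes.
#' @param I_range,n_points sweep settings for the underlying window measure.
#' @return data.frame: `param`, `direction`, `baseline_width`, `width`,
#'   `pct_change`, `vanished`.
#' @export
sensitivity_analysis <- function(circuit, delta = 0.10, params = NULL,
                                 I_range, n_points = 400) {
  if (is.null(params)) params <- names(circuit_parameters(circuit))
  w0 <- hybrid_window(circuit, I_range, n_points = n_points)$width
  if (!is.finite(w0) || w0 <= 0) stop("baseline bifurcation has no hybrid window")
  rows <- list()
  for (p in params) {
    v0 <- get_parameter(circuit, p)
    for (dir in c(1, -1)) {
      ci <- set_parameter(circuit, p, v0 * (1 + dir * delta))
      wi <- tryCatch(hybrid_window(ci, I_range, n_points = n_points)$width,
                     error = function(e) NA_real_)
      vanished <- !is.finite(wi) || wi <= 0
      rows[[length(rows) + 1]] <- data.frame(
        param = p,
        direction = if (dir > 0) sprintf("+%.0f%%", 100 * delta) else sprintf("-%.0f%%", 100 * delta),
        baseline_width = w0,
        width = if (vanished) 0 else wi,
        pct_change = if (vanished) 100 else 100 * (wi - w0) / w0,
        vanished = vanished
      )
    }
  }
  do.call(rbind, rows)
}
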