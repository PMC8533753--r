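#' Right-hand side of the circuit ODE system
#'
#' Each dynamic node's derivative is its basal production rate multiplied by
#' the product of shifted-Hill multipliers over its incoming edges (the ZEB
#' protein is translated from ZEB mRNA through the combinatorial microRNA-
#' binding module), minus first-order degradation. Clamped nodes (the external
#' signal) have zero derivative.
#'
#' @param state named numeric vector of molecule levels (one per node).
#' @param circuit an `emt_circuit`.
#' @return named numeric vector of time derivatives (molecules/hour).
#' @export
ode_rhs <- function(state, circuit) {
  m <- compile_model(circuit)
  state <- align_state(state, m$node_names)
  if (any(state < 0)) stop("ode_rhs: levels must be non-negative")
  dx <- .rhs_cpp(state, m)
  setNames(dx, m$node_names)
}

align_state <- function(state, node_names) {
  if (!is.null(names(state))) {
    missing <- setdiff(node_names, names(state))
    if (length(missing)) stop("state is missing nodes: ", paste(missing, collapse = ", "))
    state <- state[node_names]
  } else if (length(state) != length(node_names)) {
    stop("state length does not match number of nodes")
  }
  as.numeric(state)
}

# Default initial state: clamped signal node at its configured level, dynamic
# nodes at `level`.
default_state <- function(circuit, level = 0) {
  nd <- circuit$nodes
  x <- rep(level, nrow(nd))
  x[nd$clamped] <- circuit$signal$value
  setNames(x, nd$name)
}

#' Integrate the circuit ODEs
#'
#' Deterministic time integration with the stiff-capable `deSolve::lsoda`
#' solver (absolute and relative tolerance 1e-6), suited to molecule counts
#' spanning 1 to 1e5.
#'
#' @param circuit an `emt_circuit`.
#' @param state0 named initial state; defaults to all dynamic nodes at 0.
#' @param t_end end time (hours), > 0.
#' @param dt_out output sampling interval (hours).
#' @param I_ext optional external signal level overriding the circuit's.
#' @return data.frame with a `time` column and one column per node.
#' @export
integrate_circuit <- function(circuit, state0 = NULL, t_end, dt_out = 1, I_ext = NULL) {
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (!is.null(I_ext)) circuit <- set_signal(circuit, I_ext)
  m <- compile_model(circuit)
  x0 <- if (is.null(state0)) default_state(circuit) else align_state(state0, m$node_names)
  x0[m$clamped == 1L] <- circuit$signal$value
  times <- seq(0, t_end, by = dt_out)
  fn <- function(t, y, p) list(.rhs_cpp(pmax(y, 0), m))
  sol <- deSolve::lsoda(y = x0, times = times, func = fn, parms = NULL,
                        atol = 1e-6, rtol = 1e-6)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failure (solver istate ", attr(sol, "istate")[1], ")")
  }
  out <- as.data.frame(sol)
  names(out) <- c("time", m$node_names)
  out[-1][out[-1] < 0 & out[-1] > -1e-8] <- 0
  out
}

#' Reshape a trajectory to tidy long format
#' @param traj data.frame from [integrate_circuit()].
#' @return data.frame with columns `time`, `node`, `level`.
#' @export
tidy_trajectory <- function(traj) {
  nodes <- setdiff(names(traj), "time")
  data.frame(
    time = rep(traj$time, times = length(nodes)),
    node = rep(nodes, each = nrow(traj)),
    level = unlist(traj[nodes], use.names = FALSE)
  )
}

# Deterministic low-discrepancy (Halton) points in [0,1]^d, used for
# reproducible multi-start grids without touching the global RNG.
halton_points <- function(n, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (d > length(primes)) stop("too many dimensions for the Halton grid")
  one_dim <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  vapply(seq_len(d), function(j) {
    vapply(seq_len(n), one_dim, numeric(1), base = primes[j])
  }, numeric(n)) |> matrix(nrow = n)
}

# Numeric Jacobian of the free (unclamped) subsystem at x_free.
free_jacobian <- function(f, x) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * (abs(x[j]) + 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  J
}

# Damped Newton iteration on the free subsystem. Returns list(root, ok).
newton_root <- function(f, x0, max_iter = 60, tol = 1e-10) {
  x <- x0
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    res <- max(abs(fx) / (abs(x) + 1))
    if (res < tol) return(list(root = x, ok = TRUE))
    J <- free_jacobian(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(list(root = x, ok = FALSE))
    a <- 1
    repeat {
      xn <- x + a * step
      xn[xn < 0] <- 0
      fn <- f(xn)
      if (all(is.finite(fn)) &&
          max(abs(fn) / (abs(xn) + 1)) < max(abs(fx) / (abs(x) + 1)) * (1 - 0.25 * a)) {
        x <- xn; fx <- fn; break
      }
      a <- a / 2
      if (a < 1e-6) return(list(root = x, ok = max(abs(fx) / (abs(x) + 1)) < 1e-8))
    }
  }
  list(root = x, ok = max(abs(fx) / (abs(x) + 1)) < 1e-8)
}

# Unregulated level scales used to place initial-condition grids.
node_scales <- function(circuit) {
  m <- compile_model(circuit)
  nd <- circuit$nodes
  hi <- nd$g / pmax(nd$k, 1e-12)
  for (e in seq_along(m$esrc)) {
    t <- m$etgt[e] + 1L
    hi[t] <- hi[t] * max(1, m$lam[e])
  }
  if (m$has_mirna) {
    p <- m$prot + 1L
    hi[p] <- nd$g[p] * hi[m$mrna + 1L] / nd$k[p]
  }
  hi[nd$clamped] <- pmax(circuit$signal$value, 1)
  pmax(hi, 1)
}

#' Find the fixed points of the circuit at a given signal level
#'
#' Multi-start root finding: damped Newton iterations launched from a
#' log-spaced low-discrepancy grid of initial conditions, supplemented by
#' trajectory settling from the same grid (which reliably lands on the stable
#' states). Duplicate roots are merged at relative distance < 1e-4, and
#' stability is classified from the eigenvalues of the numerically evaluated
#' Jacobian (stable when the largest real part < -1e-8).
#'
#' @param circuit an `emt_circuit`.
#' @param I_ext optional signal level (molecules); defaults to the circuit's.
#' @param n_starts number of multi-start initial conditions.
#' @param extra_starts optional matrix of additional starting states
#'   (columns = dynamic nodes) used for warm-started continuation.
#' @param settle_starts how many of the grid points are also settled by time
#'   integration before polishing.
#' @param t_settle settling horizon (hours).
#' @return data.frame of class `emt_steady_states`: one row per fixed point,
#'   columns per node plus `stable` and `I_ext`. Zero rows (with a warning)
#'   when no start converges.
#' @export
find_steady_states <- function(circuit, I_ext = NULL, n_starts = 48,
                               extra_starts = NULL, settle_starts = 12,
                               t_settle = 600) {
  if (!is.null(I_ext)) circuit <- set_signal(circuit, I_ext)
  validate_circuit(circuit)
  m <- compile_model(circuit)
  nd <- circuit$nodes
  free <- which(!nd$clamped)
  nf <- length(free)
  full_state <- function(xf) {
    x <- numeric(nrow(nd))
    x[nd$clamped] <- circuit$signal$value
    x[free] <- xf
    x
  }
  f <- function(xf) .rhs_cpp(full_state(pmax(xf, 0)), m)[free]

  scales <- node_scales(circuit)[free]
  H <- halton_points(n_starts, nf)
  lo <- pmax(scales * 1e-5, 1e-3)
  starts <- matrix(lo, n_starts, nf, byrow = TRUE) *
    (matrix(scales / lo, n_starts, nf, byrow = TRUE))^H

  # settle a subset to catch every stable attractor
  ns <- min(settle_starts, n_starts)
  X0 <- matrix(0, ns, nrow(nd))
  X0[, free] <- starts[seq_len(ns), , drop = FALSE]
  X0[, which(nd$clamped)] <- circuit$signal$value
  settled <- .settle_cpp(X0, m, t_settle, 0.02, 1e-9, 100L)$states[, free, drop = FALSE]

  cand <- rbind(starts, settled)
  if (!is.null(extra_starts)) cand <- rbind(cand, extra_starts)

  roots <- list()
  for (i in seq_len(nrow(cand))) {
    r <- newton_root(f, pmax(cand[i, ], 0))
    if (r$ok && all(r$root > -1e-9)) roots[[length(roots) + 1]] <- pmax(r$root, 0)
  }
  if (!length(roots)) {
    warning("no convergence from any start; returning empty state set")
    out <- as.data.frame(matrix(numeric(0), 0, nf + 2))
    names(out) <- c(nd$name[free], "stable", "I_ext")
    class(out) <- c("emt_steady_states", class(out))
    return(out)
  }
  R <- do.call(rbind, roots)
  keep <- !logical(nrow(R))
  for (i in seq_len(nrow(R))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(R))) {
      if (j <= i || !keep[j]) next
      if (max(abs(R[i, ] - R[j, ]) / (abs(R[i, ]) + 1)) < 1e-4) keep[j] <- FALSE
    }
  }
  R <- R[keep, , drop = FALSE]
  stable <- vapply(seq_len(nrow(R)), function(i) {
    J <- free_jacobian(f, R[i, ])
    max(Re(eigen(J, only.values = TRUE)$values)) < -1e-8
  }, logical(1))
  out <- as.data.frame(R)
  names(out) <- nd$name[free]
  out$stable <- stable
  out$I_ext <- circuit$signal$value
  class(out) <- c("emt_steady_states", class(out))
  out
}
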