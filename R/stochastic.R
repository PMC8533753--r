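# Stochastic cell-population model: the external EMT-inducing signal follows
# a mean-reverting Ornstein-Uhlenbeck process, and the thresholds of the
# KLF4 -| SNAIL and SNAIL -| KLF4 inhibitions carry slow epigenetic dynamics
# so that a persistently high silencer progressively locks its target off.

#' Ornstein-Uhlenbeck noise parameters for the external signal
#'
#' Defaults reproduce the study conditions: set-point 90,000 molecules,
#' relaxation rate 0.04 /h and noise intensity 80,000 molecules^2/h, giving a
#' stationary mean of `I0` and variance `N / (2 beta)` = 1e6.
#'
#' @param I0 signal set-point (molecules), > 0.
#' @param beta relaxation rate (1/hour), > 0.
#' @param N noise intensity (molecules^2/hour), >= 0.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(I0 = 90000, beta = 0.04, N = 80000) {
  if (I0 <= 0 || beta <= 0 || N < 0) stop("require I0 > 0, beta > 0, N >= 0")
  structure(list(I0 = I0, beta = beta, N = N), class = "noise_params")
}

#' One Euler-Maruyama step of the Ornstein-Uhlenbeck signal
#'
#' `I + beta (I0 - I) dt + sqrt(N dt) xi`, clamped at zero; `xi` is standard
#' normal (drawn internally unless supplied).
#'
#' @param I current signal level (molecules); vectorised.
#' @param dt time step (hours), > 0.
#' @param noise a `noise_params` list.
#' @param xi optional standard-normal increment(s) (for reproducibility).
#' @return updated signal level(s).
#' @export
ou_signal_step <- function(I, dt, noise = noise_params(), xi = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(xi)) xi <- rnorm(length(I))
  pmax(I + noise$beta * (noise$I0 - I) * dt + sqrt(noise$N * dt) * xi, 0)
}

#' Epigenetic feedback settings for the KLF4-SNAIL axis
#'
#' `alpha1` scales KLF4-mediated silencing of SNAIL (lowers the KLF4 -| SNAIL
#' threshold KS0), `alpha2` SNAIL-mediated silencing of KLF4 (lowers SK0);
#' `zeta` is the epigenetic timescale in hours. `form` selects how the
#' silencer level enters the silencing term: `"saturating"` (default) uses the
#' bounded occupancy X / (X + X0); `"linear"` uses X / X0; `"constant"` drops
#' the level dependence. With the saturating form any `alpha <= 1` preserves
#' positive thresholds; larger values are rejected.
#'
#' @param alpha1,alpha2 silencing strengths, in [0, 1].
#' @param zeta epigenetic timescale (hours), > 0.
#' @param form silencing-term form.
#' @return list of class `epi_params`.
#' @export
epi_params <- function(alpha1 = 0, alpha2 = 0, zeta = 100,
                       form = c("saturating", "linear", "constant")) {
  form <- match.arg(form)
  if (alpha1 < 0 || alpha2 < 0) stop("alpha values must be >= 0")
  if (form != "linear" && (alpha1 > 1 || alpha2 > 1)) {
    stop("alpha has an upper bound of 1: thresholds (molecule numbers) must stay positive")
  }
  if (zeta <= 0) stop("zeta must be > 0")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, zeta = zeta, form = form),
            class = "epi_params")
}

#' One step of the epigenetic threshold dynamics
#'
#' The thresholds relax toward baseline minus a silencing term on timescale
#' `zeta`:
#' \deqn{dKS_0/dt = (KS_0(0) - KS_0 - \alpha_1\, occ(K)\, KS_0(0)) / \zeta}
#' and symmetrically for SK0 with `alpha2` and SNAIL. Thresholds are floored
#' strictly above zero.
#'
#' @param state list with current `KS0`, `SK0` and baselines `KS0_base`,
#'   `SK0_base`.
#' @param K,S current KLF4 and SNAIL levels (molecules).
#' @param dt time step (hours).
#' @param epi an `epi_params` list.
#' @return the state list with updated `KS0`, `SK0`.
#' @export
epigenetic_update <- function(state, K, S, dt, epi = epi_params()) {
  if (dt <= 0) stop("dt must be > 0")
  occ <- switch(epi$form,
    saturating = c(K / (K + state$KS0_base), S / (S + state$SK0_base)),
    linear = c(K / state$KS0_base, S / state$SK0_base),
    constant = c(1, 1))
  state$KS0 <- state$KS0 + dt / epi$zeta *
    (state$KS0_base - state$KS0 - epi$alpha1 * occ[1] * state$KS0_base)
  state$SK0 <- state$SK0 + dt / epi$zeta *
    (state$SK0_base - state$SK0 - epi$alpha2 * occ[2] * state$SK0_base)
  state$KS0 <- max(state$KS0, 1e-4 * state$KS0_base)
  state$SK0 <- max(state$SK0, 1e-4 * state$SK0_base)
  state
}

epi_edge_indices <- function(circuit) {
  ed <- circuit$edges
  e1 <- which(ed$source == "KLF4" & ed$target == "SNAIL")
  e2 <- which(ed$source == "SNAIL" & ed$target == "KLF4")
  if (length(e1) != 1 || length(e2) != 1) {
    stop("circuit must contain the KLF4 -| SNAIL and SNAIL -| KLF4 edges")
  }
  c(e1, e2)
}

# Epithelial anchor state: stable state with the lowest ZEB mRNA at I_ext = 0.
epithelial_anchor <- function(circuit, zeb_node = "ZEBm") {
  ss <- find_steady_states(circuit, I_ext = 0)
  st <- ss[ss$stable, , drop = FALSE]
  if (!nrow(st)) stop("no stable state at I_ext = 0")
  st <- st[which.min(st[[zeb_node]]), ]
  x <- default_state(circuit)
  for (nm in setdiff(names(st), c("stable", "I_ext"))) x[nm] <- st[[nm]]
  x
}

#' Circuit with epigenetically silenced thresholds at their fixed point
#'
#' At steady state the threshold dynamics reduce to
#' `KS0* = KS0(0) (1 - alpha1 occ(K))` (and symmetrically for SK0), given the
#' molecular levels. Returns the circuit with both thresholds replaced by
#' these self-consistent values.
#'
#' @param circuit the KLF4-coupled `emt_circuit`.
#' @param epi an `epi_params` list.
#' @param levels named state vector supplying the KLF4 and SNAIL levels.
#' @return the modified circuit.
#' @export
epi_effective_circuit <- function(circuit, epi, levels) {
  e <- epi_edge_indices(circuit)
  base1 <- circuit$edges$threshold[e[1]]
  base2 <- circuit$edges$threshold[e[2]]
  K <- levels[["KLF4"]]; S <- levels[["SNAIL"]]
  occ <- switch(epi$form,
    saturating = c(K / (K + base1), S / (S + base2)),
    linear = c(K / base1, S / base2),
    constant = c(1, 1))
  circuit$edges$threshold[e[1]] <- max(base1 * (1 - epi$alpha1 * occ[1]), 1e-4 * base1)
  circuit$edges$threshold[e[2]] <- max(base2 * (1 - epi$alpha2 * occ[2]), 1e-4 * base2)
  circuit
}

#' Epithelial-exit signal under quasi-static epigenetic feedback
#'
#' Sweeps the external signal upward while tracking the lower (epithelial)
#' branch, with the silenced thresholds iterated to self-consistency at each
#' signal level; returns the largest signal at which the tracked branch still
#' classifies epithelial (ZEB mRNA <= 100 molecules). Reproduces how KLF4-
#' dominant silencing (`alpha1 > alpha2`) delays the exit from the epithelial
#' state and SNAIL-dominant silencing advances it.
#'
#' @param circuit the KLF4-coupled `emt_circuit`.
#' @param epi an `epi_params` list.
#' @param I_range,n_points upward signal sweep.
#' @param zeb_node phenotype readout node.
#' @return the epithelial-exit signal level (molecules).
#' @export
epithelial_exit_with_feedback <- function(circuit, epi = epi_params(),
                                          I_range = c(0, 200000),
                                          n_points = 60, zeb_node = "ZEBm") {
  I_grid <- seq(I_range[1], I_range[2], length.out = n_points)
  state <- epithelial_anchor(circuit, zeb_node)
  exit_I <- NA_real_
  for (I in I_grid) {
    for (it in 1:4) {  # alternate threshold and level relaxation
      ci <- epi_effective_circuit(set_signal(circuit, I), epi, state)
      m <- compile_model(ci)
      x0 <- matrix(state, 1)
      x0[1, which(ci$nodes$clamped)] <- I
      state <- setNames(as.numeric(
        .settle_cpp(x0, m, 400, 0.02, 1e-9, 100L)$states[1, ]), ci$nodes$name)
    }
    if (state[[zeb_node]] > 100) break
    exit_I <- I
  }
  exit_I
}

#' Simulate one cell under signal noise and epigenetic feedback
#'
#' Couples the circuit ODEs (RK4 sub-steps), the Euler-Maruyama
#' Ornstein-Uhlenbeck signal and the epigenetic threshold updates on a shared
#' clock. The cell starts at the epithelial steady state of the noise-free
#' system (signal off, thresholds at baseline); the final phenotype is read
#' from ZEB mRNA.
#'
#' @param circuit the KLF4-coupled `emt_circuit`.
#' @param noise a `noise_params` list.
#' @param epi an `epi_params` list.
#' @param t_end simulated time (hours).
#' @param dt noise/epigenetic time step (hours); the ODEs take `substeps`
#'   RK4 sub-steps per noise step.
#' @param substeps ODE sub-steps per noise update.
#' @param seed RNG seed for this cell.
#' @param record_every record the trajectory every this many noise steps.
#' @param state0 optional initial full state (defaults to the epithelial
#'   anchor).
#' @param zeb_node phenotype readout node.
#' @return list: `trajectory` (data.frame time, zeb, I, KS0, SK0), `final`
#'   (named state), `phenotype`.
#' @export
simulate_cell <- function(circuit, noise = noise_params(), epi = epi_params(),
                          t_end = 2000, dt = 0.1, substeps = 2L, seed = 1,
                          record_every = 50L, state0 = NULL, zeb_node = "ZEBm") {
  m <- compile_model(circuit)
  i_node <- which(circuit$nodes$clamped)
  if (length(i_node) != 1) stop("circuit must have exactly one clamped signal node")
  e <- epi_edge_indices(circuit)
  sil <- match(c("KLF4", "SNAIL"), circuit$nodes$name)
  x0 <- if (is.null(state0)) epithelial_anchor(circuit, zeb_node) else
    align_state(state0, m$node_names)
  x0[i_node] <- noise$I0
  nstep <- ceiling(t_end / dt)
  xi <- with_seed(seed, rnorm(nstep))
  form_code <- match(epi$form, c("saturating", "linear", "constant")) - 1L
  res <- .simulate_cell_cpp(
    x0, m, i_node - 1L, noise$I0, noise$beta, noise$N, xi, dt, as.integer(substeps),
    epi$alpha1 > 0 || epi$alpha2 > 0, e[1] - 1L, e[2] - 1L,
    sil[1] - 1L, sil[2] - 1L, epi$alpha1, epi$alpha2, epi$zeta,
    circuit$edges$threshold[e[1]], circuit$edges$threshold[e[2]], form_code,
    as.integer(record_every), match(zeb_node, m$node_names) - 1L)
  final <- setNames(res$final, m$node_names)
  if (any(!is.finite(final))) stop("numerical failure in cell simulation")
  list(trajectory = data.frame(time = res$time, zeb = res$zeb, I = res$I,
                               KS0 = res$KS0, SK0 = res$SK0),
       final = final,
       phenotype = classify_phenotype(final[[zeb_node]]))
}

#' Simulate a population of cells and summarise phenotype fractions
#'
#' Cells are independent; per-cell seeds derive deterministically from the
#' master seed, so the result does not depend on execution order. Fractions
#' are computed from final-time phenotype labels; stationarity is checked by
#' comparing fractions at `t_end` and `t_end / 2` (warning when any fraction
#' moves by more than 3 percentage points).
#'
#' @param circuit the KLF4-coupled `emt_circuit`.
#' @param n_cells number of cells (default 500).
#' @param alpha1,alpha2 epigenetic silencing strengths.
#' @param noise a `noise_params` list.
#' @param t_end,dt,substeps time settings as in [simulate_cell()].
#' @param master_seed master RNG seed.
#' @param epi_form silencing-term form (see [epi_params()]).
#' @param zeb_node phenotype readout node.
#' @return list of class `population_summary`: `fractions` (named, sums to 1),
#'   `n_cells`, `alpha1`, `alpha2`, `I0`, `final_zeb`, `stationary`.
#' @export
simulate_population <- function(circuit, n_cells = 500, alpha1 = 0, alpha2 = 0,
                                noise = noise_params(), t_end = 2000, dt = 0.1,
                                substeps = 2L, master_seed = 1,
                                epi_form = "saturating", zeb_node = "ZEBm") {
  if (n_cells < 1) stop("n_cells must be >= 1")
  epi <- epi_params(alpha1, alpha2, form = epi_form)
  seeds <- with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n_cells))
  x0 <- epithelial_anchor(circuit, zeb_node)
  zeb_final <- numeric(n_cells); zeb_half <- numeric(n_cells)
  half_steps <- floor(ceiling(t_end / dt) / 2)
  for (i in seq_len(n_cells)) {
    cell <- simulate_cell(circuit, noise, epi, t_end = t_end, dt = dt,
                          substeps = substeps, seed = seeds[i],
                          record_every = max(1L, half_steps), state0 = x0,
                          zeb_node = zeb_node)
    zeb_final[i] <- cell$final[[zeb_node]]
    zeb_half[i] <- cell$trajectory$zeb[1]
  }
  lab <- classify_phenotype(zeb_final)
  fr <- as.numeric(table(lab)) / n_cells
  names(fr) <- levels(lab)
  fr_half <- as.numeric(table(classify_phenotype(zeb_half))) / n_cells
  stationary <- max(abs(fr - fr_half)) <= 0.03
  if (!stationary) {
    warning("population fractions moved > 3 points between t_end/2 and t_end; ",
            "consider a longer t_end")
  }
  structure(list(fractions = fr, n_cells = n_cells, alpha1 = alpha1,
                 alpha2 = alpha2, I0 = noise$I0, final_zeb = zeb_final,
                 stationary = stationary), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> n = %d, alpha1 = %.2f, alpha2 = %.2f, I0 = %g\n",
              x$n_cells, x$alpha1, x$alpha2, x$I0))
  print(round(x$fractions, 3))
  invisible(x)
}

#' Phenotype-fraction grid over the epigenetic strengths
#'
#' Runs [simulate_population()] at each (alpha1, alpha2) combination.
#'
#' @param circuit the KLF4-coupled `emt_circuit`.
#' @param alpha1_values,alpha2_values non-empty numeric grids.
#' @param ... passed to [simulate_population()] (n_cells, noise, t_end, seed...).
#' @return data.frame: `alpha1`, `alpha2`, `epithelial`, `hybrid`,
#'   `mesenchymal`.
#' @export
alpha_grid <- function(circuit, alpha1_values, alpha2_values, ...) {
  if (!length(alpha1_values) || !length(alpha2_values)) stop("empty alpha grid")
  grid <- expand.grid(alpha1 = alpha1_values, alpha2 = alpha2_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- simulate_population(circuit, alpha1 = grid$alpha1[i],
                             alpha2 = grid$alpha2[i], ...)
    data.frame(alpha1 = s$alpha1, alpha2 = s$alpha2,
               epithelial = s$fractions[["epithelial"]],
               hybrid = s$fractions[["hybrid"]],
               mesenchymal = s$fractions[["mesenchymal"]])
  })
  do.call(rbind, res)
}
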