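test_that("noiseless OU signal is fixed at its set-point", {
  np <- noise_params(I0 = 90000, beta = 0.04, N = 0)
  I <- 90000
  for (i in 1:100) I <- ou_signal_step(I, 0.1, np)
  expect_equal(I, 90000)
  expect_error(ou_signal_step(1, -0.1, np), "dt")
  expect_error(noise_params(I0 = -1), "I0")
})

test_that("OU stationary moments match the closed forms", {
  np <- noise_params()
  set.seed(17)
  n <- 2e5; dt <- 0.1
  xi <- rnorm(n)
  tr <- numeric(n); I <- np$I0
  for (i in 1:n) { I <- ou_signal_step(I, dt, np, xi[i]); tr[i] <- I }
  expect_equal(mean(tr), np$I0, tolerance = 0.005)
  expect_equal(var(tr), np$N / (2 * np$beta), tolerance = 0.1)
})

test_that("epigenetic thresholds stay at baseline without feedback and relax
           exponentially with it", {
  st <- list(KS0 = 30000, SK0 = 150000, KS0_base = 30000, SK0_base = 150000)
  epi0 <- epi_params(0, 0)
  s <- st
  for (i in 1:50) s <- epigenetic_update(s, K = 5e4, S = 2e5, dt = 1, epi0)
  expect_equal(s$KS0, st$KS0)
  expect_equal(s$SK0, st$SK0)
  # constant silencer level: linear relaxation with timescale zeta to
  # base * (1 - alpha * occ)
  epi <- epi_params(0.6, 0.4, zeta = 100)
  K <- 5e4; S <- 2e5
  occ1 <- K / (K + st$KS0_base); occ2 <- S / (S + st$SK0_base)
  target1 <- st$KS0_base * (1 - epi$alpha1 * occ1)
  dt <- 0.5; nstep <- 400  # t = 200 h = 2 zeta
  s <- st
  for (i in 1:nstep) s <- epigenetic_update(s, K, S, dt, epi)
  expected <- target1 + (st$KS0 - target1) * (1 - dt / epi$zeta)^nstep
  expect_equal(s$KS0, expected, tolerance = 1e-10)
  expect_lt(s$KS0, st$KS0)        # silencing lowers the threshold
  expect_gt(s$KS0, 0)
  expect_error(epi_params(1.4, 0), "upper bound")
})

test_that("epigenetic silencing shifts the quasi-static epithelial exit", {
  circ <- klf4_circuit()
  e00 <- epithelial_exit_with_feedback(circ, epi_params(0, 0),
                                       I_range = c(40000, 160000), n_points = 30)
  e_klf4 <- epithelial_exit_with_feedback(circ, epi_params(0.75, 0.1),
                                          I_range = c(40000, 160000), n_points = 30)
  e_snail <- epithelial_exit_with_feedback(circ, epi_params(0.25, 0.75),
                                           I_range = c(40000, 160000), n_points = 30)
  expect_gt(e_klf4, e00)   # KLF4-dominant silencing delays EMT
  expect_lt(e_snail, e00)  # SNAIL-dominant silencing advances EMT
})

test_that("single-cell simulation is seed-deterministic and classifies its end state", {
  circ <- klf4_circuit()
  c1 <- simulate_cell(circ, t_end = 200, seed = 4, record_every = 100)
  c2 <- simulate_cell(circ, t_end = 200, seed = 4, record_every = 100)
  expect_identical(c1$trajectory, c2$trajectory)
  expect_identical(c1$final, c2$final)
  expect_s3_class(c1$phenotype, "factor")
})

test_that("deterministic limit: no noise and no feedback keeps cells epithelial", {
  circ <- klf4_circuit()
  np <- noise_params(I0 = 30000, beta = 0.04, N = 0)  # monostable-E regime
  cell <- simulate_cell(circ, noise = np, t_end = 500, seed = 1,
                        record_every = 1000)
  expect_equal(as.character(cell$phenotype), "epithelial")
  # whole population collapses onto the one deterministic phenotype
  pop <- simulate_population(circ, n_cells = 8, noise = np, t_end = 400,
                             master_seed = 2)
  expect_equal(unname(pop$fractions[["epithelial"]]), 1)
  expect_equal(sum(pop$fractions), 1)
})

test_that("population fractions sum to one and respond to the epigenetic strengths", {
  circ <- klf4_circuit()
  p00 <- simulate_population(circ, n_cells = 40, alpha1 = 0, alpha2 = 0,
                             t_end = 1000, master_seed = 7)
  p10 <- simulate_population(circ, n_cells = 40, alpha1 = 0.75, alpha2 = 0.1,
                             t_end = 1000, master_seed = 7)
  p01 <- suppressWarnings(
    simulate_population(circ, n_cells = 40, alpha1 = 0.25, alpha2 = 0.75,
                        t_end = 1000, master_seed = 7))
  for (p in list(p00, p10, p01)) expect_equal(sum(p$fractions), 1)
  expect_gt(p10$fractions[["epithelial"]], p00$fractions[["epithelial"]])
  expect_gt(p01$fractions[["mesenchymal"]], p00$fractions[["mesenchymal"]])
  expect_gt(p00$fractions[["hybrid"]], p01$fractions[["hybrid"]])
})

test_that("alpha grid reports one summary per combination", {
  circ <- klf4_circuit()
  gr <- alpha_grid(circ, c(0, 0.75), c(0.1), n_cells = 10, t_end = 400,
                   master_seed = 3)
  expect_equal(nrow(gr), 2)
  expect_equal(rowSums(gr[, c("epithelial", "hybrid", "mesenchymal")]),
               c(1, 1), ignore_attr = TRUE)
  expect_error(alpha_grid(circ, numeric(0), 1), "empty")
})
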