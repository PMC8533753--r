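test_that("phenotype classification uses the ZEB mRNA cutoffs", {
  expect_equal(as.character(classify_phenotype(c(50, 300, 700))),
               c("epithelial", "hybrid", "mesenchymal"))
  # boundary values fall to the lower phenotype
  expect_equal(as.character(classify_phenotype(c(100, 600))),
               c("epithelial", "hybrid"))
  expect_error(classify_phenotype(-1), "ZEB")
})

test_that("toggle switch fixed points match the brute-force nullcline oracle", {
  circ <- toggle_circuit()
  oracle_b <- toggle_fixed_points_oracle(circ)
  expect_length(oracle_b, 3)
  ss <- find_steady_states(circ, I_ext = 0)
  expect_equal(nrow(ss), 3)
  expect_equal(sum(ss$stable), 2)
  expect_equal(sort(ss$B), sort(oracle_b), tolerance = 1e-4)
  # symmetric switch: the unstable point sits at equal levels
  un <- ss[!ss$stable, ]
  expect_equal(un$A, un$B, tolerance = 1e-4)
})

test_that("control circuit sweeps from epithelial through hybrid to mesenchymal", {
  sc <- scan_pair()$control
  st <- sc$states[sc$states$stable, ]
  first_I <- vapply(split(st$I_ext, st$phenotype), function(x)
    if (length(x)) min(x) else NA_real_, numeric(1))
  expect_true(first_I[["epithelial"]] < first_I[["hybrid"]])
  # lowest-branch phenotype sequence along increasing signal is E -> H -> M
  lowest <- vapply(split(st, st$I_ext), function(d)
    as.character(d$phenotype[which.min(d$ZEBm)]), character(1))
  lowest <- unname(lowest[order(as.numeric(names(lowest)))])
  expect_equal(rle(lowest)$values, c("epithelial", "hybrid", "mesenchymal"))
})

test_that("KLF4 shifts the epithelial exit to stronger signals", {
  sp <- scan_pair()
  expect_gt(epithelial_exit(sp$klf4), epithelial_exit(sp$control))
})

test_that("steady states on a stable branch are invariant under integration", {
  circ <- klf4_circuit()
  sc <- scan_pair()$klf4
  st <- sc$states[sc$states$stable, ]
  pick <- st[round(seq(1, nrow(st), length.out = 4)), ]
  free <- setdiff(circ$nodes$name, "Iext")
  for (i in seq_len(nrow(pick))) {
    x0 <- default_state(circuit = circ)
    x0[free] <- as.numeric(pick[i, free])
    tr <- integrate_circuit(circ, state0 = x0, t_end = 50, dt_out = 50,
                            I_ext = pick$I_ext[i])
    xe <- unlist(tr[nrow(tr), free])
    expect_lt(max(abs(xe - x0[free]) / (x0[free] + 1)), 1e-3)
  }
})

test_that("phase diagram: KLF4-SNAIL repression strength moves the epithelial exit", {
  circ <- klf4_circuit()
  # stronger repression of SNAIL by KLF4 (lower lambda_KS) -> later exit
  pd <- phase_diagram(circ, "lam:KLF4->SNAIL", c(0.15, 0.3, 0.6),
                      I_range = c(40000, 140000), n_points = 50)
  ex <- unique(pd[, c("param_value", "epithelial_exit")])
  expect_true(all(diff(ex$epithelial_exit[order(ex$param_value)]) < 0))
  # stronger repression of KLF4 by SNAIL (lower lambda_SK) -> earlier exit
  pd2 <- phase_diagram(circ, "lam:SNAIL->KLF4", c(0.1, 0.25, 0.5),
                       I_range = c(40000, 140000), n_points = 50)
  ex2 <- unique(pd2[, c("param_value", "epithelial_exit")])
  expect_true(all(diff(ex2$epithelial_exit[order(ex2$param_value)]) > 0))
  expect_error(phase_diagram(circ, "lam:NOPE->SNAIL", 1, c(0, 1)), "unknown")
})

test_that("sensitivity analysis is exactly null at zero perturbation", {
  circ <- klf4_circuit()
  sens <- sensitivity_analysis(circ, delta = 0,
                               params = c("lam:KLF4->SNAIL", "g:KLF4"),
                               I_range = c(60000, 120000), n_points = 60)
  expect_equal(nrow(sens), 4)
  expect_true(all(sens$pct_change == 0))
  expect_false(any(sens$vanished))
})
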