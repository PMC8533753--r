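# Shared fixtures, built lazily so cheap test files stay cheap.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

klf4_circuit <- function() fixture("klf4", function() emt_circuit("klf4"))
control_circuit <- function() fixture("control", function() emt_circuit("control"))
toggle_circuit <- function() generate_toy_circuit("toggle_switch")

# brute-force fixed points of the symmetric toggle switch by 1-D sign scan
# on the composed nullcline B -> g/k * HS(g/k * HS(B))
toggle_fixed_points_oracle <- function(circ, n_grid = 20000) {
  g <- circ$nodes$g[1]; k <- circ$nodes$k[1]
  e <- circ$edges[1, ]
  f <- function(B) g / k * shifted_hill(B, e$threshold, e$hill, e$lambda)
  grid <- seq(0, 1.2 * g / k, length.out = n_grid)
  h <- vapply(grid, function(B) f(f(B)) - B, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (h[i] == 0 || sign(h[i]) != sign(h[i + 1])) {
      r <- uniroot(function(B) f(f(B)) - B, c(grid[i], grid[i + 1]))$root
      roots <- c(roots, r)
    }
  }
  unique(round(roots, 6))
}

# settle the full KLF4 and control scans once for the branch-comparison tests
scan_pair <- function() fixture("scan_pair", function() {
  list(
    klf4 = bifurcation_scan(klf4_circuit(), c(0, 200000), n_points = 80),
    control = bifurcation_scan(control_circuit(), c(0, 200000), n_points = 80)
  )
})
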