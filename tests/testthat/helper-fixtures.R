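# shared fixtures: parameter sets and small lattices used across test files

baseline_pars <- function() model_params(q = 0.2, D = 0.32, P = 0.1)

fixture_net <- function(params = baseline_pars(), rows = 6, cols = 6) {
  build_hex_network(rows, cols, k_baseline = fixed_point(params)$k_star)
}

# single hexagon with one freed node and one stiffened incident spring;
# small enough for brute-force energy minimization
hex_fixture <- function(stiff_factor = 2) {
  hx <- build_hex_network(1, 1)
  hx$nodes$boundary[1L] <- FALSE
  s1 <- hx$inc_springs[1L, 1L]
  hx$springs$stiffness[s1] <- stiff_factor
  hx
}

# exhaustive two-stage grid search over the free node of hex_fixture()
hex_grid_energy <- function(hx, half = 0.4, nres = 81L) {
  p0 <- cbind(hx$nodes$x, hx$nodes$y)
  search <- function(cx, cy, half) {
    xs <- seq(cx - half, cx + half, length.out = nres)
    ys <- seq(cy - half, cy + half, length.out = nres)
    best <- c(Inf, NA, NA)
    for (x in xs) {
      for (y in ys) {
        p <- p0; p[1L, ] <- c(x, y)
        e <- total_strain_energy(hx, p)
        if (e < best[1L]) best <- c(e, x, y)
      }
    }
    best
  }
  b <- search(p0[1L, 1L], p0[1L, 2L], half)
  b <- search(b[2L], b[3L], 2 * half / (nres - 1))
  b[1L]
}
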