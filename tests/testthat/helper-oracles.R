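# Independent brute-force oracle for the sigma-potential self-consistency:
# scalar double loops, plain successive substitution with mild relaxation and
# a much tighter tolerance than the package solver.
oracle_sigma_potential <- function(areas, T, constants = cosmo_constants()) {
  grid <- sigma_grid()
  p <- areas / sum(areas)
  RT <- 8.31446 * T / 1000
  n <- length(grid)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- max(grid[i], grid[j])
      don <- min(grid[i], grid[j])
      W[i, j] <- constants$alpha_prime / 2 * (grid[i] + grid[j])^2 +
        constants$c_hb * max(0, acc - constants$sigma_hb) *
          min(0, don + constants$sigma_hb)
    }
  }
  E <- exp(-W / RT)
  gam <- rep(1, n)
  for (it in seq_len(200000L)) {
    new <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) s <- s + p[j] * gam[j] * E[i, j]
      new[i] <- 1 / s
    }
    if (max(abs(new - gam)) < 1e-13) {
      gam <- new
      break
    }
    gam <- 0.3 * gam + 0.7 * new
  }
  RT * log(gam) / constants$a_eff
}

# Closed-form ideal solubility, written independently of the package.
oracle_ideal_solubility <- function(Tm, dHm_kJ, T) {
  min(exp(-(dHm_kJ * 1000 / 8.31446) * (1 / T - 1 / Tm)), 1)
}

# A toy profile concentrated in a handful of bins of the canonical grid.
toy_areas <- function(bins, areas) {
  a <- numeric(61)
  a[bins] <- areas
  a
}
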