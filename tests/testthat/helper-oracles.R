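# Independent oracles and tiny fixtures shared across tests.

# Brute-force Riemann (midpoint) average of the powder integrand; the
# reference the quadrature-based kernel is compared against.
riemann_kernel <- function(t, r, n = 1e6) {
  u <- (seq_len(n) - 0.5) / n
  omega <- 2 * pi * 52.04 / r^3
  mean(cos((1 - 3 * u^2) * omega * t))
}

# Minimal structure with arbitrary atoms; coords is an N x 3 matrix (one
# model) or a list of such matrices (multi-model).
make_structure <- function(atoms, coords) {
  if (is.matrix(coords)) coords <- list(coords)
  xyz <- do.call(rbind, lapply(coords, function(m) as.vector(t(m))))
  deerfit:::structure_model(atoms, xyz)
}

# Two isolated ALA-like residues whose CB atoms are `gap` Angstrom apart
# along x; no clash environment.
two_residue_fixture <- function(gap = 30) {
  atoms <- data.frame(
    elety = rep(c("N", "CA", "CB"), 2),
    resid = "ALA", chain = "A",
    resno = rep(c(1L, 2L), each = 3),
    elesy = rep(c("N", "C", "C"), 2),
    x = 0, y = 0, z = 0)
  coords <- rbind(
    c(-1.2, 1.0, 0), c(0, 0, 0), c(1.5, 0, 0),            # residue 1
    c(gap - 1.2 + 1.5, 1.0, 0), c(gap + 1.5, 0, 0), c(gap, 0, 0))  # residue 2, CB facing back
  make_structure(atoms, coords)
}

# Standard noiseless single-Gaussian trace used by several fitting tests.
reference_trace <- function(r0 = 3.5, sigma = 0.25, delta = 0.3, kappa = 0.2,
                            t_max = 3, n = 300, grid = distance_grid()) {
  P <- distance_distribution(grid, components = gaussian_components(r0, sigma))
  compose_signal(P, background_model(kappa, 3), delta,
                 seq(0, t_max, length.out = n), meta = list(pair = "p1"))
}
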