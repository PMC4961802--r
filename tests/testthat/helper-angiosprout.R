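# Shared fixtures: small, fast scenario configurations.

short_config <- function(total = 3000L, ..., potts = potts_params(),
                         signalling = signalling_params()) {
  scenario_config(signalling = signalling, potts = potts,
                  total_timesteps = total, ...)
}

# A tiny two-cell mesh (one band, two half-cylinder cells).
two_cell_mesh <- function() {
  build_sprout(lattice_config(n_cells = 2L, axial_length = 30L))
}

# A random two-cell mesh on a small lattice, for Hamiltonian oracles:
# two connected blobs grown from random seeds.
random_two_cell_owner <- function(L = 6L, C = 6L, n_sites = 8L) {
  owner <- matrix(0L, L, C)
  starts <- sample(L * C, 2)
  for (cell in 1:2) {
    sites <- starts[cell]
    while (length(sites) < n_sites) {
      p <- sites[sample.int(length(sites), 1)]
      r <- (p - 1L) %% L + 1L
      cc <- (p - 1L) %/% L + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < L) p + 1L,
              (cc %% C) * L + r, ((cc - 2L + C) %% C) * L + r)
      nb <- setdiff(nb, sites)
      nb <- nb[owner[nb] == 0L]
      if (!length(nb)) break
      q <- nb[sample.int(length(nb), 1)]
      sites <- c(sites, q)
    }
    owner[sites] <- cell
  }
  owner
}

# Independent full-Hamiltonian oracle, written from the energy definition
# (kept separate from the package's internals on purpose).
oracle_hamiltonian <- function(owner, alpha, J0, J_cm, gamma, lambda_A,
                               target_area) {
  L <- nrow(owner); C <- ncol(owner)
  pair_e <- function(o1, o2) {
    if (o1 == o2) return(0)
    if (o1 == 0L || o2 == 0L) return(J_cm + gamma)
    J0 - alpha[o1] - alpha[o2] + 2 * gamma
  }
  H <- 0
  for (r in seq_len(L)) {
    for (cc in seq_len(C)) {
      if (r < L) H <- H + pair_e(owner[r, cc], owner[r + 1L, cc])
      H <- H + pair_e(owner[r, cc], owner[r, cc %% C + 1L])
    }
  }
  for (cell in seq_along(alpha)) {
    H <- H + lambda_A * (sum(owner == cell) - target_area)^2
  }
  H
}

# Wrap a mesh around an owner matrix so R-level operations can run on it.
mesh_from_owner <- function(owner, n_cells, band_length = 10L) {
  cfg <- lattice_config(circumference = ncol(owner),
                        axial_length = nrow(owner),
                        cells_per_cross_section = 1L,
                        n_cells = as.integer(n_cells),
                        band_length = 1L)
  structure(list(owner = owner, config = cfg,
                 genotype = rep(GENOTYPE_WT, n_cells),
                 filopodia = list(cell = rep(0L, ncol(owner)),
                                  lo = rep(-1L, ncol(owner)),
                                  hi = rep(-1L, ncol(owner)))),
            class = "sprout_mesh")
}
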