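# Shared fixtures: built in code, deterministic.

# A typical responsive tumour parameter set calibrated to a given doubling
# time; the same construction is used in round-trip recovery fixtures.
typical_params <- function(td = 80, n_limp = 6, ckr = 0.2, ...) {
  calibrate_td(parameter_set(n_limp = n_limp,
                             lq = lq_params(0.3, 0.03, 1.5, 2),
                             ckr = ckr, t_necrosis = 300, p_sleep = 0.2,
                             ...),
               td = td)
}

# Spherical mask of radius r voxels inside a grid padded by `pad` voxels.
sphere_mask <- function(r, pad = 6L) {
  d <- as.integer(2 * r + 2 * pad + 1)
  ctr <- (d + 1) / 2
  g <- expand.grid(i = seq_len(d), j = seq_len(d), k = seq_len(d))
  inside <- (g$i - ctr)^2 + (g$j - ctr)^2 + (g$k - ctr)^2 <= r^2
  mask <- array(0, c(d, d, d))
  mask[as.matrix(g)[inside, , drop = FALSE]] <- 1
  mask
}

# Tiny two-GC lattice with prescribed occupancies (fractions of capacity),
# placed side by side along the first axis.
two_gc_lattice <- function(occ1, occ2, params = parameter_set(n_limp = 2)) {
  mask <- array(0, c(4, 3, 3))
  mask[2, 2, 2] <- 1
  mask[3, 2, 2] <- 1
  lat <- init_tumour(mask, tumour_profile(60, 30, 5), params)
  for (j in 1:2) {
    occ <- c(occ1, occ2)[j]
    lat$states[, j] <- lat$states[, j] * occ
  }
  lat
}

# Default study profiles
high_prolif <- function() tumour_profile(60, 30, 5)
low_prolif <- function() tumour_profile(10, 30, 5)
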