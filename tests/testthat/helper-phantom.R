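# Small, fast phantom for unit tests: 2 x 2 x 6 mm voxels over the same
# landmark geometry as the default spec. Coarser than the study-scale
# defaults (which the acceptance checks use), but exercises every code
# path in seconds.
small_phantom_spec <- function(concentration = 0, noise_sd = 10, seed = 1,
                               family = NULL, vat_total_volume = 1200, ...) {
  if (is.null(family))
    family <- if (concentration > 0) "beta" else "uniform"
  phantom_spec(grid_shape = c(120L, 92L, 52L),
               voxel_spacing = c(2, 2, 6),
               body_radius = c(110, 78),
               vat_total_volume = vat_total_volume,
               vat_profile = profile_spec(family, concentration),
               noise_sd = noise_sd,
               seed = seed,
               ...)
}

random_mask <- function(dim, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  label_mask(array(runif(prod(dim)) < p, dim), spacing)
}

# Brute-force pairwise AUC: mean of psi over all positive-negative pairs.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(psi)
}
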