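# Programmatic fixtures shared across the suite.

random_mask <- function(dm, p = 0.4, seed = NULL) {
  arr <- if (is.null(seed)) array(runif(prod(dm)) < p, dm)
  else trabsep:::with_seed(seed, array(runif(prod(dm)) < p, dm))
  mask3d(arr)
}

random_volume <- function(dm, bit_depth = 8L, seed = 1L) {
  maxv <- 2L^bit_depth
  arr <- trabsep:::with_seed(seed,
                             array(sample.int(maxv, prod(dm),
                                              replace = TRUE) - 1L, dm))
  volume3d(arr, bit_depth = bit_depth)
}

# Default noise-free validation phantom (closed cortex, strut lattice).
validation_phantom <- function(dim = c(64, 64, 64), ...) {
  generate_phantom(phantom_config(dim = dim, noise_sd = 0, ...))
}

phantom_roi <- function(ph) mask_or(ph$bone_truth, ph$marrow_truth)

# Recover bone and marrow from the phantom image the way a user would:
# dark-range threshold at the compartment midpoint, restricted to the ROI.
threshold_phantom <- function(ph) {
  mid <- (ph$config$bone_intensity + ph$config$marrow_intensity) %/% 2L
  roi <- phantom_roi(ph)
  marrow <- extract_marrow(roi, threshold_range(ph$image, 0, mid))
  bone <- mask_and(roi, as_mask(ph$image, mid + 1L))
  list(roi = roi, marrow = marrow, bone = bone)
}
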