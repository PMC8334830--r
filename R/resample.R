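#' Box-filter downsampling of a volume
#'
#' Averages non-overlapping `factor^3` blocks; partial blocks at the grid
#' edge are averaged over the voxels actually present, so arbitrary scan
#' sizes are accepted.  Means are rounded half-up to integer intensities
#' and the voxel size is multiplied by the factor.  When the dimensions
#' divide evenly the pre-rounding block means preserve the grid mean
#' exactly.
#'
#' @param v a [volume3d()].
#' @param factor integer downsampling factor, >= 1 (1 is the identity).
#' @return A [volume3d()] of size `ceiling(dim(v) / factor)`.
#' @export
downsample_volume <- function(v, factor) {
  if (!inherits(v, "volume3d")) stop_param("v must be a volume3d")
  factor <- check_ds_factor(factor)
  if (factor == 1L) return(v)
  means <- block_reduce(as_array(v), factor)
  out <- floor(means + 0.5)
  volume3d(out, voxel_size = voxel_size(v) * factor,
           bit_depth = bit_depth(v))
}

#' Downsample a binary mask by block foreground fraction
#'
#' Each `factor^3` block becomes foreground iff its foreground fraction is
#' `>= frac`.  The output is monotone in `frac`: raising it never adds
#' voxels.
#'
#' @param m a [mask3d()].
#' @param factor integer downsampling factor, >= 1.
#' @param frac block foreground fraction threshold, in `(0, 1]`
#'   (default 0.5).
#' @return A [mask3d()].
#' @export
downsample_mask <- function(m, factor, frac = 0.5) {
  if (!inherits(m, "mask3d")) stop_param("m must be a mask3d")
  factor <- check_ds_factor(factor)
  if (length(frac) != 1L || is.na(frac) || frac <= 0 || frac > 1)
    stop_param("frac must be in (0, 1]")
  if (factor == 1L) return(m)
  means <- block_reduce(as_array(m) * 1, factor)
  mask3d(means >= frac - 1e-12, voxel_size = voxel_size(m) * factor)
}

check_ds_factor <- function(factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != as.integer(factor))
    stop_param("factor must be a single integer >= 1")
  as.integer(factor)
}

# Mean over factor^3 blocks; partial edge blocks averaged over available
# voxels.  Returns an array of dim ceiling(d / factor).
block_reduce <- function(arr, factor) {
  d <- dim(arr)
  nb <- (d + factor - 1L) %/% factor
  b1 <- (seq_len(d[1L]) - 1L) %/% factor
  b2 <- (seq_len(d[2L]) - 1L) %/% factor
  b3 <- (seq_len(d[3L]) - 1L) %/% factor
  grp <- b1[slice.index(arr, 1L)] +
    nb[1L] * (b2[slice.index(arr, 2L)] + nb[2L] * b3[slice.index(arr, 3L)])
  sums <- rowsum(as.vector(arr), group = as.vector(grp))
  cnts <- rowsum(rep_len(1, length(arr)), group = as.vector(grp))
  array(sums / cnts, nb)   # rowsum sorts by group = column-major order
}

#' Plan a downsampling experiment
#'
#' Reports the expected feature (trabecular thickness) size in pixels at a
#' given downsampling factor, to two decimals, and warns when it falls
#' below 2 px — a regime where the segmentation becomes rough because
#' features approach the voxel size.
#'
#' @param reference_thickness_px average trabecular thickness in the
#'   full-resolution scan, pixels; must be > 0.
#' @param factor integer downsampling factor, >= 1.
#' @return Expected thickness in pixels, rounded half-up to 2 decimals.
#' @export
#' @examples
#' plan_downsample(13.29, 2)  # 6.65
#' plan_downsample(13.29, 8)  # 1.66, with a warning
plan_downsample <- function(reference_thickness_px, factor) {
  if (length(reference_thickness_px) != 1L ||
      is.na(reference_thickness_px) || reference_thickness_px <= 0)
    stop_param("reference_thickness_px must be > 0")
  factor <- check_ds_factor(factor)
  out <- floor(reference_thickness_px / factor * 100 + 0.5) / 100
  if (out < 2)
    warning(sprintf(paste0("expected feature size %.2f px is below 2 px; ",
                           "segmentation at this resolution will not be ",
                           "precise"), out), call. = FALSE)
  out
}
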