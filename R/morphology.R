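#' Euclidean ball structuring element
#'
#' Integer offsets `d` with `||d||_2 <= radius`, the structuring element of
#' every morphological step in the segmentation recipe.  Always contains
#' the origin and is symmetric under negation of any axis.
#'
#' @param radius non-negative integer, in voxels.
#' @return Integer matrix, one `(dz, dy, dx)` offset per row, with a
#'   `radius` attribute.
#' @export
#' @examples
#' nrow(ball_offsets(0))  # 1
#' nrow(ball_offsets(1))  # 7: centre + 6 face neighbours
#' nrow(ball_offsets(2))  # 33
ball_offsets <- function(radius) {
  radius <- check_radius(radius)
  r <- seq(-radius, radius)
  g <- expand.grid(dz = r, dy = r, dx = r)
  keep <- g$dz^2 + g$dy^2 + g$dx^2 <= radius^2
  off <- as.matrix(g[keep, , drop = FALSE])
  rownames(off) <- NULL
  structure(off, radius = radius)
}

check_radius <- function(radius) {
  if (length(radius) != 1L || is.na(radius) || radius < 0 ||
      radius != as.integer(radius))
    stop_param("radius must be a single non-negative integer, got ",
               deparse(substitute(radius)), " = ", radius)
  as.integer(radius)
}

# The recipe radii are defined for isotropic voxels only; a ball element on
# an anisotropic grid would be silently distorted, so refuse it.
check_isotropic <- function(m) {
  vs <- voxel_size(m)
  if (!is.null(vs) && diff(range(vs)) > 1e-12 * max(vs))
    stop_param("ball morphology requires isotropic voxels; got spacing (",
               paste(format(vs), collapse = ", "), ")")
  invisible(TRUE)
}

# Squared distance from every voxel to the nearest TRUE voxel (>= 1e12
# where the mask is empty).
sqdist_to <- function(arr) {
  d <- dim(arr)
  out <- cpp_sqdist(as.logical(arr), as.integer(d))
  dim(out) <- d
  out
}

pad_array <- function(arr, r, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, d + 2L * r)
  out[r + seq_len(d[1L]), r + seq_len(d[2L]), r + seq_len(d[3L])] <- arr
  out
}

crop_array <- function(arr, r, d) {
  arr[r + seq_len(d[1L]), r + seq_len(d[2L]), r + seq_len(d[3L]), drop = FALSE]
}

#' Binary morphology with a Euclidean ball
#'
#' Exact ball erosion, dilation, opening and closing on 3-D masks, the
#' computational substrate of the shrink-wrap recipe.  The normative
#' definitions are per-voxel: dilation sets a voxel where *any*
#' ball-offset neighbour is foreground, erosion where *every* ball-offset
#' neighbour is foreground; opening is erosion-then-dilation and closing
#' dilation-then-erosion with the same ball.  Outside the image counts as
#' background for all operations (so erosion shrinks at the borders);
#' closing is computed on a grid padded by `radius` voxels of background
#' and cropped back, which makes it exactly the infinite-grid closing —
#' the shrink-wrap can never clip against the image edge.
#'
#' The implementation uses an exact squared Euclidean distance transform
#' rather than offset scans, which is algebraically identical for ball
#' elements and much faster at recipe-scale radii.
#'
#' @param m a [mask3d()] with isotropic voxels.
#' @param radius non-negative integer ball radius in voxels; 0 is the
#'   identity for all four operations.
#' @return A [mask3d()] on the same grid.
#' @seealso [ball_offsets()], [segment_trabecular()]
#' @export
mask_dilate <- function(m, radius) {
  radius <- check_radius(radius)
  if (!inherits(m, "mask3d")) stop_param("m must be a mask3d")
  check_isotropic(m)
  if (radius == 0L) return(m)
  sq <- sqdist_to(as_array(m))
  mask3d(sq <= radius^2 + 0.5, voxel_size = voxel_size(m))
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(m, radius) {
  radius <- check_radius(radius)
  if (!inherits(m, "mask3d")) stop_param("m must be a mask3d")
  check_isotropic(m)
  if (radius == 0L) return(m)
  d <- dim(m)
  padded <- pad_array(as_array(m), radius, FALSE)
  sq <- sqdist_to(!padded)          # distance to background incl. outside
  keep <- sq > radius^2 + 0.5
  mask3d(crop_array(keep, radius, d), voxel_size = voxel_size(m))
}

#' @rdname mask_dilate
#' @export
mask_open <- function(m, radius) {
  mask_dilate(mask_erode(m, radius), radius)
}

#' @rdname mask_dilate
#' @export
mask_close <- function(m, radius) {
  radius <- check_radius(radius)
  if (!inherits(m, "mask3d")) stop_param("m must be a mask3d")
  check_isotropic(m)
  if (radius == 0L) return(m)
  d <- dim(m)
  vs <- voxel_size(m)
  padded <- mask3d(pad_array(as_array(m), radius, FALSE), voxel_size = vs)
  closed <- mask_erode(mask_dilate(padded, radius), radius)
  mask3d(crop_array(as_array(closed), radius, d), voxel_size = vs)
}

#' Boolean mask algebra
#'
#' Voxelwise AND / OR / NOT / set difference on masks, preserving grid
#' metadata and enforcing grid compatibility.
#'
#' @param a,b [mask3d()]s on the same grid.
#' @return A [mask3d()].
#' @export
mask_and <- function(a, b) {
  check_same_grid(a, b, "masks")
  mask3d(as_array(a) & as_array(b), voxel_size = voxel_size(a))
}

#' @rdname mask_and
#' @export
mask_or <- function(a, b) {
  check_same_grid(a, b, "masks")
  mask3d(as_array(a) | as_array(b), voxel_size = voxel_size(a))
}

#' @rdname mask_and
#' @export
mask_not <- function(a) {
  mask3d(!as_array(a), voxel_size = voxel_size(a))
}

#' @rdname mask_and
#' @export
mask_diff <- function(a, b) {
  check_same_grid(a, b, "masks")
  mask3d(as_array(a) & !as_array(b), voxel_size = voxel_size(a))
}
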