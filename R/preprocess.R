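#' Edge-preserving denoising
#'
#' Non-local means: each voxel becomes a weighted average of voxels in a
#' search window, weighted by patch similarity `exp(-MSE / strength^2)`.
#' Self-similar structure (flat marrow, flat bone) is averaged while the
#' bone/marrow edge is preserved, which is what the subsequent
#' gradient-based watershed needs.  Fully deterministic.  A separable
#' Gaussian blur is available as a cheap fallback.
#'
#' @param v a [volume3d()].
#' @param strength filter strength in intensity units (the `h` of NLM, or
#'   the Gaussian sigma in voxels for `method = "gaussian"`); must be > 0.
#' @param patch_radius half-width of the similarity patch, voxels (>= 1).
#' @param search_radius half-width of the search window, voxels (>= 1).
#' @param method `"nlm"` (default) or `"gaussian"`.
#' @return A denoised [volume3d()] on the same grid.
#' @export
denoise <- function(v, strength = 10, patch_radius = 1, search_radius = 2,
                    method = c("nlm", "gaussian")) {
  method <- match.arg(method)
  if (!inherits(v, "volume3d")) stop_param("v must be a volume3d")
  if (length(strength) != 1L || is.na(strength) || strength <= 0)
    stop_param("strength must be > 0")
  if (patch_radius < 1 || search_radius < 1)
    stop_param("patch_radius and search_radius must be >= 1")
  arr <- as_array(v)
  out <- if (method == "nlm") {
    res <- cpp_nlm(as.numeric(arr), as.integer(dim(arr)), strength,
                   as.integer(patch_radius), as.integer(search_radius))
    dim(res) <- dim(arr)
    res
  } else {
    gaussian_blur(arr, strength)
  }
  maxv <- 2L^bit_depth(v) - 1L
  out <- pmin(pmax(floor(out + 0.5), 0), maxv)
  volume3d(out, voxel_size = voxel_size(v), bit_depth = bit_depth(v))
}

# Separable Gaussian convolution with edge replication.
gaussian_blur <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) arr <- convolve_axis(arr, k, axis)
  arr
}

convolve_axis <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2L
  n <- dim(arr)[axis]
  idx <- function(i) pmin(pmax(i, 1L), n)   # replicate edges
  out <- array(0, dim(arr))
  for (j in seq_along(k)) {
    sel <- idx(seq_len(n) + (j - r - 1L))
    out <- out + k[j] * switch(axis,
                               arr[sel, , , drop = FALSE],
                               arr[, sel, , drop = FALSE],
                               arr[, , sel, drop = FALSE])
  }
  out
}

#' Greyscale range threshold
#'
#' Voxel is foreground iff `lo <= intensity <= hi`, both bounds inclusive —
#' matching the "0-70"-style marrow-space threshold ranges used on 8-bit
#' scans.  Complementary ranges `[0, t]` and `[t+1, max]` tile the grid.
#'
#' @param v a [volume3d()].
#' @param lo,hi inclusive intensity bounds, `0 <= lo <= hi <= 2^bit_depth - 1`.
#' @return A [mask3d()].
#' @export
#' @examples
#' v <- volume3d(array(c(0L, 70L, 71L, 200L), c(1, 2, 2)))
#' sum(threshold_range(v, 0, 70))  # 2
threshold_range <- function(v, lo, hi) {
  if (!inherits(v, "volume3d")) stop_param("v must be a volume3d")
  maxv <- 2L^bit_depth(v) - 1L
  if (hi < lo) stop_param("invalid threshold range: hi (", hi,
                          ") < lo (", lo, ")")
  if (lo < 0 || hi > maxv)
    stop_param("threshold range [", lo, ", ", hi, "] outside [0, ", maxv, "]")
  arr <- as_array(v)
  mask3d(arr >= lo & arr <= hi, voxel_size = voxel_size(v))
}

#' Gradient magnitude of a volume
#'
#' Central differences per axis with edge replication at the borders;
#' magnitude is the Euclidean norm of the three components.  This is the
#' height function flooded by [seeded_watershed()].
#'
#' @param v a [volume3d()].
#' @return A numeric 3-D array.
#' @export
gradient_magnitude <- function(v) {
  arr <- as_array(v)
  g2 <- array(0, dim(arr))
  for (axis in 1:3) {
    n <- dim(arr)[axis]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    d <- switch(axis,
                arr[hi, , , drop = FALSE] - arr[lo, , , drop = FALSE],
                arr[, hi, , drop = FALSE] - arr[, lo, , drop = FALSE],
                arr[, , hi, drop = FALSE] - arr[, , lo, drop = FALSE]) / 2
    g2 <- g2 + d^2
  }
  sqrt(g2)
}

#' Seeded watershed region assignment
#'
#' Priority-flood watershed on the gradient magnitude of `v`: seed voxels
#' keep their labels and unlabeled voxels are flooded in order of
#' ascending gradient, so region boundaries settle on greyscale edges.
#' Ties are broken by queue insertion order (first-come, first-served),
#' which makes the result fully deterministic and — on a constant volume —
#' identical to a multi-source breadth-first flood from the seeds in array
#' (column-major) order.  6-connected flooding.
#'
#' @param v a [volume3d()].
#' @param seeds a [label_map()] on the same grid; 0 = unassigned, labels
#'   >= 1 are flooded.  At least one nonzero seed voxel is required.
#' @return A [label_map()] with every voxel labeled.
#' @export
seeded_watershed <- function(v, seeds) {
  if (!inherits(v, "volume3d")) stop_param("v must be a volume3d")
  if (!inherits(seeds, "label_map")) stop_param("seeds must be a label_map")
  check_same_grid(v, seeds, "volume and seeds")
  if (!any(seeds > 0L)) stop_param("seeds must contain at least one label")
  g <- gradient_magnitude(v)
  lab <- cpp_priority_flood(as.numeric(g), as.integer(as_array(seeds)),
                            as.integer(dim(g)))
  dim(lab) <- dim(g)
  label_map(lab, voxel_size = voxel_size(v))
}

#' Extract one watershed region as a mask
#'
#' @param labels a [label_map()].
#' @param roi_label the label to isolate; must be present.
#' @return A [mask3d()] of voxels carrying `roi_label`.
#' @export
isolate_roi <- function(labels, roi_label) {
  if (!inherits(labels, "label_map")) stop_param("labels must be a label_map")
  if (!any(labels == roi_label))
    stop_param("label ", roi_label, " not present in label map")
  mask3d(as_array(labels) == roi_label, voxel_size = voxel_size(labels))
}

#' Restrict threshold-derived marrow to the region of interest
#'
#' The range threshold fires on everything dark (marrow *and* exterior
#' air); intersecting with the watershed ROI keeps only marrow belonging
#' to the bone of interest.
#'
#' @param roi a [mask3d()] of the bone-of-interest region.
#' @param marrow_by_threshold a [mask3d()] from [threshold_range()].
#' @return A [mask3d()]: `roi AND marrow_by_threshold`.
#' @export
extract_marrow <- function(roi, marrow_by_threshold) {
  mask_and(roi, marrow_by_threshold)
}

#' Remove sealed regions from the marrow space
#'
#' Mask arithmetic for foramen sealing (and for growth-plate-bridge
#' exclusion masks): returns `marrow AND NOT seal`.  Seal masks are
#' ordinary mask files, so a manual sealing session is a reproducible
#' artifact.
#'
#' @param marrow,seal [mask3d()]s on the same grid.
#' @return A [mask3d()].
#' @export
apply_seals <- function(marrow, seal) {
  mask_diff(marrow, seal)
}

#' Detect foramina: marrow in contact with the exterior
#'
#' A foramen is a channel through the cortex connecting the marrow space
#' to the exterior.  Its signature is marrow voxels 6-adjacent to the ROI
#' exterior (a non-ROI voxel or the image border).  Contact voxels are
#' grouped into 26-connected components; for each component the report
#' gives voxel count, centroid, bounding box and an estimated width in
#' voxels (the area-equivalent disc diameter of the contact patch —
#' approximately the channel diameter).
#'
#' @param marrow a [mask3d()]; must be a subset of `roi`.
#' @param roi a [mask3d()] of the bone + marrow region of interest.
#' @return A data frame of class `foramen_report` with one row per contact
#'   component (columns `component`, `n_voxels`, `centroid_z/y/x`,
#'   `z0,z1,y0,y1,x0,x1`, `width_vox`) and the component label map in
#'   `attr(, "labels")`.  Zero rows when the cortex is closed.
#' @export
detect_foramina <- function(marrow, roi) {
  check_same_grid(marrow, roi, "marrow and roi")
  ma <- as_array(marrow)
  ra <- as_array(roi)
  if (any(ma & !ra))
    stop_consistency("marrow extends outside the region of interest")

  # exterior = non-ROI voxels; outside the grid counts as exterior
  ext <- !ra
  touches <- array(FALSE, dim(ma))
  for (axis in 1:3) for (s in c(-1L, 1L))
    touches <- touches | shift_array(ext, axis, s, fill = TRUE)
  contact <- ma & touches

  lab <- cpp_label_components(as.logical(contact), as.integer(dim(ma)), 26L)
  dim(lab) <- dim(ma)
  ncomp <- max(lab)

  if (ncomp == 0L) {
    # nothing to measure
    rep_df <- data.frame(component = integer(), n_voxels = integer(),
                         centroid_z = numeric(), centroid_y = numeric(),
                         centroid_x = numeric(),
                         z0 = integer(), z1 = integer(), y0 = integer(),
                         y1 = integer(), x0 = integer(), x1 = integer(),
                         width_vox = numeric())
  } else {
    idx <- which(lab > 0L)
    comp <- lab[idx]
    pos <- arrayInd(idx, dim(ma))
    rep_df <- do.call(rbind, lapply(seq_len(ncomp), function(cc) {
      sel <- comp == cc
      p <- pos[sel, , drop = FALSE]
      data.frame(component = cc, n_voxels = sum(sel),
                 centroid_z = mean(p[, 1L]), centroid_y = mean(p[, 2L]),
                 centroid_x = mean(p[, 3L]),
                 z0 = min(p[, 1L]), z1 = max(p[, 1L]),
                 y0 = min(p[, 2L]), y1 = max(p[, 2L]),
                 x0 = min(p[, 3L]), x1 = max(p[, 3L]),
                 # the contact patch is one voxel deep, so its voxel count
                 # is the channel cross-section area; the area-equivalent
                 # disc diameter is robust on a discrete grid, where a
                 # centre-to-centre inscribed-ball radius would
                 # systematically underestimate channels whose axis falls
                 # between lattice points
                 width_vox = 2 * sqrt(sum(sel) / pi))
    }))
  }
  structure(rep_df,
            labels = label_map(lab, voxel_size = voxel_size(marrow)),
            class = c("foramen_report", "data.frame"))
}

# Shift along one axis, filling vacated voxels with `fill`.
shift_array <- function(arr, axis, by, fill = FALSE) {
  n <- dim(arr)[axis]
  out <- array(fill, dim(arr))
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  sel2 <- function(a, i) switch(axis,
                                a[i, , , drop = FALSE],
                                a[, i, , drop = FALSE],
                                a[, , i, drop = FALSE])
  val <- sel2(arr, src)
  switch(axis,
         out[dst, , ] <- val,
         out[, dst, ] <- val,
         out[, , dst] <- val)
  out
}

#' @export
print.foramen_report <- function(x, ...) {
  cat(sprintf("<foramen_report> %d contact component(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export a foramen report to CSV or JSON
#'
#' @param report a `foramen_report` from [detect_foramina()].
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
export_foramen_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(report)
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    stop_param("unsupported report format '.", ext, "' (csv or json)")
  }
  invisible(path)
}
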