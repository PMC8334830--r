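#' Intersection over union of two masks
#'
#' `100 * |a AND b| / |a OR b|`, in percent.  Symmetric; 100 iff the masks
#' are identical.  When both masks are empty there is nothing to disagree
#' about, so the value is defined as 100 (documented convention).
#'
#' @param a,b [mask3d()]s on the same grid.
#' @return Overlap in percent.
#' @export
iou <- function(a, b) {
  check_same_grid(a, b, "masks")
  uni <- sum(as_array(a) | as_array(b))
  if (uni == 0) return(100)
  100 * sum(as_array(a) & as_array(b)) / uni
}

#' Relative difference between sealed and non-sealed results
#'
#' `100 * (sealed - nonsealed) / sealed`, rounded half away from zero to
#' two decimals (reported "to the nearest 0.01%").  Antisymmetry under
#' swapping the arguments holds on the numerator only, since the
#' denominator is always the sealed value.
#'
#' @param sealed_value reference value (from the sealed run); must be
#'   nonzero.
#' @param nonsealed_value comparison value.
#' @return Signed percent difference, rounded to 2 decimals.
#' @export
#' @examples
#' relative_difference(200, 198)  # 1.00
relative_difference <- function(sealed_value, nonsealed_value) {
  if (length(sealed_value) != 1L || is.na(sealed_value) ||
      sealed_value == 0)
    stop_param("sealed_value must be a single nonzero number")
  round_half_away(100 * (sealed_value - nonsealed_value) / sealed_value, 2L)
}

round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Trabecular bone volume fraction (BV/TV)
#'
#' Trabecular bone volume over total volume of the trabecular compartment.
#' TV is the shrink-wrapped, smoothed trabecular region the recipe itself
#' produces — the natural total-volume compartment of this method.
#'
#' @param res a `segmentation_result` from [segment_trabecular()].
#' @return Fraction in `[0, 1]`; 0 when the region is empty.
#' @export
bv_tv <- function(res) {
  if (!inherits(res, "segmentation_result"))
    stop_param("res must be a segmentation_result")
  tv <- sum(res$trabecular_region)
  if (tv == 0) return(0)
  sum(res$trabecular) / tv
}

#' Trabecular / cortical volume ratio
#'
#' @param res a `segmentation_result`.
#' @return `|trabecular| / |cortical|`.
#' @export
tb_ct_ratio <- function(res) {
  if (!inherits(res, "segmentation_result"))
    stop_param("res must be a segmentation_result")
  ct <- sum(res$cortical)
  if (ct == 0) stop_param("cortical compartment is empty: ratio undefined")
  sum(res$trabecular) / ct
}

# Deterministic quasi-uniform directions on the sphere (Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(z, r * cos(phi), r * sin(phi))   # (z, y, x) components
}

#' Degree of anisotropy from mean intercept length
#'
#' Standard fabric analysis: mean intercept length (MIL) is measured along
#' a deterministic Fibonacci lattice of sphere directions with a raster of
#' parallel test lines per direction; a second-rank fabric tensor is fit
#' by least squares to `1/MIL(n)^2 = n' A n`, and the degree of anisotropy
#' is computed from the principal MIL values `m_i = 1/sqrt(lambda_i)`.
#' The default convention is `DA = 1 - m_min/m_max`, bounded in `[0, 1)`
#' (0 = perfectly isotropic); `convention = "ratio"` gives the
#' `m_max/m_min >= 1` alternative.
#'
#' The direction set is deterministic; the seed only jitters the line
#' raster offsets, so a fixed seed gives a bit-identical value.
#'
#' @param trab a [mask3d()] containing both foreground and background.
#' @param n_directions number of test directions (>= 30).
#' @param n_lines_spacing spacing of the parallel test lines, voxels.
#' @param step marching step along each line, voxels.
#' @param seed integer seed for the raster jitter.
#' @param convention `"one_minus_ratio"` (default) or `"ratio"`.
#' @return A single number.
#' @export
degree_of_anisotropy <- function(trab, n_directions = 64, n_lines_spacing = 1,
                                 step = 0.5, seed = 1L,
                                 convention = c("one_minus_ratio", "ratio")) {
  convention <- match.arg(convention)
  if (!inherits(trab, "mask3d")) stop_param("trab must be a mask3d")
  if (n_directions < 30) stop_param("n_directions must be >= 30")
  arr <- as_array(trab)
  if (all(arr) || !any(arr))
    stop_consistency("mask has no bone/background interface: ",
                     "anisotropy undefined")

  dirs <- fibonacci_directions(n_directions)
  jit <- with_seed(seed, matrix(runif(2L * n_directions), ncol = 2L))
  raw <- cpp_mil(as.logical(arr), as.integer(dim(arr)), dirs, jit,
                 n_lines_spacing, step)
  ok <- raw[, 2L] > 0
  if (sum(ok) < 6L)
    stop_consistency("too few directions intersect the structure")
  mil <- raw[ok, 1L] / raw[ok, 2L]
  u <- dirs[ok, , drop = FALSE]

  # least-squares fabric tensor: 1/MIL^2 = u' A u
  X <- cbind(u[, 1L]^2, u[, 2L]^2, u[, 3L]^2,
             2 * u[, 1L] * u[, 2L], 2 * u[, 1L] * u[, 3L],
             2 * u[, 2L] * u[, 3L])
  y <- 1 / mil^2
  b <- solve(crossprod(X), crossprod(X, y))
  A <- matrix(c(b[1L], b[4L], b[5L],
                b[4L], b[2L], b[6L],
                b[5L], b[6L], b[3L]), 3L, 3L)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, max(ev) * 1e-9)   # numerical guard
  m <- 1 / sqrt(ev)                # principal mean intercept lengths
  if (convention == "one_minus_ratio") 1 - min(m) / max(m)
  else max(m) / min(m)
}

#' Full metrics report for a segmentation
#'
#' @param res a `segmentation_result`.
#' @param da also compute the degree of anisotropy (slower).
#' @param n_directions,seed passed to [degree_of_anisotropy()].
#' @return A one-row data frame: `bv_tv`, `tb_volume_mm3`, `ct_volume_mm3`,
#'   `tb_ct_ratio`, `degree_of_anisotropy` (NA unless `da = TRUE`).
#' @export
metrics_report <- function(res, da = FALSE, n_directions = 64, seed = 1L) {
  if (!inherits(res, "segmentation_result"))
    stop_param("res must be a segmentation_result")
  vvol <- prod(voxel_size(res$trabecular))
  nct <- sum(res$cortical)
  data.frame(
    bv_tv = bv_tv(res),
    tb_volume_mm3 = sum(res$trabecular) * vvol,
    ct_volume_mm3 = nct * vvol,
    tb_ct_ratio = if (nct > 0) sum(res$trabecular) / nct else NA_real_,
    degree_of_anisotropy = if (da)
      degree_of_anisotropy(res$trabecular, n_directions = n_directions,
                           seed = seed)
    else NA_real_
  )
}

#' Export a metrics report to CSV or JSON
#'
#' @param report a data frame from [metrics_report()].
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
export_metrics_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(report, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(as.list(report), path, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    stop_param("unsupported report format '.", ext, "' (csv or json)")
  }
  invisible(path)
}
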