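#' Greyscale 3-D volume
#'
#' A `volume3d` is a 3-D array of non-negative integer intensities with
#' physical voxel size metadata.  The axis convention is fixed throughout
#' the package: slice-major `(z, y, x)`, i.e. `v[z, y, x]`, with TIFF pages
#' mapping to z-slices.  Coordinates are voxel indices; a voxel is a closed
#' unit cell.
#'
#' @param data 3-D numeric array of intensities, all within
#'   `[0, 2^bit_depth - 1]`.
#' @param voxel_size positive length-3 numeric, physical voxel size in mm
#'   in `(z, y, x)` order.
#' @param bit_depth 8 or 16.
#' @return An object of class `volume3d` (an integer array with `voxel_size`
#'   and `bit_depth` attributes).
#' @seealso [mask3d()], [read_volume()], [as_mask()]
#' @export
#' @examples
#' v <- volume3d(array(7L, c(4, 4, 4)))
#' dim(v)
#' voxel_size(v)
volume3d <- function(data, voxel_size = c(1, 1, 1), bit_depth = 8L) {
  if (length(dim(data)) != 3L)
    stop_dim("volume3d data must be a 3-D array, got ",
             length(dim(data)), " dimension(s)")
  if (any(dim(data) < 1L)) stop_dim("all three dimensions must be >= 1")
  check_voxel_size(voxel_size)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop_param("bit_depth must be 8 or 16, got ", bit_depth)
  maxv <- 2L^bit_depth - 1L
  if (anyNA(data)) stop_param("volume intensities must not contain NA")
  if (min(data) < 0 || max(data) > maxv)
    stop_param("intensities must lie in [0, ", maxv, "] for ", bit_depth,
               "-bit data")
  d <- dim(data)
  data <- as.integer(round(data))
  dim(data) <- d
  structure(data,
            voxel_size = as.numeric(voxel_size),
            bit_depth = bit_depth,
            class = "volume3d")
}

#' Binary 3-D mask
#'
#' A logical grid on the same `(z, y, x)` convention as [volume3d()].
#' Every binary operation between masks/volumes enforces identical shape
#' and voxel size.
#'
#' @param data 3-D logical array.
#' @param voxel_size positive length-3 numeric `(z, y, x)` in mm.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop_dim("mask3d data must be a 3-D array")
  if (any(dim(data) < 1L)) stop_dim("all three dimensions must be >= 1")
  check_voxel_size(voxel_size)
  d <- dim(data)
  data <- as.logical(data)
  if (anyNA(data)) stop_param("mask must not contain NA")
  dim(data) <- d
  structure(data, voxel_size = as.numeric(voxel_size), class = "mask3d")
}

#' Integer label map
#'
#' Non-negative integer labels per voxel; 0 means unassigned.  Used for
#' watershed seeds and results.
#'
#' @param data 3-D integer array of labels (>= 0).
#' @param voxel_size positive length-3 numeric `(z, y, x)` in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop_dim("label_map data must be a 3-D array")
  check_voxel_size(voxel_size)
  d <- dim(data)
  data <- as.integer(data)
  if (anyNA(data) || min(data) < 0L)
    stop_param("labels must be non-negative integers")
  dim(data) <- d
  structure(data, voxel_size = as.numeric(voxel_size), class = "label_map")
}

check_voxel_size <- function(vs) {
  if (length(vs) != 3L || !is.numeric(vs) || anyNA(vs) || any(vs <= 0))
    stop_param("voxel_size must be a positive (z, y, x) triple")
  invisible(vs)
}

#' @export
#' @rdname volume3d
voxel_size <- function(x) attr(x, "voxel_size")

#' @export
#' @rdname volume3d
bit_depth <- function(x) attr(x, "bit_depth")

# Strip class/attrs, keep dims.
as_array <- function(x) {
  y <- unclass(x)
  attr(y, "voxel_size") <- NULL
  attr(y, "bit_depth") <- NULL
  y
}

# Grid compatibility guard used by every binary mask/volume operation.
check_same_grid <- function(a, b, what = "operands") {
  if (!identical(dim(a), dim(b)))
    stop_grid(what, " are on different grids: ",
              paste(dim(a), collapse = "x"), " vs ",
              paste(dim(b), collapse = "x"))
  va <- voxel_size(a); vb <- voxel_size(b)
  if (!is.null(va) && !is.null(vb) && !isTRUE(all.equal(va, vb)))
    stop_grid(what, " have different voxel sizes")
  invisible(TRUE)
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, %d-bit, voxel size (z,y,x) = (%s) mm\n",
              paste(dim(x), collapse = " x "), bit_depth(x),
              paste(format(voxel_size(x)), collapse = ", ")))
  cat(sprintf("  intensity range [%d, %d]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> %s voxels, %d foreground (%.2f%%)\n",
              paste(dim(x), collapse = " x "), sum(x),
              100 * mean(x)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  labs <- sort(unique(as.vector(x)))
  cat(sprintf("<label_map> %s voxels, labels: %s\n",
              paste(dim(x), collapse = " x "),
              paste(utils::head(labs, 10), collapse = ", ")))
  invisible(x)
}

detect_format <- function(path, format_hint = NULL) {
  if (!is.null(format_hint) && format_hint != "auto") return(format_hint)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff",
         nrrd = "nrrd",
         stop_format("cannot detect volume format from extension '.",
                     ext, "' (use format = \"tiff\" or \"nrrd\")"))
}

#' Read a 3-D volume from a multi-page TIFF or NRRD file
#'
#' The format is detected from the file extension unless `format` is given.
#' NRRD files carry voxel spacing in their `space directions` field and it
#' is restored to full precision; TIFF stacks carry no z-spacing, so the
#' spacing defaults to `(1, 1, 1)` with a warning.  All recipe radii are in
#' voxels, so a default spacing never changes segmentation output, only
#' reported physical volumes.
#'
#' @param path file to read.
#' @param format `"auto"` (default), `"tiff"` or `"nrrd"`.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, format = "auto") {
  if (!file.exists(path)) stop_io("file not found: ", path)
  fmt <- detect_format(path, format)
  if (fmt == "tiff") read_tiff_volume(path) else read_nrrd(path)
}

#' Write a 3-D volume to multi-page TIFF or NRRD
#'
#' Lossless: `read_volume(write_volume(v, path))` reproduces `v`
#' bit-exactly (including spacing, for NRRD).
#'
#' @param v a [volume3d()].
#' @param path output path; format from extension unless `format` given.
#' @param format `"auto"`, `"tiff"` or `"nrrd"`.
#' @param encoding NRRD payload encoding, `"raw"` or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = "auto", encoding = "raw") {
  if (!inherits(v, "volume3d")) stop_param("v must be a volume3d")
  if (!dir.exists(dirname(path)))
    stop_io("parent directory does not exist: ", dirname(path))
  fmt <- detect_format(path, format)
  if (fmt == "tiff") write_tiff_volume(v, path) else write_nrrd(v, path, encoding)
  invisible(path)
}

read_tiff_volume <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop_io("cannot read TIFF '", path,
                                                "': ", conditionMessage(e)))
  if (length(pages) < 2L)
    stop_dim("'", path, "' has a single page: a 2-D image is not a volume")
  first <- pages[[1L]]
  if (length(dim(first)) != 2L)
    stop_format("'", path, "' is not single-channel greyscale")
  bits <- attr(first, "bits.per.sample")
  bits <- if (is.null(bits)) NA_integer_ else as.integer(bits)
  if (is.na(bits)) bits <- if (max(vapply(pages, max, 0)) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L))
    stop_format("unsupported TIFF sample depth: ", bits, " bits")
  nz <- length(pages)
  ny <- nrow(first); nx <- ncol(first)
  arr <- array(0L, c(nz, ny, nx))
  for (p in seq_len(nz)) {
    pg <- pages[[p]]
    if (!identical(dim(pg)[1:2], c(ny, nx)))
      stop_format("TIFF pages have inconsistent dimensions")
    arr[p, , ] <- pg
  }
  warning("TIFF carries no z-spacing; defaulting voxel size to (1, 1, 1)",
          call. = FALSE)
  volume3d(arr, voxel_size = c(1, 1, 1), bit_depth = bits)
}

write_tiff_volume <- function(v, path) {
  maxv <- 2^bit_depth(v) - 1
  arr <- as_array(v)
  pages <- lapply(seq_len(dim(arr)[1L]),
                  function(z) arr[z, , , drop = TRUE] / maxv)
  ok <- tryCatch(tiff::writeTIFF(pages, path,
                                 bits.per.sample = bit_depth(v),
                                 compression = "none"),
                 error = function(e) stop_io("cannot write TIFF '", path,
                                             "': ", conditionMessage(e)))
  invisible(ok)
}

#' Threshold a volume into a mask
#'
#' Voxel is foreground iff its intensity is `>= foreground_min`.  Raising
#' the cutoff never adds voxels (monotone).
#'
#' @param v a [volume3d()].
#' @param foreground_min minimum foreground intensity.
#' @return A [mask3d()] on the same grid.
#' @export
as_mask <- function(v, foreground_min) {
  if (!inherits(v, "volume3d")) stop_param("v must be a volume3d")
  mask3d(as_array(v) >= foreground_min, voxel_size = voxel_size(v))
}

#' Read / write a binary mask
#'
#' Masks are serialized as 8-bit volumes with 0 = background and
#' 255 = foreground, for maximal portability across image tools.
#'
#' @param path file path (TIFF or NRRD).
#' @param foreground_min intensities at or above this read as foreground.
#' @param m a [mask3d()].
#' @param format,encoding see [write_volume()].
#' @return `read_mask`: a [mask3d()]; `write_mask`: `path`, invisibly.
#' @export
read_mask <- function(path, foreground_min = 128) {
  as_mask(read_volume(path), foreground_min)
}

#' @rdname read_mask
#' @export
write_mask <- function(m, path, format = "auto", encoding = "raw") {
  if (!inherits(m, "mask3d")) stop_param("m must be a mask3d")
  v <- volume3d(array(ifelse(as_array(m), 255L, 0L), dim(m)),
                voxel_size = voxel_size(m), bit_depth = 8L)
  write_volume(v, path, format = format, encoding = encoding)
}
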