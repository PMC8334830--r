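#' Parameters of the trabecular segmentation recipe
#'
#' The four ball radii, in voxels, of the marrow shrink-wrap algorithm.
#' The defaults `(3, 25, 1, 3)` are the published recipe: a 3-voxel ball
#' opening that smooths the marrow and deletes small foramina, a 25-voxel
#' ball closing that shrink-wraps the marrow over the trabeculae, a
#' 1-voxel ball opening that removes aberrant single voxels, and a 3-voxel
#' erosion of the marrow space whose subtraction from the shrink-wrapped
#' region leaves the trabecular layer.  `r_marrow_erode` shares its
#' published value with `r_open_initial` but is an independent parameter.
#'
#' @param r_open_initial radius of the first marrow opening (default 3).
#' @param r_close radius of the shrink-wrap closing (default 25).
#' @param r_open_final radius of the second, noise-removal opening
#'   (default 1).
#' @param r_marrow_erode radius of the marrow erosion subtracted from the
#'   shrink-wrapped region (default 3).
#' @return An object of class `recipe_params`.
#' @seealso [segment_trabecular()], [scale_params()]
#' @export
recipe_params <- function(r_open_initial = 3, r_close = 25,
                          r_open_final = 1, r_marrow_erode = 3) {
  p <- list(r_open_initial = r_open_initial, r_close = r_close,
            r_open_final = r_open_final, r_marrow_erode = r_marrow_erode)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0 || v != as.integer(v))
      stop_param(nm, " must be a single non-negative integer, got ", v)
    p[[nm]] <- as.integer(v)
  }
  structure(p, class = "recipe_params")
}

#' @export
print.recipe_params <- function(x, ...) {
  cat(sprintf(paste0("<recipe_params> open %d | close %d | open %d | ",
                     "marrow erode %d (voxels)\n"),
              x$r_open_initial, x$r_close, x$r_open_final, x$r_marrow_erode))
  invisible(x)
}

#' Scale recipe parameters for downsampled scans
#'
#' When a scan is downsampled by an integer factor, the recipe radii must
#' shrink by approximately the same factor so that each step acts at the
#' same physical scale (radii are whole voxels, so exact division is not
#' always possible).  Starting from the published defaults the scaled
#' values follow the published worked examples: factor 2 gives
#' `(1, 12, 1)`, factor 4 `(0, 6, 0)` and factor 8 `(0, 3, 0)` for the
#' initial opening / closing / final opening — the opening radii are
#' zeroed at factors 4 and 8 because even a single-voxel erosion would be
#' large relative to the feature size at those resolutions.  For any
#' other starting parameters or factor the rule is floor division, with
#' the closing radius never dropping below 1.
#'
#' @param params a [recipe_params()].
#' @param factor integer downsampling factor, >= 1.
#' @return A scaled [recipe_params()].
#' @export
#' @examples
#' scale_params(recipe_params(), 2)  # open 1 | close 12 | open 1
#' scale_params(recipe_params(), 8)  # open 0 | close 3  | open 0
scale_params <- function(params, factor) {
  if (!inherits(params, "recipe_params"))
    stop_param("params must be a recipe_params")
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != as.integer(factor))
    stop_param("factor must be a single integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(params)

  defaults <- recipe_params()
  if (identical(unclass(params), unclass(defaults)) &&
      factor %in% c(2L, 4L, 8L)) {
    # published override table for the default recipe
    tab <- list(`2` = c(1L, 12L, 1L, 1L),
                `4` = c(0L, 6L, 0L, 0L),
                `8` = c(0L, 3L, 0L, 0L))[[as.character(factor)]]
    return(recipe_params(tab[1L], tab[2L], tab[3L], tab[4L]))
  }
  recipe_params(
    r_open_initial = params$r_open_initial %/% factor,
    r_close = max(1L, params$r_close %/% factor),
    r_open_final = params$r_open_final %/% factor,
    r_marrow_erode = params$r_marrow_erode %/% factor
  )
}

#' Separate trabecular from cortical bone by marrow shrink-wrapping
#'
#' The core algorithm.  Starting from a binary marrow-space mask it
#' computes, in order:
#' \enumerate{
#'   \item `M1 = open(marrow, r_open_initial)` — smooth the marrow and
#'     delete small foramina so they are not shrink-wrapped;
#'   \item `W = close(M1, r_close)` — "shrink-wrap": grow the marrow over
#'     its concavities so the envelope covers the trabeculae;
#'   \item `W2 = open(W, r_open_final)` — second smoothing pass;
#'   \item `layer = W2 \ erode(marrow, r_marrow_erode)` — subtract the
#'     eroded marrow space, leaving the trabecular layer;
#'   \item `trabecular = layer AND bone` — keep only bone voxels (this
#'     removes the rare floating non-bone voxels near the shrink-wrap
#'     boundary; it is idempotent when unnecessary, so it is always
#'     applied);
#'   \item `cortical = bone \ trabecular`.
#' }
#' The subtraction in step 4 erodes the *raw* input marrow by default
#' (`erode_opened = FALSE`); set `erode_opened = TRUE` to erode the opened
#' marrow `M1` instead.  The result is bit-deterministic: identical inputs
#' give identical outputs.
#'
#' Trabecular and cortical masks always partition the bone input exactly;
#' `trabecular_region` is the shrink-wrapped, smoothed envelope `W2` and
#' serves as the total volume (TV) compartment for BV/TV.
#'
#' @param bone a [mask3d()] of all bone voxels (e.g. the complement of the
#'   marrow threshold within the ROI).
#' @param marrow a [mask3d()] of the marrow space, disjoint from `bone`.
#' @param params a [recipe_params()].
#' @param erode_opened erode the opened marrow instead of the raw marrow
#'   in the subtraction step.
#' @param keep_intermediates also return the opened marrow and the closed
#'   (pre-final-opening) envelope, for stage-by-stage inspection.
#' @return An object of class `segmentation_result`: list with elements
#'   `trabecular`, `cortical`, `trabecular_region`, `marrow_used`
#'   ([mask3d()]s), `params`, and optionally `intermediates` (named list).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(dim = c(32, 32, 32),
#'                                       cortex_thickness = 3,
#'                                       strut_spacing = 8,
#'                                       strut_thickness = 2,
#'                                       noise_sd = 0))
#' res <- segment_trabecular(ph$bone_truth, ph$marrow_truth,
#'                           recipe_params(1, 8, 0, 1))
#' iou(res$trabecular, ph$trab_truth)
segment_trabecular <- function(bone, marrow, params = recipe_params(),
                               erode_opened = FALSE,
                               keep_intermediates = FALSE) {
  if (!inherits(bone, "mask3d") || !inherits(marrow, "mask3d"))
    stop_param("bone and marrow must be mask3d objects")
  check_same_grid(bone, marrow, "bone and marrow")
  if (!inherits(params, "recipe_params"))
    stop_param("params must be a recipe_params")
  if (any(as_array(bone) & as_array(marrow)))
    stop_consistency("bone and marrow overlap: a voxel cannot be both")

  vs <- voxel_size(bone)
  if (!any(marrow)) {
    warning("marrow space is empty; trabecular output is empty",
            call. = FALSE)
    empty <- mask3d(array(FALSE, dim(bone)), voxel_size = vs)
    res <- list(trabecular = empty, cortical = bone,
                trabecular_region = empty, marrow_used = marrow,
                params = params)
    if (keep_intermediates)
      res$intermediates <- list(opened_marrow = empty, closed_region = empty)
    return(structure(res, class = "segmentation_result"))
  }

  m1 <- mask_open(marrow, params$r_open_initial)
  w  <- mask_close(m1, params$r_close)
  w2 <- mask_open(w, params$r_open_final)
  eroded <- mask_erode(if (erode_opened) m1 else marrow,
                       params$r_marrow_erode)
  layer <- mask_diff(w2, eroded)
  trab <- mask_and(layer, bone)
  cort <- mask_diff(bone, trab)

  res <- list(trabecular = trab, cortical = cort, trabecular_region = w2,
              marrow_used = marrow, params = params)
  if (keep_intermediates)
    res$intermediates <- list(opened_marrow = m1, closed_region = w)
  structure(res, class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  cat(sprintf("  trabecular: %d voxels\n", sum(x$trabecular)))
  cat(sprintf("  cortical:   %d voxels\n", sum(x$cortical)))
  cat(sprintf("  region:     %d voxels\n", sum(x$trabecular_region)))
  print(x$params)
  invisible(x)
}
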