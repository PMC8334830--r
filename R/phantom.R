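# Run code under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic bone phantom
#'
#' Describes a cortical shell of configurable thickness enclosing a
#' trabecular network, with optional foramina channels through the
#' cortex, compartment greyscale intensities, and additive Gaussian
#' noise.  Two trabecular generators are available: a regular strut
#' lattice (exact analytic ground truth, used for validation) and a
#' thresholded smoothed random field (more organic morphology).  A fixed
#' seed makes the whole phantom deterministic.
#'
#' Default intensities (bone 180, marrow 40 on 8-bit, noise sd 8) are set
#' so that a dark-range threshold of the style used on real scans (e.g.
#' `[0, 110]`, the compartment midpoint) recovers the marrow exactly in
#' the noise-free case.
#'
#' @param dim grid dimensions `(z, y, x)`.
#' @param shape cortex geometry, `"box"` or `"sphere"`.
#' @param margin exterior margin around the cortex, voxels.
#' @param cortex_thickness shell thickness, voxels (>= 1).
#' @param trab_model `"lattice"`, `"field"`, or `"none"`.
#' @param strut_thickness,strut_spacing lattice strut thickness and
#'   spacing in voxels (thickness < spacing).
#' @param correlation_length,fill_fraction random-field smoothing sigma
#'   (voxels) and target trabecular solid fraction.
#' @param foramina list of channels, each a list with `axis` (1 = z,
#'   2 = y, 3 = x), `radius` (voxels) and optional `offset` (in-plane
#'   `(a, b)` voxel offset from the channel axis through the centre).
#' @param bone_intensity,marrow_intensity compartment mean intensities.
#' @param noise_sd additive Gaussian noise standard deviation (0 = none).
#' @param bit_depth 8 or 16.
#' @param voxel_size physical voxel size `(z, y, x)` in mm.
#' @param seed integer; fixes all randomness.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(64, 64, 64), shape = c("box", "sphere"),
                           margin = 2, cortex_thickness = 4,
                           trab_model = c("lattice", "field", "none"),
                           strut_thickness = 3, strut_spacing = 10,
                           correlation_length = 3, fill_fraction = 0.25,
                           foramina = list(),
                           bone_intensity = 180, marrow_intensity = 40,
                           noise_sd = 8, bit_depth = 8,
                           voxel_size = c(1, 1, 1), seed = 1L) {
  shape <- match.arg(shape)
  trab_model <- match.arg(trab_model)
  if (length(dim) != 3L || any(dim < 8))
    stop_param("dim must be three values >= 8")
  if (cortex_thickness < 1) stop_param("cortex_thickness must be >= 1")
  if (margin < 0) stop_param("margin must be >= 0")
  if (trab_model == "lattice" && strut_thickness >= strut_spacing - strut_thickness)
    stop_param("degenerate lattice: strut thickness (", strut_thickness,
               ") must be smaller than the inter-strut gap (",
               strut_spacing - strut_thickness, ")")
  if (bone_intensity <= marrow_intensity)
    stop_param("bone_intensity must exceed marrow_intensity")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  maxv <- 2^bit_depth - 1
  if (bone_intensity > maxv)
    stop_param("bone_intensity exceeds the bit depth")
  for (f in foramina) {
    if (is.null(f$axis) || !f$axis %in% 1:3 || is.null(f$radius) ||
        f$radius < 1)
      stop_param("each foramen needs axis in {1,2,3} and radius >= 1")
  }
  structure(list(dim = as.integer(dim), shape = shape,
                 margin = as.integer(margin),
                 cortex_thickness = as.integer(cortex_thickness),
                 trab_model = trab_model,
                 strut_thickness = as.integer(strut_thickness),
                 strut_spacing = as.integer(strut_spacing),
                 correlation_length = correlation_length,
                 fill_fraction = fill_fraction,
                 foramina = foramina,
                 bone_intensity = as.integer(bone_intensity),
                 marrow_intensity = as.integer(marrow_intensity),
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a synthetic bone phantom with ground truth
#'
#' Builds the greyscale image and voxel-exact compartment truth masks for
#' a [phantom_config()].  The truth masks satisfy: cortex and trabecular
#' truths are disjoint and their union is the bone truth; bone, marrow
#' and exterior truths are pairwise disjoint and tile the grid; with zero
#' foramina no marrow voxel has a non-bone 6-connected path to the
#' exterior.
#'
#' @param cfg a [phantom_config()].
#' @return An object of class `phantom_truth`: list with `image`
#'   ([volume3d()]), `bone_truth`, `marrow_truth`, `cortex_truth`,
#'   `trab_truth`, `exterior_truth` ([mask3d()]s), `foramen_masks` (list
#'   of [mask3d()]s, one per configured channel), and `config`.
#' @export
generate_phantom <- function(cfg) {
  if (!inherits(cfg, "phantom_config"))
    stop_param("cfg must be a phantom_config")
  d <- cfg$dim
  iz <- slice.index(array(0L, d), 1L)
  iy <- slice.index(array(0L, d), 2L)
  ix <- slice.index(array(0L, d), 3L)

  if (cfg$shape == "box") {
    lo <- rep(cfg$margin + 1L, 3L)
    hi <- d - cfg$margin
    t <- cfg$cortex_thickness
    outer <- iz >= lo[1L] & iz <= hi[1L] & iy >= lo[2L] & iy <= hi[2L] &
      ix >= lo[3L] & ix <= hi[3L]
    cavity <- iz >= lo[1L] + t & iz <= hi[1L] - t &
      iy >= lo[2L] + t & iy <= hi[2L] - t &
      ix >= lo[3L] + t & ix <= hi[3L] - t
  } else {
    ctr <- (d + 1) / 2
    rad2 <- (iz - ctr[1L])^2 + (iy - ctr[2L])^2 + (ix - ctr[3L])^2
    R <- min(d) / 2 - cfg$margin
    outer <- rad2 <= R^2
    cavity <- rad2 <= (R - cfg$cortex_thickness)^2
  }
  if (!any(cavity))
    stop_param("geometry error: cavity is empty after discretization")
  cortex <- outer & !cavity

  trab <- switch(cfg$trab_model,
    none = array(FALSE, d),
    lattice = lattice_struts(iz, iy, ix, cfg, d, cavity),
    field = field_struts(d, cfg) & cavity
  )
  marrow <- cavity & !trab

  # carve foramina channels through the cortex (channel voxels become
  # marrow, connecting the cavity to the exterior)
  foramen_masks <- list()
  if (cfg$shape == "box") {
    ctr <- (d + 1) / 2
  }
  for (f in cfg$foramina) {
    off <- if (is.null(f$offset)) c(0, 0) else f$offset
    ax <- f$axis
    others <- setdiff(1:3, ax)
    ia <- list(iz, iy, ix)[[others[1L]]]
    ib <- list(iz, iy, ix)[[others[2L]]]
    ctr_all <- (d + 1) / 2
    inplane <- (ia - (ctr_all[others[1L]] + off[1L]))^2 +
      (ib - (ctr_all[others[2L]] + off[2L]))^2 <= f$radius^2
    ch <- inplane & cortex &
      (list(iz, iy, ix)[[ax]] > ctr_all[ax])   # one side only
    cortex <- cortex & !ch
    marrow <- marrow | ch
    foramen_masks <- c(foramen_masks,
                       list(mask3d(ch, voxel_size = cfg$voxel_size)))
  }

  bone <- cortex | trab
  exterior <- !outer

  base <- array(cfg$marrow_intensity, d)
  base[bone] <- cfg$bone_intensity
  img <- volume3d(base, voxel_size = cfg$voxel_size,
                  bit_depth = cfg$bit_depth)
  if (cfg$noise_sd > 0)
    img <- add_noise(img, cfg$noise_sd, seed = cfg$seed)

  vs <- cfg$voxel_size
  structure(list(
    image = img,
    bone_truth = mask3d(bone, voxel_size = vs),
    marrow_truth = mask3d(marrow, voxel_size = vs),
    cortex_truth = mask3d(cortex, voxel_size = vs),
    trab_truth = mask3d(trab, voxel_size = vs),
    exterior_truth = mask3d(exterior, voxel_size = vs),
    foramen_masks = foramen_masks,
    config = cfg
  ), class = "phantom_truth")
}

# Orthogonal rod lattice: a voxel is strut where at least two of the
# three per-axis phase conditions hold, giving connected rods along all
# three axes.  The network is confined to the cavity shrunk by one
# inter-strut gap on every side, so a marrow jacket at least as wide as
# the gaps separates it from the endosteal wall: the jacket survives any
# opening that the gaps survive, which keeps the shrink-wrap sealed at
# the wall.  (Real trabeculae anastomose with the cortex; that contact
# zone is a documented limitation of this generator.)
lattice_struts <- function(iz, iy, ix, cfg, d, cavity) {
  s <- cfg$strut_spacing
  t <- cfg$strut_thickness
  g <- s - t                                     # inter-strut gap
  wall <- cfg$margin + cfg$cortex_thickness
  if (cfg$shape == "box") {
    lo <- wall + g + 1L                          # first lattice voxel
    hi <- d - wall - g
    inner <- iz >= lo & iz <= hi[1L] & iy >= lo & iy <= hi[2L] &
      ix >= lo & ix <= hi[3L]
    anchor <- lo
  } else {
    ctr <- (d + 1) / 2
    R <- min(d) / 2 - cfg$margin
    inner <- (iz - ctr[1L])^2 + (iy - ctr[2L])^2 + (ix - ctr[3L])^2 <=
      (R - cfg$cortex_thickness - g)^2
    anchor <- 1L
  }
  phase <- function(i) ((i - anchor) %% s) < t
  pz <- phase(iz); py <- phase(iy); px <- phase(ix)
  ((pz & py) | (pz & px) | (py & px)) & inner & cavity
}

# Thresholded smoothed Gaussian random field.
field_struts <- function(d, cfg) {
  noise <- with_seed(cfg$seed + 1L, array(rnorm(prod(d)), d))
  sm <- gaussian_blur(noise, cfg$correlation_length)
  cut <- quantile(sm, 1 - cfg$fill_fraction)
  sm >= cut
}

#' Add Gaussian noise to a volume
#'
#' Independent Gaussian perturbation per voxel, rounded and clipped to the
#' bit depth; deterministic per seed, and the caller's RNG state is left
#' untouched.
#'
#' @param v a [volume3d()].
#' @param sd noise standard deviation in intensity units (>= 0).
#' @param seed integer seed.
#' @return A [volume3d()].
#' @export
add_noise <- function(v, sd, seed = 1L) {
  if (!inherits(v, "volume3d")) stop_param("v must be a volume3d")
  if (length(sd) != 1L || is.na(sd) || sd < 0)
    stop_param("sd must be >= 0")
  if (sd == 0) return(v)
  arr <- as_array(v)
  noise <- with_seed(seed, array(rnorm(length(arr), sd = sd), dim(arr)))
  maxv <- 2L^bit_depth(v) - 1L
  out <- pmin(pmax(floor(arr + noise + 0.5), 0), maxv)
  volume3d(out, voxel_size = voxel_size(v), bit_depth = bit_depth(v))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s, %s cortex, %s trabecular model\n",
              paste(dim(x$image), collapse = "x"), x$config$shape,
              x$config$trab_model))
  cat(sprintf("  bone %d | marrow %d | exterior %d voxels; %d foramen(ina)\n",
              sum(x$bone_truth), sum(x$marrow_truth), sum(x$exterior_truth),
              length(x$foramen_masks)))
  invisible(x)
}
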