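test_that("ball offsets enumerate the Euclidean ball", {
  b0 <- ball_offsets(0)
  expect_identical(nrow(b0), 1L)
  expect_true(all(b0[1, ] == 0))
  expect_identical(nrow(ball_offsets(1)), 7L)   # centre + 6 face neighbours
  expect_identical(nrow(ball_offsets(2)), 33L)
  for (r in 0:3) {
    b <- ball_offsets(r)
    expect_true(any(rowSums(abs(b)) == 0))            # contains origin
    expect_true(all(rowSums(b^2) <= r^2))
    # symmetric under negation of each axis
    key <- function(m) sort(apply(m, 1, paste, collapse = ","))
    for (ax in 1:3) {
      neg <- b; neg[, ax] <- -neg[, ax]
      expect_identical(key(neg), key(b))
    }
    # independent enumeration count
    s <- seq(-r, r)
    expect_identical(nrow(b),
                     sum(outer(outer(s^2, s^2, "+"), s^2, "+") <= r^2))
  }
  expect_error(ball_offsets(-1), class = "trabsep_param_error")
})

test_that("dilation and erosion match their per-voxel definitions", {
  # single centred voxel, radius 1, 5^3 -> the 7-voxel ball
  m <- mask3d(array(FALSE, c(5, 5, 5))); m[3, 3, 3] <- TRUE
  d1 <- mask_dilate(m, 1)
  expect_identical(sum(d1), 7L)
  expect_identical(array(as.logical(d1), dim(d1)),
                   oracle_dilate(array(as.logical(m), dim(m)), 1))
  # solid 5^3 cube centred in 9^3, radius 1 -> inner 3^3 cube
  cube <- mask3d(array(FALSE, c(9, 9, 9))); cube[3:7, 3:7, 3:7] <- TRUE
  er <- mask_erode(cube, 1)
  expect_identical(sum(er), 27L)
  expect_true(all(er[4:6, 4:6, 4:6]))
  # single voxel erodes to empty; erosion shrinks at borders
  expect_false(any(mask_erode(m, 1)))
  full <- mask3d(array(TRUE, c(4, 4, 4)))
  expect_identical(sum(mask_erode(full, 1)), 8L)  # only the 2^3 core
  # radius 0 is the identity everywhere
  rm5 <- random_mask(c(5, 5, 5), seed = 11)
  for (op in list(mask_dilate, mask_erode, mask_open, mask_close))
    expect_identical(as.vector(op(rm5, 0)), as.vector(rm5))
})

test_that("opening removes sub-ball features and closing fills holes", {
  # isolated radius-1 blob (7 voxels) vanishes under opening radius 3
  m <- mask3d(array(FALSE, c(11, 11, 11))); m[6, 6, 6] <- TRUE
  blob <- mask_dilate(m, 1)
  expect_identical(sum(blob), 7L)
  expect_false(any(mask_open(blob, 3)))
  # solid cube with one interior voxel removed: closing radius 1 fills it
  h <- mask3d(array(FALSE, c(9, 9, 9))); h[2:8, 2:8, 2:8] <- TRUE
  h[5, 5, 5] <- FALSE
  expect_identical(sum(mask_close(h, 1)), 343L)
  # opening a solid cube stays inside it and is idempotent
  cube <- mask3d(array(FALSE, c(13, 13, 13))); cube[2:12, 2:12, 2:12] <- TRUE
  op <- mask_open(cube, 2)
  expect_true(all(as.vector(op) <= as.vector(cube)))
  expect_identical(as.vector(mask_open(op, 2)), as.vector(op))
})

test_that("fast-path morphology equals the brute-force oracle on random masks", {
  for (seed in 1:6) {
    m <- random_mask(c(12, 12, 12), p = 0.35, seed = seed)
    a <- array(as.logical(m), dim(m))
    r <- (seed %% 3L) + 1L
    expect_identical(array(as.logical(mask_dilate(m, r)), dim(m)),
                     oracle_dilate(a, r), info = paste("dilate", seed))
    expect_identical(array(as.logical(mask_erode(m, r)), dim(m)),
                     oracle_erode(a, r), info = paste("erode", seed))
    expect_identical(array(as.logical(mask_open(m, r)), dim(m)),
                     oracle_open(a, r), info = paste("open", seed))
    expect_identical(array(as.logical(mask_close(m, r)), dim(m)),
                     oracle_close(a, r), info = paste("close", seed))
  }
})

test_that("duality: dilation is the complement of eroding the complement", {
  # the identity holds wherever both operands see the same neighbourhood,
  # i.e. on the interior of a grid padded by r (at the outer border the
  # mask's background and the complement's foreground both continue
  # off-grid, which a finite grid cannot represent for both at once)
  for (seed in 1:4) {
    r <- (seed %% 3L) + 1L
    m <- random_mask(c(10, 10, 10), seed = seed)
    d <- dim(m)
    a <- trabsep:::pad_array(array(as.logical(m), d), r, FALSE)
    pm <- mask3d(a)
    dil <- trabsep:::crop_array(array(as.logical(mask_dilate(pm, r)),
                                      dim(a)), r, d)
    ero <- trabsep:::crop_array(
      array(as.logical(mask_not(mask_erode(mask_not(pm), r))), dim(a)), r, d)
    expect_identical(dil, ero)
  }
})

test_that("morphology is monotone; opening/closing idempotent and bounded", {
  for (seed in 1:4) {
    r <- (seed %% 3L) + 1L
    small <- random_mask(c(10, 10, 10), p = 0.25, seed = seed)
    extra <- random_mask(c(10, 10, 10), p = 0.2, seed = seed + 100)
    big <- mask_or(small, extra)
    for (op in list(mask_dilate, mask_erode, mask_open, mask_close)) {
      os <- op(small, r); ob <- op(big, r)
      expect_true(all(as.vector(os) <= as.vector(ob)))
    }
    op1 <- mask_open(small, r)
    expect_true(all(as.vector(op1) <= as.vector(small)))      # anti-extensive
    expect_identical(as.vector(mask_open(op1, r)), as.vector(op1))
    cl1 <- mask_close(small, r)
    expect_true(all(as.vector(small) <= as.vector(cl1)))      # extensive
    expect_identical(as.vector(mask_close(cl1, r)), as.vector(cl1))
  }
})

test_that("opening equals the union of contained balls (exhaustive, small grid)", {
  r <- 2L
  m <- random_mask(c(8, 8, 8), p = 0.75, seed = 5)
  a <- array(as.logical(m), dim(m))
  off <- o_ball(r)
  un <- array(FALSE, dim(a))
  for (i in which(a)) {
    ctr <- arrayInd(i, dim(a))
    pts <- sweep(off, 2L, as.integer(ctr), "+")
    inside <- pts[, 1] >= 1 & pts[, 1] <= dim(a)[1] &
      pts[, 2] >= 1 & pts[, 2] <= dim(a)[2] &
      pts[, 3] >= 1 & pts[, 3] <= dim(a)[3]
    if (!all(inside)) next
    lin <- pts[, 1] + dim(a)[1] * (pts[, 2] - 1) +
      dim(a)[1] * dim(a)[2] * (pts[, 3] - 1)
    if (all(a[lin])) un[lin] <- TRUE
  }
  expect_identical(array(as.logical(mask_open(m, r)), dim(a)), un)
})

test_that("anisotropic grids are refused by ball morphology", {
  m <- mask3d(array(TRUE, c(4, 4, 4)), voxel_size = c(1, 1, 2))
  expect_error(mask_dilate(m, 1), class = "trabsep_param_error")
  expect_error(mask_close(m, 2), class = "trabsep_param_error")
})
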