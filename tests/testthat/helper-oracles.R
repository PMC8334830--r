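# Independent brute-force oracles. These implement the normative per-voxel
# definitions directly (offset scans over the structuring element, list
# scans for flooding) and share no code path with the package's distance
# transform / C++ implementations.

# shift a logical array by an integer offset, vacated cells FALSE
o_shift <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]
    by <- d[ax]
    if (abs(by) >= n) return(out)
    src[[ax]] <- if (by >= 0) seq_len(n - by) else seq(1 - by, n)
    dst[[ax]] <- if (by >= 0) seq(1 + by, n) else seq_len(n + by)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

o_ball <- function(r) {
  s <- seq(-r, r)
  g <- as.matrix(expand.grid(s, s, s))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

oracle_dilate <- function(a, r) {
  off <- o_ball(r)
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(off))) out <- out | o_shift(a, off[i, ])
  out
}

oracle_erode <- function(a, r) {
  off <- o_ball(r)
  out <- array(TRUE, dim(a))
  for (i in seq_len(nrow(off))) out <- out & o_shift(a, off[i, ])
  out
}

oracle_open <- function(a, r) oracle_dilate(oracle_erode(a, r), r)

oracle_close <- function(a, r) {
  if (r == 0L) return(a)
  d <- dim(a)
  p <- array(FALSE, d + 2L * r)
  p[r + seq_len(d[1L]), r + seq_len(d[2L]), r + seq_len(d[3L])] <- a
  res <- oracle_erode(oracle_dilate(p, r), r)
  res[r + seq_len(d[1L]), r + seq_len(d[2L]), r + seq_len(d[3L]),
      drop = FALSE]
}

# Priority flood in plain R: pop the queued voxel with the smallest
# (priority, insertion sequence) key, label its unlabeled 6-neighbours in
# the fixed offset order (-z,+z,-y,+y,-x,+x), matching the documented
# tie-break.
oracle_flood <- function(prio, seeds) {
  dm <- dim(prio)
  lab <- seeds
  qp <- numeric(0); qs <- integer(0); qi <- integer(0)
  sq <- 0L
  for (i in which(as.vector(seeds) > 0L)) {
    sq <- sq + 1L
    qp <- c(qp, prio[i]); qs <- c(qs, sq); qi <- c(qi, i)
  }
  offs <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
                c(0L, 0L, -1L), c(0L, 0L, 1L))
  while (length(qi)) {
    k <- order(qp, qs)[1L]
    i <- qi[k]
    qp <- qp[-k]; qs <- qs[-k]; qi <- qi[-k]
    p <- arrayInd(i, dm)
    for (t in seq_len(6L)) {
      nb <- p + offs[t, , drop = FALSE]
      if (any(nb < 1L) || any(nb > dm)) next
      j <- nb[1L] + dm[1L] * (nb[2L] - 1L) + dm[1L] * dm[2L] * (nb[3L] - 1L)
      if (lab[j] == 0L) {
        lab[j] <- lab[i]
        sq <- sq + 1L
        qp <- c(qp, prio[j]); qs <- c(qs, sq); qi <- c(qi, j)
      }
    }
  }
  lab
}

# Multi-source BFS from seeds in array order, FIFO, same neighbour order.
oracle_bfs <- function(seeds) {
  dm <- dim(seeds)
  lab <- seeds
  queue <- which(as.vector(seeds) > 0L)
  offs <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
                c(0L, 0L, -1L), c(0L, 0L, 1L))
  head <- 1L
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    p <- arrayInd(i, dm)
    for (t in seq_len(6L)) {
      nb <- p + offs[t, , drop = FALSE]
      if (any(nb < 1L) || any(nb > dm)) next
      j <- nb[1L] + dm[1L] * (nb[2L] - 1L) + dm[1L] * dm[2L] * (nb[3L] - 1L)
      if (lab[j] == 0L) {
        lab[j] <- lab[i]
        queue <- c(queue, j)
      }
    }
  }
  lab
}

# Block-counting downsample oracle (triple loop over output blocks).
oracle_block_mean <- function(arr, f) {
  d <- dim(arr)
  nb <- ceiling(d / f)
  out <- array(0, nb)
  for (k in seq_len(nb[3L])) for (j in seq_len(nb[2L])) for (i in seq_len(nb[1L])) {
    zz <- ((i - 1L) * f + 1L):min(i * f, d[1L])
    yy <- ((j - 1L) * f + 1L):min(j * f, d[2L])
    xx <- ((k - 1L) * f + 1L):min(k * f, d[3L])
    out[i, j, k] <- mean(arr[zz, yy, xx])
  }
  out
}
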