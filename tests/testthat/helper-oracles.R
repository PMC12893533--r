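# Independent brute-force oracles. These deliberately share no code with
# the package internals: labeling by queue-based flood fill in plain R,
# ENN by all-pairs distances over every cell, metrics by direct formula
# evaluation, FAD by a per-pixel double loop, and the signed-rank p-value
# by enumeration of all 2^n sign assignments.

makeBinary <- function(m, cellSize = 30) {
  categoricalRaster(m, cellSize = cellSize, nodata = -9999L)
}

randomBinaryMatrix <- function(nr, nc, pForest = 0.5, pNodata = 0) {
  v <- sample(0:1, nr * nc, replace = TRUE, prob = c(1 - pForest, pForest))
  v <- as.integer(v)
  if (pNodata > 0)
    v[runif(nr * nc) < pNodata] <- NA_integer_
  matrix(v, nr, nc)
}

# queue-based 8-connected flood fill, row-major over transposed index
# order (same discovery convention as the package but independent code)
naiveLabel8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  isFg <- function(r, c) !is.na(m[r, c]) && m[r, c] == 1L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!isFg(r, c) || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1L] + dr; cc <- cur[2L] + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (isFg(rr, cc) && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# label-invariant partition comparison
samePartition <- function(l1, l2) {
  f1 <- l1[l1 > 0L]; f2 <- l2[l2 > 0L]
  if (!identical(which(l1 > 0L), which(l2 > 0L))) return(FALSE)
  key1 <- as.integer(factor(f1, levels = unique(f1)))
  key2 <- as.integer(factor(f2, levels = unique(f2)))
  identical(key1, key2)
}

# all-pairs cell-centre distances over every cell of every patch
naiveEnn <- function(lab, cellSize) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) < 2L) return(rep(NA_real_, length(ids)))
  cells <- lapply(ids, function(i) which(lab == i, arr.ind = TRUE))
  out <- numeric(length(ids))
  for (i in seq_along(ids)) {
    best <- Inf
    for (j in seq_along(ids)) {
      if (i == j) next
      a <- cells[[i]]; b <- cells[[j]]
      d2 <- outer(a[, 1L], b[, 1L], `-`)^2 + outer(a[, 2L], b[, 2L], `-`)^2
      best <- min(best, min(d2))
    }
    out[i] <- sqrt(best) * cellSize
  }
  out
}

# direct Table-style formula evaluation from a label matrix
naiveMetrics <- function(lab, cellSize, validCells) {
  A <- validCells * cellSize^2
  ids <- sort(unique(lab[lab > 0L]))
  a <- vapply(ids, function(i) sum(lab == i) * cellSize^2, 0)
  n <- length(ids)
  enn <- naiveEnn(lab, cellSize)
  list(
    pa_mn_ha = if (n) sum(a) / n / 1e4 else NA_real_,
    np = n,
    pd_per100ha = n / A * 1e4 * 100,
    lpi_pct = if (n) 100 * max(a) / A else 0,
    enn_mn_m = if (n >= 2L) mean(enn) else NA_real_,
    mesh_ha = sum(a^2) / A / 1e4
  )
}

# per-pixel double-loop FAD
naiveFad <- function(m, window) {
  r <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j]) || m[i, j] != 1L) next
    win <- m[max(1L, i - r):min(nr, i + r), max(1L, j - r):min(nc, j + r)]
    out[i, j] <- 100 * sum(win == 1L, na.rm = TRUE) / sum(!is.na(win))
  }
  out
}

# exact two-sided signed-rank p by enumeration of all 2^n sign vectors
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  wobs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  p <- if (wobs > mu) 2 * mean(w >= wobs) else 2 * mean(w <= wobs)
  min(1, p)
}
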