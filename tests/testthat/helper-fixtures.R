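# Shared fixture builders; everything is generated in code at test time.

disk_region <- function(nr, nc, cy, cx, r) {
  dy <- matrix(seq_len(nr) - cy, nr, nc)
  dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  (dy^2 + dx^2) <= r^2
}

region_dice2 <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# noiseless default-geometry phantom, shared across tests (generation ~1 s)
clean_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_head_phantom(phantom_spec(noise_sd = 0,
                                                   bias_amplitude = 0))
    cache
  }
})

# brute-force directed Hausdorff over boundary cells (the oracle)
hd_oracle <- function(m, n, spacing = NULL) {
  d <- dim(m)
  sp <- if (is.null(spacing)) rep(1, length(d)) else spacing
  is_boundary <- function(x) {
    idx <- which(x, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (i in seq_len(nrow(idx))) {
      p <- idx[i, ]
      for (ax in seq_along(d)) {
        for (s in c(-1L, 1L)) {
          q <- p; q[ax] <- q[ax] + s
          if (q[ax] < 1 || q[ax] > d[ax] ||
              !x[matrix(q, 1)]) { keep[i] <- TRUE }
        }
      }
    }
    idx[keep, , drop = FALSE]
  }
  bm <- is_boundary(m); bn <- is_boundary(n)
  mx <- 0
  for (i in seq_len(nrow(bm))) {
    dd <- sqrt(colSums((t(bn) - bm[i, ])^2 * sp^2))
    mx <- max(mx, min(dd))
  }
  mx
}

random_mask3d <- function(dims, p = 0.6) {
  array(stats::runif(prod(dims)) > p, dims)
}

# discrete |grad phi|: steepest slope over the 8 neighbour directions (the
# axis-aligned central difference under-reads a signed distance field at
# raster kinks; the true SDF bound for this operator is [cos(pi/8), 1])
slope8 <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  get <- function(di, dj) {
    ri <- pmin(pmax((1:nr) + di, 1), nr)
    ci <- pmin(pmax((1:nc) + dj, 1), nc)
    phi[ri, ci]
  }
  best <- matrix(0, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    best <- pmax(best, abs(get(d[1], d[2]) - phi))
  for (d in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    best <- pmax(best, abs(get(d[1], d[2]) - phi) / sqrt(2))
  best
}
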