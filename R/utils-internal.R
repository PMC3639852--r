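# Internal numerical helpers: matrix shifts, separable box rank/mean filters
# with clipped windows, and an n-dimensional Euclidean distance transform.
# These back the ACN statistics and the Hausdorff metric.

# Shift a matrix by (di, dj); vacated cells take `fill`.
shift_mat <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- max(1, 1 - di):min(nr, nr - di)
  src_c <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(src_r) < 1L || length(src_c) < 1L || src_r[1] > src_r[length(src_r)]) return(out)
  out[src_r + di, src_c + dj] <- m[src_r, src_c]
  out
}

# Window offsets for a side-length n box "centered" on a pixel.  Even n is
# left-biased: rows [i - floor((n-1)/2), i + floor(n/2)], always n wide.
box_offsets <- function(n) {
  stopifnot(n >= 1)
  -((n - 1) %/% 2):(n %/% 2)
}

# Running max/min over an n x n box, windows clipped at the image border
# (statistics are computed over the window-image intersection only).
# Separable: row pass then column pass.
box_filter_rank <- function(m, n, op = c("max", "min")) {
  op <- match.arg(op)
  f <- if (op == "max") pmax else pmin
  pad <- if (op == "max") -Inf else Inf
  offs <- box_offsets(n)
  # window covers m[i + o] for o in offs; shift_mat(x, d)[i] = x[i - d]
  acc <- m
  for (o in offs) if (o != 0) acc <- f(acc, shift_mat(m, -o, 0, pad))
  out <- acc
  for (o in offs) if (o != 0) out <- f(out, shift_mat(acc, 0, -o, pad))
  out
}

box_max <- function(m, n) box_filter_rank(m, n, "max")
box_min <- function(m, n) box_filter_rank(m, n, "min")

# Exact clipped-window box mean via integral images.
box_mean <- function(m, n) {
  offs <- box_offsets(n)
  lo <- -offs[1]; hi <- offs[length(offs)]
  nr <- nrow(m); nc <- ncol(m)
  # integral image with a zero border row/col
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(1, seq_len(nr) - lo); r2 <- pmin(nr, seq_len(nr) + hi)
  c1 <- pmax(1, seq_len(nc) - lo); c2 <- pmin(nc, seq_len(nc) + hi)
  sums <- S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  sums / counts
}

# Shift an n-D logical/numeric array by one or more cells along one axis;
# vacated cells take `fill`.
axis_shift <- function(arr, ax, by, fill) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(ax, seq_len(nd)[-ax])
  v <- aperm(arr, perm)
  mdim <- dim(v)
  v <- matrix(v, nrow = d[ax])
  n <- d[ax]; o <- abs(by)
  out <- if (o >= n) matrix(fill, n, ncol(v))
         else if (by > 0) rbind(matrix(fill, o, ncol(v)), v[seq_len(n - o), , drop = FALSE])
         else rbind(v[-seq_len(o), , drop = FALSE], matrix(fill, o, ncol(v)))
  aperm(array(out, mdim), order(perm))
}

# Smallest k such that every TRUE cell of `query` lies within Chebyshev
# distance k of a TRUE cell of `target` (via iterated box dilation).
chebyshev_bound <- function(query, target) {
  cur <- target
  k <- 0L
  limit <- sum(dim(target))
  while (any(query & !cur)) {
    for (ax in seq_along(dim(cur)))
      cur <- cur | axis_shift(cur, ax, 1L, FALSE) | axis_shift(cur, ax, -1L, FALSE)
    k <- k + 1L
    if (k > limit)
      acnm_error("acnm_validation_error", "target mask is empty")
  }
  k
}

# Squared Euclidean distance (per-axis spacing aware) from every cell of an
# n-D array to the nearest TRUE cell.  Separable: axis-by-axis minimization
# of shifted candidates, exact because squared distance decomposes per axis.
# `max_dist` (same units as spacing) restricts the per-axis offset range;
# values are exact wherever the true distance is <= max_dist.
sq_edt <- function(mask, spacing = NULL, max_dist = NULL) {
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  nd <- length(d)
  if (is.null(spacing)) spacing <- rep(1, nd)
  stopifnot(length(spacing) == nd, all(spacing > 0))
  D2 <- array(ifelse(as.logical(mask), 0, Inf), dim = d)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    if (n == 1L) next
    perm <- c(ax, seq_len(nd)[-ax])
    v <- aperm(D2, perm)
    mdim <- dim(v)
    v <- matrix(v, nrow = n)
    best <- v
    sp2 <- spacing[ax]^2
    o_max <- n - 1L
    if (!is.null(max_dist))
      o_max <- min(o_max, as.integer(ceiling(max_dist / spacing[ax])))
    for (o in seq_len(o_max)) {
      cost <- (o^2) * sp2
      up <- rbind(v[-seq_len(o), , drop = FALSE],
                  matrix(Inf, o, ncol(v)))
      dn <- rbind(matrix(Inf, o, ncol(v)),
                  v[seq_len(n - o), , drop = FALSE])
      best <- pmin(best, up + cost, dn + cost)
    }
    D2 <- aperm(array(best, mdim), order(perm))
  }
  D2
}

# Face-adjacency boundary cells of a binary array (4-neighbour in 2D,
# 6-neighbour in 3D); cells outside the array count as background.
boundary_cells <- function(mask) {
  d <- dim(mask)
  mask <- array(as.logical(mask), dim = d)
  interior <- mask
  for (ax in seq_along(d)) {
    interior <- interior & axis_shift(mask, ax, 1L, FALSE) &
      axis_shift(mask, ax, -1L, FALSE)
  }
  array(mask & !interior, dim = d)
}

# Classed conditions used across modules.
acnm_error <- function(class, message, ...) {
  stop(structure(class = c(class, "acnm_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
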