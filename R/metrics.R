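#' Segmentation overlap and distance metrics
#'
#' The five evaluation measures for a predicted mask `m` against a ground
#' truth `n` (voxel-count arithmetic throughout): Dice `2|M&N|/(|M|+|N|)`,
#' Jaccard `|M&N|/|M|+|N|-|M&N|`, false positive rate `|M - M&N|/|N|`, false
#' negative rate `|N - N&M|/|N|` (both relative to the truth volume, so the
#' FP rate can exceed 1 under gross over-inclusion), and the directed
#' Hausdorff distance between boundary voxel sets.
#'
#' @param m,n binary arrays of equal shape ([acnm_mask] or plain arrays);
#'   `n` is the ground truth.
#' @return `dice`/`jaccard`/rates: numbers; see [hausdorff_directed] for the
#'   distance.
#' @name metrics
NULL

mask_data <- function(x) {
  if (inherits(x, "acnm_volume")) x$data else x
}

check_pair <- function(m, n, require_n = TRUE) {
  m <- mask_data(m); n <- mask_data(n)
  if (length(dim(m)) != length(dim(n)) || !all(dim(m) == dim(n)))
    acnm_error("acnm_validation_error", "mask shapes differ")
  dm <- dim(m)
  m <- array(as.logical(m), dm)
  n <- array(as.logical(n), dm)
  if (require_n && !any(n))
    acnm_error("acnm_undefined_metric", "ground-truth mask is empty")
  list(m = m, n = n)
}

#' @rdname metrics
#' @export
dice <- function(m, n) {
  p <- check_pair(m, n, require_n = FALSE)
  s <- sum(p$m) + sum(p$n)
  if (s == 0) acnm_error("acnm_undefined_metric", "both masks are empty")
  2 * sum(p$m & p$n) / s
}

#' @rdname metrics
#' @export
jaccard <- function(m, n) {
  p <- check_pair(m, n, require_n = FALSE)
  u <- sum(p$m | p$n)
  if (u == 0) acnm_error("acnm_undefined_metric", "both masks are empty")
  sum(p$m & p$n) / u
}

#' @rdname metrics
#' @export
fp_fn_rates <- function(m, n) {
  p <- check_pair(m, n)
  inter <- sum(p$m & p$n)
  nn <- sum(p$n)
  c(fp_rate = (sum(p$m) - inter) / nn,
    fn_rate = (nn - inter) / nn)
}

#' Directed Hausdorff distance between mask boundaries
#'
#' `HD(M, N) = max over a in boundary(M) of min over b in boundary(N) of
#' d(a, b)`, Euclidean, computed over face-adjacency boundary voxels.
#' Asymmetric by definition; `symmetric = TRUE` returns
#' `max(HD(M,N), HD(N,M))`.  Distances are in voxel units unless `spacing`
#' supplies per-axis sizes in mm.
#'
#' @param m,n binary arrays or [acnm_mask]s, both non-empty.
#' @param spacing `NULL` for voxel units, or per-axis voxel size.
#' @param symmetric return the symmetric (max of both directions) distance.
#' @return A nonnegative number.
#' @export
hausdorff_directed <- function(m, n, spacing = NULL, symmetric = FALSE) {
  p <- check_pair(m, n)
  if (!any(p$m)) acnm_error("acnm_undefined_metric", "predicted mask is empty")
  bm <- boundary_cells(p$m)
  bn <- boundary_cells(p$n)
  sp <- if (is.null(spacing)) rep(1, length(dim(bm))) else as.numeric(spacing)
  directed <- function(from, to) {
    # Chebyshev bound caps the offset range of the exact transform
    k <- chebyshev_bound(from, to)
    if (k == 0L) return(0)
    r <- k * sqrt(sum(sp^2))
    sqrt(max(sq_edt(to, spacing, max_dist = r)[from]))
  }
  d_mn <- directed(bm, bn)
  if (!symmetric) return(d_mn)
  max(d_mn, directed(bn, bm))
}

#' Full evaluation report
#'
#' @param m predicted mask; `n` ground truth; `spacing` optional mm voxel
#'   sizes for the mm-valued Hausdorff entries.
#' @param symmetric_hd also report the symmetric Hausdorff distance.
#' @return list of class `acnm_eval`: `ds`, `js`, `fp_rate`, `fn_rate`
#'   (fractions), `fp_rate_pct`, `fn_rate_pct`, `hd_vox`, and `hd_mm` when
#'   spacing is known.
#' @export
eval_report <- function(m, n, spacing = NULL, symmetric_hd = FALSE) {
  if (is.null(spacing) && inherits(m, "acnm_volume")) spacing <- m$spacing
  rates <- fp_fn_rates(m, n)
  out <- list(ds = dice(m, n), js = jaccard(m, n),
              fp_rate = unname(rates["fp_rate"]),
              fn_rate = unname(rates["fn_rate"]),
              fp_rate_pct = 100 * unname(rates["fp_rate"]),
              fn_rate_pct = 100 * unname(rates["fn_rate"]),
              hd_vox = hausdorff_directed(m, n, symmetric = symmetric_hd))
  if (!is.null(spacing))
    out$hd_mm <- hausdorff_directed(m, n, spacing = spacing,
                                    symmetric = symmetric_hd)
  structure(out, class = "acnm_eval")
}

#' @export
print.acnm_eval <- function(x, ...) {
  cat(sprintf("DS %.4f  JS %.4f  FP %.2f%%  FN %.2f%%  HD %.2f vox%s\n",
              x$ds, x$js, x$fp_rate_pct, x$fn_rate_pct, x$hd_vox,
              if (!is.null(x$hd_mm)) sprintf(" (%.2f mm)", x$hd_mm) else ""))
  invisible(x)
}
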