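#' Planar contour: a filled region and its border
#'
#' A contour couples a filled 2D binary region with the ordered closed pixel
#' chains of its border (one chain per connected component) and the index of
#' the slice it lives on.  The border is the region's 8-connected inner
#' boundary: region pixels with at least one background pixel among their 8
#' neighbours.
#'
#' @param region 2D binary matrix (logical or 0/1), non-empty.
#' @param slice_index position along the slice axis (1-based), or `NA`.
#' @return An object of class `acnm_contour` with elements `region`
#'   (logical matrix), `boundary_mask` (logical matrix), `chains` (list of
#'   n x 2 matrices of 1-based (row, col) coordinates), `slice_index`,
#'   `area` (pixel count).
#' @export
contour_from_region <- function(region, slice_index = NA_integer_) {
  region <- matrix(as.logical(region), nrow(region), ncol(region))
  if (!any(region))
    acnm_error("acnm_empty_contour", "region is empty")
  bmask <- region & !(as.matrix(EBImage::erode(region * 1,
                                               EBImage::makeBrush(3, "box"))) > 0)
  lab <- EBImage::bwlabel(region * 1)
  ch <- EBImage::ocontour(lab)
  chains <- lapply(ch, function(m) m + 1L)  # 0-based (row, col) -> 1-based
  structure(list(region = region, boundary_mask = bmask, chains = chains,
                 slice_index = as.integer(slice_index), area = sum(region)),
            class = "acnm_contour")
}

#' @export
print.acnm_contour <- function(x, ...) {
  cat(sprintf("acnm contour: slice %s, area %d px, %d chain(s)\n",
              ifelse(is.na(x$slice_index), "?", x$slice_index),
              x$area, length(x$chains)))
  invisible(x)
}

contour_centroid <- function(contour) {
  idx <- which(contour$region, arr.ind = TRUE)
  colMeans(idx)
}

region_dice <- function(a, b) {
  ia <- sum(a & b)
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * ia / s
}
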