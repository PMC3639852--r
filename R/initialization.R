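#' Initial contour on the middle slice
#'
#' Surrogate for a deformable-surface initializer: threshold the normalized
#' slice at the Otsu level (floored at 0.2), keep the largest connected
#' component, fill holes, morphologically close, then contract by a safety
#' margin so the starting contour sits near or inside the brain.  The level
#' set only needs a closed contour in the neighbourhood of the brain
#' boundary; the downstream evolution tolerates a crude start (a plain
#' circle initializer is also provided, see [circle_initial_contour]).
#'
#' @param slice 2D intensity matrix on \[0, 1\] containing a foreground object.
#' @param min_component_area smallest admissible component, pixels.
#' @param safety_margin erosion radius applied to the component, pixels.
#' @return An [acnm_contour].
#' @export
initial_contour_middle_slice <- function(slice, min_component_area = 50,
                                         safety_margin = 1) {
  stopifnot(is.matrix(slice))
  thr <- max(EBImage::otsu(EBImage::Image(slice), range = c(0, 1)), 0.2)
  bw <- slice > thr
  lab <- EBImage::bwlabel(bw * 1)
  if (max(lab) < 1)
    acnm_error("acnm_init_error", "no foreground component above threshold")
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_component_area)
    acnm_error("acnm_init_error",
               sprintf("largest component (%d px) below minimum area %d",
                       max(sizes), min_component_area))
  comp <- lab == which.max(sizes)
  # a head is surrounded by background; a component reaching the image
  # border is thresholded air/noise or a gradient artefact, not a brain
  if (any(comp[1, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1]) || any(comp[, ncol(comp)]))
    acnm_error("acnm_init_error", "foreground component touches the image border")
  comp <- as.matrix(EBImage::fillHull(comp * 1)) > 0
  comp <- EBImage::closing(comp * 1, disc_brush(2)) > 0
  shrunk <- EBImage::erode(comp * 1, disc_brush(safety_margin)) > 0
  if (!any(shrunk)) shrunk <- comp
  # erosion can split the component; keep the largest piece
  lab2 <- EBImage::bwlabel(shrunk * 1)
  sizes2 <- tabulate(lab2[lab2 > 0])
  shrunk <- lab2 == which.max(sizes2)
  contour_from_region(shrunk)
}

#' Circle initializer at 0.83 x the reference area
#'
#' Builds a filled circle with the same centroid as the reference contour
#' and 0.83 times its area (rasterized), the alternative initialization used
#' to show that the evolution tolerates a coarse start.
#'
#' @param ref an [acnm_contour].
#' @param area_ratio circle area as a fraction of `ref`'s area.
#' @param min_area smallest admissible reference area, pixels.
#' @return An [acnm_contour] on the same grid.
#' @export
circle_initial_contour <- function(ref, area_ratio = 0.83, min_area = 10) {
  stopifnot(inherits(ref, "acnm_contour"))
  if (ref$area < min_area)
    acnm_error("acnm_init_error",
               sprintf("reference area %d below minimum %d", ref$area, min_area))
  cen <- contour_centroid(ref)
  r <- sqrt(area_ratio * ref$area / pi)
  nr <- nrow(ref$region); nc <- ncol(ref$region)
  dy <- matrix(seq_len(nr) - cen[1], nr, nc)
  dx <- matrix(seq_len(nc) - cen[2], nr, nc, byrow = TRUE)
  disk <- (dy^2 + dx^2) <= r^2
  contour_from_region(disk, ref$slice_index)
}

#' Contract-or-expand discriminant between adjacent slices
#'
#' Partitions the image into R1 (pixels where the current slice is brighter
#' than the next) and R2 (the rest), counts how much of the current slice's
#' resultant mask falls in each, and decides: if the mask covers R1 at least
#' as much as R2 the brain is receding, so the next slice's initial contour
#' should be a contracted copy; otherwise an expanded one.  Ties (including
#' an empty mask) fall to `contract`, the safer error: the level set can
#' re-expand inside its neighbourhood, while outward leakage is the failure
#' mode the model exists to prevent.  The decision depends only on the sign
#' of `current - next`, so it is invariant to adding a constant to both.
#'
#' @param current_slice,next_slice 2D intensity matrices of equal shape.
#' @param resultant_mask 2D binary matrix, the current slice's segmentation.
#' @return list of class `acnm_propagation_decision`: `direction`
#'   (`"contract"` or `"expand"`), `r1_cover`, `r2_cover`.
#' @export
propagation_decision <- function(current_slice, next_slice, resultant_mask) {
  if (!all(dim(current_slice) == dim(next_slice)) ||
      !all(dim(current_slice) == dim(resultant_mask)))
    acnm_error("acnm_validation_error", "slices and mask must share shape")
  r1 <- current_slice > next_slice
  m <- as.logical(resultant_mask)
  r1_cover <- sum(m & r1)
  r2_cover <- sum(m & !r1)
  structure(list(direction = if (r1_cover >= r2_cover) "contract" else "expand",
                 r1_cover = r1_cover, r2_cover = r2_cover),
            class = "acnm_propagation_decision")
}

#' Propagate a resultant contour to the adjacent slice
#'
#' Erodes (contract) or dilates (expand) the filled region with a Euclidean
#' disc of radius `r_prop` and re-extracts the border, producing the initial
#' contour for the next slice.
#'
#' @param resultant an [acnm_contour].
#' @param decision an `acnm_propagation_decision` (or its `direction` string).
#' @param r_prop disc radius in pixels, >= 1 (default 1: a deeper contraction
#'   biases the next slice's first belt toward the brain interior, where the
#'   belt mean can land above the gray-matter intensity and strand the
#'   contour at the WM/GM interface).
#' @return An [acnm_contour]; signals `acnm_empty_contour` if erosion empties
#'   the region (the caller stops propagating in that direction).
#' @export
propagate_initial_contour <- function(resultant, decision, r_prop = 1) {
  stopifnot(inherits(resultant, "acnm_contour"), r_prop >= 1)
  dir <- if (is.character(decision)) decision else decision$direction
  dir <- match.arg(dir, c("contract", "expand"))
  op <- if (dir == "contract") EBImage::erode else EBImage::dilate
  out <- op(resultant$region * 1, disc_brush(r_prop)) > 0
  if (!any(out))
    acnm_error("acnm_empty_contour", "contraction emptied the region")
  contour_from_region(out, resultant$slice_index)
}
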