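#' Build the belt-shaped active contour neighbourhood (ACN)
#'
#' The ACN is obtained by dilating the contour's border pixel chain (not the
#' filled region) with a Euclidean disc of radius `r_acn`, yielding a belt
#' that straddles the contour.  Its two global statistics drive the
#' nonlinear speed function: `mu`, the mean intensity over the whole belt
#' (dragged down by the dark tissue outside the brain boundary), is the
#' lower bound of the gray levels treated as brain; `i_m`, the maximum over
#' the brain side of the belt (belt intersected with the contour's filled
#' region), is the upper bound.  Values beyond `i_m` — e.g. an eyeball the
#' belt reaches across a weak boundary — are excluded by contraction.
#' Taking `i_m` from the brain side only keeps the exclusion stable: bright
#' non-brain tissue entering the belt must not raise the very bound meant
#' to shut it out.
#'
#' @param contour an [acnm_contour].
#' @param slice 2D intensity matrix underlying the contour.
#' @param r_acn dilation radius in pixels, >= 1.
#' @return list of class `acnm_belt`: `belt` (logical matrix), `mu`, `i_m`,
#'   `r_acn`.
#' @export
build_acn <- function(contour, slice, r_acn = 5) {
  if (!inherits(contour, "acnm_contour") || !any(contour$region))
    acnm_error("acnm_validation_error", "valid non-empty contour required")
  stopifnot(is.matrix(slice), all(dim(slice) == dim(contour$region)), r_acn >= 1)
  belt <- as.matrix(EBImage::dilate(contour$boundary_mask * 1,
                                    disc_brush(r_acn))) > 0
  inner <- belt & contour$region
  if (!any(inner)) inner <- belt
  # 99.5th percentile rather than the strict maximum: a handful of bright
  # outlier pixels straying into the brain side of the belt (noise, or the
  # first rim pixels of a structure being excluded) must not ratchet the
  # upper intensity bound upward and disable the very exclusion mechanism
  i_m <- unname(stats::quantile(slice[inner], 0.995))
  structure(list(belt = belt, mu = mean(slice[belt]), i_m = i_m,
                 r_acn = as.integer(r_acn)),
            class = "acnm_belt")
}

#' Windowed local statistics feeding the regional value
#'
#' For each pixel: the maximum over the `n1 x n1` window centred there, and
#' the minimum and mean over the `n2 x n2` window.  Windows are clipped at
#' the image border (statistics over the window-image intersection).  The
#' window "size" is the square side length; even sizes are left-biased by
#' half a pixel.  Maps are computed over the full slice so that pixels in
#' the evaluation domain see tissue context beyond it.
#'
#' @param slice 2D intensity matrix.
#' @param domain 2D binary matrix, the pixels the statistics are meant for
#'   (validated non-empty; maps are returned for the full slice).
#' @param n1,n2 window side lengths, `n1 >= n2 >= 1`.
#' @return list of class `acnm_local_stats`: `i_max`, `i_min`, `i_mu`
#'   (matrices), `n1`, `n2`.
#' @export
local_stats <- function(slice, domain = NULL, n1 = 40, n2 = 20) {
  stopifnot(is.matrix(slice))
  if (!(n1 >= n2 && n2 >= 1))
    acnm_error("acnm_validation_error", "need n1 >= n2 >= 1")
  if (!is.null(domain) && !any(domain))
    acnm_error("acnm_validation_error", "domain is empty")
  structure(list(i_max = box_max(slice, n1),
                 i_min = box_min(slice, n2),
                 i_mu = box_mean(slice, n2),
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "acnm_local_stats")
}

#' Regional value: a boundary indicator from local intensity statistics
#'
#' `i_r = ((i_max - i_min) + |i_mu - i|) / 2`: half the sum of the local
#' intensity range and the pixel's deviation from its local mean.  It is
#' zero in homogeneous regions and large near tissue boundaries — including
#' weak boundaries with no usable gradient — which is why the smoothing term
#' is driven by it rather than by the image gradient.
#'
#' @param i_max,i_min,i_mu per-pixel statistics (scalars or matrices).
#' @param i pixel intensity (same shape).
#' @return `i_r`, nonnegative, same shape as the inputs.
#' @export
regional_value <- function(i_max, i_min, i_mu, i) {
  ((i_max - i_min) + abs(i_mu - i)) / 2
}

#' Edge-stopping function of the regional value
#'
#' `g = 1 / (1 + (i_r / sigma_g)^2)`: the classical inverse-quadratic
#' edge-stopping profile, applied to the regional value instead of the
#' gradient magnitude.  `g = 1` in homogeneous regions (full smoothing
#' speed) and decays toward 0 as `i_r` grows, slowing the contour at
#' boundaries.
#'
#' @param i_r regional value(s), >= 0.
#' @param sigma_g scale at which `g` drops to 1/2, > 0.
#' @return `g` in (0, 1], same shape as `i_r`.
#' @export
edge_stop <- function(i_r, sigma_g = 0.1) {
  stopifnot(sigma_g > 0)
  1 / (1 + (i_r / sigma_g)^2)
}
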