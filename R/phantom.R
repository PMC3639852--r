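#' Synthetic T1-like head phantom specification
#'
#' Describes the geometry, tissue palette, artefact levels and RNG seed of a
#' synthetic head phantom.  The phantom emulates the features a T1-weighted
#' head scan presents to a brain extractor: bright white matter, mid gray
#' matter, dark CSF and background, a scalp ring separated from the brain by
#' a dark gap, an optional bright eyeball connected to the brain through a
#' low-contrast ("weak boundary") corridor, additive Gaussian noise and a
#' smooth multiplicative bias field.  Ground truth is the brain proper:
#' white matter, gray matter and interior (ventricular) CSF; scalp, skull
#' gap, eye and background are excluded.
#'
#' @param shape integer length-3: slices, rows, cols (each >= 32).
#' @param intensities named list on \[0,1\]: `background`, `csf`, `gm`, `wm`,
#'   `scalp`, `eye`, `gap` (the weak-boundary corridor).  The eye must be
#'   brighter than white matter and CSF darker than gray matter.
#' @param gyri_amp sinusoidal perturbation of the brain radius, as a
#'   fraction of the radius; `gyri_k` is its angular frequency.
#' @param eye logical: include the eyeball + weak-boundary corridor.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_amplitude amplitude of the multiplicative low-order cosine
#'   bias field (intensity scaled by `1 + bias`, `|bias| <= bias_amplitude`).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 128, 128),
                         intensities = list(background = 0.05, csf = 0.15,
                                            gm = 0.45, wm = 0.75, scalp = 0.55,
                                            eye = 0.95, gap = 0.40),
                         gyri_amp = 0.07, gyri_k = 9,
                         eye = TRUE,
                         noise_sd = 0.02, bias_amplitude = 0.1,
                         seed = 0L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    acnm_error("acnm_validation_error", "shape must be 3 dims, each >= 32")
  pal <- intensities
  need <- c("background", "csf", "gm", "wm", "scalp", "eye", "gap")
  if (!all(need %in% names(pal)))
    acnm_error("acnm_validation_error",
               paste("intensities must name:", paste(need, collapse = ", ")))
  v <- unlist(pal[need])
  if (any(v < 0 | v > 1))
    acnm_error("acnm_validation_error", "intensities must lie in [0,1]")
  if (pal$eye <= pal$wm)
    acnm_error("acnm_validation_error", "eye intensity must exceed white matter")
  if (pal$csf >= pal$gm)
    acnm_error("acnm_validation_error", "CSF intensity must be below gray matter")
  if (noise_sd < 0 || bias_amplitude < 0)
    acnm_error("acnm_validation_error", "noise_sd and bias_amplitude must be >= 0")
  structure(list(shape = shape, intensities = pal, gyri_amp = gyri_amp,
                 gyri_k = gyri_k, eye = isTRUE(eye), noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Geometry shared by the full generator and the slice fixtures.  Brain
# cross-sections are ellipses whose radius is modulated by a sinusoidal
# "gyri" perturbation r(theta) = r0 * (1 + a*sin(k*theta)) and scaled by an
# ellipsoidal slice profile so per-slice areas are unimodal along the axis.
phantom_geometry <- function(spec) {
  S <- spec$shape[1]; R <- spec$shape[2]; C <- spec$shape[3]
  mid <- (S + 1) / 2
  half_span <- 0.42 * S          # brain occupies the central ~84% of slices
  a_max <- 0.31 * R              # row semi-axis at the widest slice
  b_max <- 0.27 * C              # col semi-axis
  list(S = S, R = R, C = C, mid = mid, half_span = half_span,
       cy = (R + 1) / 2, cx = (C + 1) / 2,
       a_max = a_max, b_max = b_max,
       head_pad = 0.14 * min(R, C),   # CSF/skull gap + scalp ring width
       ring_px = max(3, round(0.03 * min(R, C))),
       eye_slice = round(mid - 0.22 * S),
       eye_r = max(4, round(0.035 * min(R, C))),
       eye_gap = 3)                   # weak-boundary corridor length, px
}

phantom_slice_profile <- function(geom, s) {
  u <- (s - geom$mid) / geom$half_span
  if (abs(u) >= 1) 0 else sqrt(1 - u^2)
}

# Paint one noiseless slice; returns list(img, truth, eye_mask).
phantom_paint_slice <- function(spec, geom, s) {
  pal <- spec$intensities
  R <- geom$R; C <- geom$C
  f <- phantom_slice_profile(geom, s)
  img <- matrix(pal$background, R, C)
  truth <- matrix(0, R, C)
  eye_mask <- matrix(0, R, C)
  if (f <= 0) return(list(img = img, truth = truth, eye_mask = eye_mask))
  a <- geom$a_max * f; b <- geom$b_max * f
  dy <- matrix(seq_len(R) - geom$cy, R, C)
  dx <- matrix(seq_len(C) - geom$cx, R, C, byrow = TRUE)
  # head: constant-width pad outside the brain ellipse
  ah <- a + geom$head_pad; bh <- b + geom$head_pad
  rho_h <- sqrt((dy / ah)^2 + (dx / bh)^2)
  head <- rho_h <= 1
  img[head] <- pal$csf
  ring <- head & (rho_h >= 1 - geom$ring_px / min(ah, bh))
  img[ring] <- pal$scalp
  # brain with gyri-modulated radius
  theta <- atan2(dy, dx)
  mod <- 1 + spec$gyri_amp * sin(spec$gyri_k * theta)
  rho_b <- sqrt((dy / a)^2 + (dx / b)^2) / mod
  brain <- rho_b <= 1
  img[brain & rho_b > 0.80] <- pal$gm
  img[brain & rho_b <= 0.80] <- pal$wm
  # ventricular CSF: small central ellipse, part of the ground truth
  rho_v <- sqrt((dy / (0.30 * a))^2 + (dx / (0.12 * b))^2)
  vent <- brain & rho_v <= 1
  img[vent] <- pal$csf
  truth[brain] <- 1
  # eyeball + weak-boundary corridor on designated slices
  if (spec$eye) {
    ds <- (s - geom$eye_slice) * 1.0
    if (abs(ds) < geom$eye_r) {
      re <- sqrt(geom$eye_r^2 - ds^2)
      f_e <- phantom_slice_profile(geom, geom$eye_slice)
      a_e <- geom$a_max * f_e
      # just below the brain edge (gyri crest), inside the CSF/skull gap
      ey <- geom$cy + a_e * (1 + spec$gyri_amp) + geom$eye_gap + geom$eye_r
      ex <- geom$cx
      rho_e <- sqrt((dy + geom$cy - ey)^2 + (dx + geom$cx - ex)^2)
      eye_px <- rho_e <= re
      # corridor from brain edge to eye: weak contrast against gray matter
      corridor <- !brain & !eye_px & head & !ring &
        abs(dx) <= max(2, 0.4 * re) &
        dy > 0 & (dy + geom$cy) < ey
      img[corridor] <- pal$gap
      img[eye_px] <- pal$eye
      eye_mask[eye_px] <- 1
      truth[eye_px] <- 0
    }
  }
  list(img = img, truth = truth, eye_mask = eye_mask)
}

#' Generate a synthetic head phantom with voxel-exact ground truth
#'
#' Deterministic given `spec$seed`.  Noise and bias are applied to the
#' noiseless tissue painting: `I = clip((I0 + noise) * (1 + bias), 0, 1)`
#' with `bias` a separable low-order cosine surface.
#'
#' @param spec a [phantom_spec].
#' @return A list of class `phantom_result`: `volume` ([acnm_volume]),
#'   `truth` ([acnm_mask]), `eye` ([acnm_mask] of the eyeball voxels), and
#'   `truth_areas` (per-slice truth voxel counts).
#' @export
generate_head_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    acnm_error("acnm_validation_error", "spec must be a phantom_spec")
  geom <- phantom_geometry(spec)
  S <- geom$S; R <- geom$R; C <- geom$C
  vol <- array(0, c(S, R, C)); truth <- array(0, c(S, R, C))
  eye <- array(0, c(S, R, C))
  for (s in seq_len(S)) {
    sl <- phantom_paint_slice(spec, geom, s)
    vol[s, , ] <- sl$img; truth[s, , ] <- sl$truth; eye[s, , ] <- sl$eye_mask
  }
  if (spec$noise_sd > 0 || spec$bias_amplitude > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    if (spec$bias_amplitude > 0) {
      bs <- cos(pi * (seq_len(S) - 1) / (S - 1))
      br <- cos(pi * (seq_len(R) - 1) / (R - 1))
      bc <- cos(pi * (seq_len(C) - 1) / (C - 1))
      bias <- spec$bias_amplitude * outer(outer(bs, br), bc)
      vol <- vol * (1 + bias)
    }
    if (spec$noise_sd > 0)
      vol <- vol + array(stats::rnorm(length(vol), sd = spec$noise_sd), dim(vol))
    vol[vol < 0] <- 0; vol[vol > 1] <- 1
  }
  structure(list(volume = acnm_volume(vol, meta = list(format = "phantom")),
                 truth = acnm_mask(truth),
                 eye = acnm_mask(eye),
                 truth_areas = apply(truth, 1, sum),
                 spec = spec),
            class = "phantom_result")
}

#' Adjacent-slice fixtures for the contract/expand discriminant
#'
#' Returns two adjacent phantom slices between which the brain
#' cross-section strictly shrinks (or grows), together with the current
#' slice's truth region standing in for a segmentation result.  The
#' spec's noise is applied (deterministically from its seed): the
#' discriminant partitions the image by the sign of `current - next`, and
#' on ideal noise-free tissue every unchanged pixel would fall on one side
#' of that partition; noise splits unchanged tissue evenly, as in a real
#' scan, leaving the systematic boundary-band difference to tip the count.
#'
#' @param kind `"shrinking"` or `"growing"`.
#' @param spec a [phantom_spec]; the bias field is ignored.
#' @return list: `current`, `nxt` (2D intensity matrices), `current_truth`,
#'   `next_truth` (binary matrices).
#' @export
slice_pair_fixture <- function(kind = c("shrinking", "growing"),
                               spec = phantom_spec(eye = FALSE)) {
  kind <- match.arg(kind)
  geom <- phantom_geometry(spec)
  # descending side of the slice profile: areas fall with slice index
  s0 <- round(geom$mid + 0.30 * geom$S)
  a <- phantom_paint_slice(spec, geom, s0)
  b <- phantom_paint_slice(spec, geom, s0 + 1)
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    noisy <- function(m) {
      m <- m + matrix(stats::rnorm(length(m), sd = spec$noise_sd),
                      nrow(m), ncol(m))
      m[m < 0] <- 0; m[m > 1] <- 1
      m
    }
    a$img <- noisy(a$img)
    b$img <- noisy(b$img)
  }
  if (kind == "shrinking")
    list(current = a$img, nxt = b$img,
         current_truth = a$truth, next_truth = b$truth)
  else
    list(current = b$img, nxt = a$img,
         current_truth = b$truth, next_truth = a$truth)
}

#' Weak-boundary (eye) slice fixture
#'
#' The phantom slice through the eyeball centre: a bright sphere
#' cross-section sits just outside the brain, joined to it by a
#' low-contrast corridor.  Returned with the slice truth, the eye pixels,
#' and an initial contour (the truth eroded by `init_margin`, emulating a
#' contour arriving from the neighbouring slice) — the standard scenario
#' for comparing speed laws on boundary leakage.
#'
#' @param spec a [phantom_spec] with `eye = TRUE`; `spec$noise_sd` is
#'   applied to the slice (deterministically from `spec$seed`).
#' @param init_margin erosion radius for the initial contour, pixels.
#' @return list: `slice` (matrix), `truth`, `eye` (binary matrices),
#'   `init` ([acnm_contour]), `slice_index`.
#' @export
eye_slice_fixture <- function(spec = phantom_spec(), init_margin = 2) {
  if (!spec$eye)
    acnm_error("acnm_validation_error", "fixture requires eye = TRUE")
  geom <- phantom_geometry(spec)
  s <- geom$eye_slice
  sl <- phantom_paint_slice(spec, geom, s)
  img <- sl$img
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                        nrow(img), ncol(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  init_region <- EBImage::erode(sl$truth, disc_brush(init_margin)) > 0
  list(slice = img, truth = sl$truth > 0, eye = sl$eye_mask > 0,
       init = contour_from_region(init_region, s), slice_index = s)
}

#' @export
print.phantom_result <- function(x, ...) {
  cat(sprintf("head phantom: %s voxels, truth fraction %.3f, seed %d\n",
              paste(dim(x$volume$data), collapse = " x "),
              mean(x$truth$data), x$spec$seed))
  invisible(x)
}
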