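#' Evolution parameters for the hybrid level set
#'
#' @param beta weight of the smoothing (edge-stopped curvature) term.
#' @param t speed parameter of the nonlinear data term: larger `t` speeds up
#'   contraction and slows expansion, taming leakage through weak
#'   boundaries.  The reference protocol fixes `beta = 1.2`, `t = 6`.
#' @param alpha weight applied to the linear-baseline data term; the
#'   baseline swaps only the data term, all smoothing machinery is shared.
#' @param T0,epsilon brightness centre and half-range of the linear baseline
#'   data term `D = epsilon - |I - T0|`; `NULL` derives them from the ACN
#'   statistics as `T0 = i_m` (the bright brain tissue the model targets)
#'   and `epsilon = i_m - mu` (reaching down to the dark brain bound), so
#'   the baseline expands over the same brain interval `[mu, i_m]` as the
#'   nonlinear law.  Being symmetric about its target, the linear profile
#'   then necessarily also expands on `(i_m, i_m + epsilon)` — it cannot
#'   include `[mu, i_m]` and exclude brighter tissue at the same time, which
#'   is the leakage defect the nonlinear law exists to remove.
#' @param dt explicit time step, or `NULL` for the per-step stability bound
#'   `0.45 / (max|D| + 4 * beta_eff * max g)`.
#' @param inner_max maximum PDE iterations per ACN.
#' @param inner_tol inner-loop stall threshold: mean zero-set movement per
#'   reinitialization window, as a fraction of the boundary length, below
#'   which the inner loop stops early.  Set to 0 to always run the full
#'   `inner_max` steps (a fixed iteration budget, as used when comparing
#'   speed laws).
#' @param outer_max maximum ACN replacements.
#' @param reinit_every iterations between signed-distance reinitializations.
#' @param converge_tol Dice between successive ACN contours at which the
#'   outer loop stops.
#' @param min_area components below this survive neither contour extraction
#'   nor the final mask, pixels.
#' @return list of class `speed_params`.
#' @export
speed_params <- function(beta = 1.2, t = 6, alpha = 1,
                         T0 = NULL, epsilon = NULL, dt = NULL,
                         inner_max = 120, inner_tol = 0.1, outer_max = 10,
                         reinit_every = 20, converge_tol = 0.995,
                         min_area = 30) {
  if (beta < 0 || t <= 0 || (!is.null(dt) && dt <= 0) ||
      converge_tol <= 0 || converge_tol > 1 || alpha < 0 || alpha > 1)
    acnm_error("acnm_validation_error", "invalid speed parameters")
  structure(list(beta = beta, t = t, alpha = alpha, T0 = T0, epsilon = epsilon,
                 dt = dt, inner_max = as.integer(inner_max),
                 inner_tol = inner_tol,
                 outer_max = as.integer(outer_max),
                 reinit_every = as.integer(reinit_every),
                 converge_tol = converge_tol, min_area = as.integer(min_area)),
            class = "speed_params")
}

#' Nonlinear piecewise data term
#'
#' The intensity-driven speed, parameterized by the ACN statistics `mu`
#' (belt mean) and `i_m` (belt maximum) and the speed parameter `t`.  With
#' `r = |i - mu| / ((i_m - mu) t)`:
#' \describe{
#'   \item{`i < mu`}{`D = -exp(-r)` — strong contraction over dark non-brain
#'     tissue.}
#'   \item{`i >= mu`}{`D = exp(-r) - exp(-(2 (i_m - mu) - |i - mu|) /
#'     ((i_m - mu) t))` — positive (expansion) on `(mu, i_m)`, zero exactly
#'     at `i = i_m`, negative beyond, so voxels brighter than the belt
#'     maximum (e.g. an eyeball across a weak boundary) are excluded by
#'     contraction.}
#' }
#' Increasing `t` strengthens contraction and weakens expansion.  `D` jumps
#' at `i = mu` (left limit -1, right limit `1 - exp(-2/t)`); the
#' discontinuity is part of the speed law.
#'
#' @param i intensity value(s) on \[0, 1\].
#' @param mu,i_m ACN belt mean and maximum, `0 <= mu < i_m`.
#' @param t speed parameter, > 0.
#' @return `D`, same shape as `i`.
#' @export
data_term_nonlinear <- function(i, mu, i_m, t = 6) {
  if (!(t > 0)) acnm_error("acnm_validation_error", "t must be > 0")
  if (!(i_m > mu + 1e-6))
    acnm_error("acnm_degenerate_acn",
               sprintf("degenerate ACN statistics: i_m (%.4g) <= mu (%.4g)", i_m, mu))
  s <- (i_m - mu) * t
  ad <- abs(i - mu)
  lower <- -exp(-ad / s)
  upper <- exp(-ad / s) - exp(-(2 * (i_m - mu) - ad) / s)
  ifelse(i < mu, lower, upper)
}

#' Linear baseline data term
#'
#' `D = epsilon - |i - T0|`: positive inside the brightness interval
#' `T0 +/- epsilon` (expansion), negative outside (contraction).  Kept as a
#' baseline: its unbounded-from-below linear tail contracts only weakly at
#' bright outliers, which is what lets a contour leak through a weak
#' boundary toward, e.g., an eyeball.
#'
#' @param i intensity value(s).
#' @param T0 target brightness.
#' @param epsilon half-range, > 0.
#' @return `D`, same shape as `i`.
#' @export
data_term_linear <- function(i, T0, epsilon) {
  if (!(epsilon > 0)) acnm_error("acnm_validation_error", "epsilon must be > 0")
  epsilon - abs(i - T0)
}

#' Signed distance field of a region
#'
#' `phi` is the Euclidean distance to the region boundary, positive inside
#' and negative outside (the zero level runs between the pixel grid), so
#' `|grad phi| ~ 1` — the premise under which the level-set speed law takes
#' its simple form.
#'
#' @param region 2D binary matrix, neither empty nor full-frame.
#' @return list of class `acnm_field`: `phi` (matrix).
#' @export
signed_distance <- function(region) {
  region <- matrix(as.logical(region), nrow(region), ncol(region))
  if (!any(region) || all(region))
    acnm_error("acnm_validation_error", "region must be neither empty nor full")
  inside <- EBImage::distmap(region * 1)
  outside <- EBImage::distmap((!region) * 1)
  phi <- as.matrix(inside) - as.matrix(outside)
  # shift by half a pixel so the zero crossing sits between grid points
  phi <- phi - 0.5 * sign(phi)
  structure(list(phi = phi), class = "acnm_field")
}

#' One belt-confined evolution step
#'
#' Explicit update `phi += dt * (D |grad phi|_upwind + beta * (g kappa
#' |grad phi| + grad g . grad phi))`, applied only on belt pixels; everything
#' off the belt is frozen.  The advection term uses the Godunov upwind
#' gradient; the edge-stopped curvature term uses central differences in the
#' expanded geodesic form `div(g grad phi / |grad phi|) |grad phi| =
#' g kappa |grad phi| + grad g . grad phi`.  The data term is multiplied by
#' `|grad phi|` (the signed-distance premise makes this the printed speed
#' law when `|grad phi| = 1`, and it is numerically robust otherwise).
#'
#' @param field an `acnm_field`.
#' @param d_map per-pixel data term `D` (matrix).
#' @param g_map per-pixel edge-stop `g` (matrix).
#' @param params a [speed_params]; `params$dt = NULL` uses the stability
#'   bound `0.45 / (max|D| + 4 beta max g)`.
#' @param belt logical matrix confining the update.
#' @return The updated `acnm_field`.
#' @export
evolve_step <- function(field, d_map, g_map, params, belt) {
  phi <- field$phi
  stopifnot(all(dim(phi) == dim(d_map)), all(dim(phi) == dim(g_map)),
            all(dim(phi) == dim(belt)))
  belt <- matrix(as.logical(belt), nrow(phi), ncol(phi))
  B <- make_band(belt)
  d0 <- d_map[B$idx]; g0 <- g_map[B$idx]
  dt <- params$dt
  if (is.null(dt)) {
    denom <- max(abs(d0), 0) + 4 * params$beta * max(g0, 0)
    dt <- if (denom > 0) 0.45 / denom else 0
  }
  phi_new <- evolve_band_step(phi, B, d0, g0,
                              (g_map[B$dn] - g_map[B$up]) / 2,
                              (g_map[B$rt] - g_map[B$lf]) / 2,
                              params$beta, dt)
  if (!all(is.finite(phi_new[B$idx])))
    acnm_error("acnm_numerical_error",
               sprintf("non-finite level set update (dt = %.4g)", dt))
  structure(list(phi = phi_new), class = "acnm_field")
}

#' Restore the signed-distance property
#'
#' Runs the reinitialization PDE `phi_tau = S(phi0) (1 - |grad phi|)` with a
#' smoothed sign `S = phi0 / sqrt(phi0^2 + 1)`, Godunov upwinding, and the
#' sub-cell interface fix: cells adjacent to the zero crossing relax toward
#' their distance interpolated from the incoming field, so the front —
#' including its sub-pixel position — stays in place while `|grad phi|` is
#' driven back to 1.  (Rebuilding the distance from the binarized region
#' instead would quantize slowly moving fronts to the pixel grid and stall
#' them.)
#'
#' @param field an `acnm_field` with finite `phi`.
#' @param iters pseudo-time iterations; the default corrects a band of
#'   roughly +/- 5 pixels around the zero set.
#' @param dtau pseudo-time step (< 0.5 for stability).
#' @return A reinitialized `acnm_field`.
#' @export
reinitialize <- function(field, iters = 12, dtau = 0.45) {
  phi <- field$phi
  if (!all(is.finite(phi)))
    acnm_error("acnm_numerical_error", "non-finite field in reinitialization")
  B <- make_band(matrix(TRUE, nrow(phi), ncol(phi)))
  structure(list(phi = reinit_band(phi, B, iters, dtau)), class = "acnm_field")
}

#' Extract the contour of a level-set field
#'
#' The region is `{phi >= 0}`; connected components smaller than `min_area`
#' are dropped, the survivors are hole-filled, and the union becomes the
#' contour region (multiple components are allowed — cerebrum and cerebellum
#' can be disjoint within a slice).
#'
#' @param field an `acnm_field`.
#' @param min_area smallest surviving component, pixels.
#' @return An [acnm_contour]; signals `acnm_empty_contour` if nothing
#'   survives.
#' @export
extract_contour <- function(field, min_area = 30) {
  region <- field$phi >= 0
  if (!any(region))
    acnm_error("acnm_empty_contour", "level set field is everywhere negative")
  lab <- EBImage::bwlabel(region * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L)
    acnm_error("acnm_empty_contour",
               sprintf("no component reaches min_area = %d", min_area))
  region <- matrix(lab %in% keep, nrow(region), ncol(region))
  region <- as.matrix(EBImage::fillHull(region * 1)) > 0
  contour_from_region(region)
}

# Precomputed gather indices for belt-confined updates: for each belt pixel,
# the linear indices of its 4- and diagonal neighbours with replicated
# borders.  Lets the inner loop work on length-|belt| vectors instead of
# full matrices; the update formulas are identical to evolve_step's.
make_band <- function(belt) {
  d <- dim(belt); nr <- d[1]; nc <- d[2]
  idx <- which(belt)
  ai <- arrayInd(idx, d); ri <- ai[, 1]; ci <- ai[, 2]
  at <- function(r, c) (pmin(pmax(c, 1L), nc) - 1L) * nr + pmin(pmax(r, 1L), nr)
  list(idx = idx,
       up = at(ri - 1L, ci), dn = at(ri + 1L, ci),
       lf = at(ri, ci - 1L), rt = at(ri, ci + 1L),
       ul = at(ri - 1L, ci - 1L), ur = at(ri - 1L, ci + 1L),
       dl = at(ri + 1L, ci - 1L), dr = at(ri + 1L, ci + 1L))
}

evolve_band_step <- function(phi, B, d0, g0, ggx, ggy, beta, dt) {
  p0 <- phi[B$idx]
  pu <- phi[B$up]; pd <- phi[B$dn]; pl <- phi[B$lf]; pr <- phi[B$rt]
  dxm <- p0 - pu; dxp <- pd - p0; dym <- p0 - pl; dyp <- pr - p0
  gp <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 + pmax(dym, 0)^2 + pmin(dyp, 0)^2)
  gm <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 + pmin(dym, 0)^2 + pmax(dyp, 0)^2)
  rhs <- pmax(d0, 0) * gp + pmin(d0, 0) * gm
  if (beta > 0) {
    gx <- (pd - pu) / 2; gy <- (pr - pl) / 2
    gxx <- pd - 2 * p0 + pu; gyy <- pr - 2 * p0 + pl
    pxy <- (phi[B$dr] - phi[B$dl] - phi[B$ur] + phi[B$ul]) / 4
    kap <- (gxx * gy^2 - 2 * gx * gy * pxy + gyy * gx^2) / (gx^2 + gy^2 + 1e-10)
    rhs <- rhs + beta * (g0 * kap + ggx * gx + ggy * gy)
  }
  phi[B$idx] <- p0 + dt * rhs
  phi
}

# Band-restricted reinitialization: same PDE + sub-cell fix as
# reinitialize(), updating belt pixels only (the zero set lives there).
reinit_band <- function(phi, B, iters = 12, dtau = 0.45) {
  p0 <- phi[B$idx]
  pu0 <- phi[B$up]; pd0 <- phi[B$dn]; pl0 <- phi[B$lf]; pr0 <- phi[B$rt]
  s0 <- sign(p0)
  interface <- (s0 * sign(pu0) < 0) | (s0 * sign(pd0) < 0) |
               (s0 * sign(pl0) < 0) | (s0 * sign(pr0) < 0)
  g0 <- pmax(sqrt(((pd0 - pu0) / 2)^2 + ((pr0 - pl0) / 2)^2),
             abs(pd0 - p0), abs(p0 - pu0), abs(pr0 - p0), abs(p0 - pl0), 1e-6)
  dist0 <- p0 / g0
  S <- p0 / sqrt(p0^2 + 1)
  for (k in seq_len(iters)) {
    pc <- phi[B$idx]
    pu <- phi[B$up]; pd <- phi[B$dn]; pl <- phi[B$lf]; pr <- phi[B$rt]
    dxm <- pc - pu; dxp <- pd - pc; dym <- pc - pl; dyp <- pr - pc
    gp <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 + pmax(dym, 0)^2 + pmin(dyp, 0)^2)
    gm <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 + pmin(dym, 0)^2 + pmax(dyp, 0)^2)
    upd <- S * (1 - ifelse(S > 0, gp, gm))
    upd[interface] <- (dist0 - pc)[interface]
    phi[B$idx] <- pc + dtau * upd
  }
  if (!all(is.finite(phi[B$idx])))
    acnm_error("acnm_numerical_error", "non-finite field in reinitialization")
  phi
}

#' Segment one slice by iterated ACN replacement
#'
#' The per-slice core: build the belt around the current contour, take its
#' statistics, evaluate the data term and the regional-value edge stop on
#' the belt, evolve the signed distance field of the current region inside
#' the belt until the zero set stalls, extract the new contour, and repeat
#' with the new contour's belt until two successive contours agree (Dice >=
#' `converge_tol`) or `outer_max` is reached.
#'
#' @param slice 2D intensity matrix, normalized to \[0, 1\].
#' @param init an [acnm_contour] to start from.
#' @param params a [speed_params].
#' @param r_acn belt dilation radius, pixels.
#' @param n1,n2 local-statistics window sizes.
#' @param sigma_g edge-stop scale.
#' @param speed `"nonlinear"` (the model) or `"linear"` (the baseline law).
#' @return An [acnm_contour] with attribute `iterations` (total PDE steps)
#'   and `outer` (ACN replacements used).
#' @export
run_acnm_slice <- function(slice, init, params = speed_params(), r_acn = 5,
                           n1 = 40, n2 = 20, sigma_g = 0.1,
                           speed = c("nonlinear", "linear")) {
  speed <- match.arg(speed)
  stopifnot(inherits(init, "acnm_contour"))
  contour <- init
  total_steps <- 0L
  outer_used <- 0L
  for (outer in seq_len(params$outer_max)) {
    outer_used <- outer
    acn <- build_acn(contour, slice, r_acn)
    st <- local_stats(slice, acn$belt, n1, n2)
    i_r <- regional_value(st$i_max, st$i_min, st$i_mu, slice)
    g_map <- edge_stop(i_r, sigma_g)
    if (speed == "nonlinear") {
      d_map <- data_term_nonlinear(slice, acn$mu, acn$i_m, params$t)
    } else {
      # baseline: swap only the data term, keep the smoothing machinery
      T0 <- if (is.null(params$T0)) acn$i_m else params$T0
      eps <- if (is.null(params$epsilon)) acn$i_m - acn$mu else params$epsilon
      d_map <- params$alpha * data_term_linear(slice, T0, eps)
    }
    B <- make_band(acn$belt)
    d0 <- d_map[B$idx]; g0 <- g_map[B$idx]
    ggx <- (g_map[B$dn] - g_map[B$up]) / 2
    ggy <- (g_map[B$rt] - g_map[B$lf]) / 2
    dt <- params$dt
    if (is.null(dt)) {
      denom <- max(abs(d0), 0) + 4 * params$beta * max(g0, 0)
      dt <- if (denom > 0) 0.45 / denom else 0
    }
    phi <- signed_distance(contour$region)$phi
    sign_prev <- phi[B$idx] >= 0
    blen <- max(1L, sum(contour$boundary_mask))
    for (it in seq_len(params$inner_max)) {
      phi <- evolve_band_step(phi, B, d0, g0, ggx, ggy, params$beta, dt)
      total_steps <- total_steps + 1L
      # zero-set movement is assessed per reinitialization window: CFL
      # speeds are O(0.01) px/step, so creeping fronts flip pixels in rare
      # synchronized bursts and a per-step test would stop them spuriously
      if (it %% params$reinit_every == 0L) {
        phi <- reinit_band(phi, B)
        sign_now <- phi[B$idx] >= 0
        moved <- sum(xor(sign_now, sign_prev))
        sign_prev <- sign_now
        if (params$inner_tol > 0 && moved / blen < params$inner_tol) break
      }
    }
    if (!all(is.finite(phi)))
      acnm_error("acnm_numerical_error", "non-finite level set field")
    new_contour <- extract_contour(structure(list(phi = phi),
                                             class = "acnm_field"),
                                   params$min_area)
    new_contour$slice_index <- contour$slice_index
    d <- region_dice(new_contour$region, contour$region)
    contour <- new_contour
    if (!is.na(d) && d >= params$converge_tol) break
  }
  attr(contour, "iterations") <- total_steps
  attr(contour, "outer") <- outer_used
  contour
}
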