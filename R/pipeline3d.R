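#' Whole-volume brain extraction
#'
#' Orchestrates slice-by-slice extraction: normalize the volume, segment the
#' middle slice from a fresh initial contour (threshold surrogate, or the
#' circle variant), then sweep ascending and descending slice indices, each
#' slice's initial contour obtained by contracting or expanding the previous
#' slice's result according to the brightness-change discriminant.  A
#' direction stops when the contour empties or its area falls below
#' `min_brain_area`; remaining slices in that direction stay empty.  Slices
#' are evolved independently after initialization — no 3D regularization is
#' applied.
#'
#' @param vol an [acnm_volume]; normalized internally unless `normalize =
#'   FALSE`.
#' @param params a [speed_params].
#' @param r_acn belt radius, pixels.
#' @param r_prop contraction/expansion radius for slice-to-slice contour
#'   propagation, pixels.
#' @param initializer `"surrogate"` (robust threshold) or `"circle"` (a
#'   circle of 0.83 x the surrogate's area at its centroid).
#' @param n1,n2,sigma_g see [run_acnm_slice].
#' @param min_brain_area slice area (pixels) below which a propagation
#'   direction terminates.
#' @param normalize apply [normalize_intensity] with `p_low`/`p_high`.
#' @param p_low,p_high normalization percentiles.
#' @param speed `"nonlinear"` or `"linear"` slice speed law.
#' @return An object of class `acnm_run`: `mask` ([acnm_mask]), `log`
#'   (per-slice data frame: slice, decision, outer iterations, PDE steps,
#'   area), `params`, and the effective configuration `config`.
#' @export
run_acnm_volume <- function(vol, params = speed_params(), r_acn = 5, r_prop = 1,
                            initializer = c("surrogate", "circle"),
                            n1 = 40, n2 = 20, sigma_g = 0.1,
                            min_brain_area = 50,
                            normalize = TRUE, p_low = 2, p_high = 100,
                            speed = c("nonlinear", "linear")) {
  stopifnot(inherits(vol, "acnm_volume"))
  initializer <- match.arg(initializer)
  speed <- match.arg(speed)
  nvol <- if (normalize) normalize_intensity(vol, p_low, p_high) else vol
  dims <- dim(nvol$data)
  n_slices <- dims[1]
  mid <- n_slices %/% 2L
  if (mid < 1L) mid <- 1L

  mask <- array(0, dims)
  log_rows <- vector("list", n_slices)
  note <- function(slice, decision, contour) {
    log_rows[[slice]] <<- data.frame(
      slice = slice, decision = decision,
      outer = if (is.null(contour)) 0L else attr(contour, "outer") %||% 0L,
      steps = if (is.null(contour)) 0L else attr(contour, "iterations") %||% 0L,
      area = if (is.null(contour)) 0L else contour$area)
  }

  mid_slice <- nvol$data[mid, , ]
  init <- tryCatch(initial_contour_middle_slice(mid_slice),
                   acnm_error = function(e)
                     acnm_error("acnm_extraction_error",
                                paste("middle-slice initialization failed:",
                                      conditionMessage(e))))
  if (initializer == "circle") init <- circle_initial_contour(init)
  init$slice_index <- mid
  mid_contour <- tryCatch(
    run_acnm_slice(mid_slice, init, params, r_acn, n1, n2, sigma_g, speed),
    acnm_error = function(e)
      acnm_error("acnm_extraction_error",
                 paste("middle-slice segmentation failed:",
                       conditionMessage(e))))
  mid_contour$slice_index <- mid
  mask[mid, , ] <- mid_contour$region * 1
  note(mid, "middle", mid_contour)

  sweep <- function(indices) {
    prev <- mid_contour
    prev_slice <- mid_slice
    for (s in indices) {
      cur_slice <- nvol$data[s, , ]
      res <- tryCatch({
        dec <- propagation_decision(prev_slice, cur_slice, prev$region)
        ini <- propagate_initial_contour(prev, dec, r_prop)
        ini$slice_index <- s
        ctr <- run_acnm_slice(cur_slice, ini, params, r_acn, n1, n2,
                              sigma_g, speed)
        ctr$slice_index <- s
        list(dec = dec$direction, ctr = ctr)
      }, acnm_empty_contour = function(e) NULL,
         acnm_degenerate_acn = function(e) NULL,
         acnm_init_error = function(e) NULL)
      if (is.null(res) || res$ctr$area < min_brain_area) {
        if (!is.null(res)) note(s, res$dec, NULL)
        break
      }
      mask[s, , ] <<- res$ctr$region * 1
      note(s, res$dec, res$ctr)
      prev <- res$ctr
      prev_slice <- cur_slice
    }
  }
  if (mid < n_slices) sweep((mid + 1L):n_slices)
  if (mid > 1L) sweep((mid - 1L):1L)

  empty <- vapply(seq_len(n_slices), function(s) is.null(log_rows[[s]]), logical(1))
  for (s in which(empty))
    log_rows[[s]] <- data.frame(slice = s, decision = "skipped",
                                outer = 0L, steps = 0L, area = 0L)
  log_df <- do.call(rbind, log_rows)
  log_df <- log_df[order(log_df$slice), ]
  rownames(log_df) <- NULL

  structure(list(
    mask = acnm_mask(mask, nvol$spacing),
    log = log_df,
    params = params,
    config = list(beta = params$beta, t = params$t, r_acn = r_acn,
                  r_prop = r_prop, n1 = n1, n2 = n2, sigma_g = sigma_g,
                  initializer = initializer, speed = speed,
                  min_brain_area = min_brain_area,
                  normalize = normalize, p_low = p_low, p_high = p_high,
                  inner_max = params$inner_max, outer_max = params$outer_max,
                  reinit_every = params$reinit_every,
                  converge_tol = params$converge_tol,
                  min_area = params$min_area,
                  middle_slice = mid)),
    class = "acnm_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Machine-readable run summary
#'
#' @param run an `acnm_run`.
#' @return list: `config` (complete effective configuration), `slices`
#'   (per-slice decision/iterations/area), `total_steps`, `mask_voxels`.
#'   Serializes cleanly to JSON/YAML and back.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "acnm_run"))
  list(config = run$config,
       slices = run$log,
       total_steps = sum(run$log$steps),
       mask_voxels = sum(run$mask$data))
}

#' @export
print.acnm_run <- function(x, ...) {
  seg <- sum(x$log$area > 0)
  cat(sprintf("acnm run: %d/%d slices segmented, %d mask voxels, beta=%.3g t=%.3g\n",
              seg, nrow(x$log), sum(x$mask$data), x$config$beta, x$config$t))
  invisible(x)
}

#' @export
summary.acnm_run <- function(object, ...) {
  s <- summarize_run(object)
  cat("acnm extraction run\n")
  cat("  configuration:", jsonlite::toJSON(s$config, auto_unbox = TRUE), "\n")
  cat(sprintf("  segmented slices: %d of %d\n", sum(s$slices$area > 0),
              nrow(s$slices)))
  cat(sprintf("  total PDE steps: %d; mask voxels: %d\n",
              s$total_steps, as.integer(s$mask_voxels)))
  invisible(s)
}
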