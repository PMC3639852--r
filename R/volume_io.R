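#' Volume and mask containers
#'
#' An `acnm_volume` wraps a 3D intensity array together with its voxel
#' spacing (mm) and source-format metadata; it is the unit of I/O for the
#' whole package.  The first array axis is the slice axis: slice-by-slice
#' processing operates in the plane of `data[i, , ]`.  An `acnm_mask` is a
#' volume whose values are restricted to {0, 1}.
#'
#' @param data 3D numeric array (slices x rows x cols), all values finite.
#' @param spacing numeric length-3, per-axis voxel size in mm, all > 0.
#' @param meta list of format metadata (at least `format`).
#' @return An object of class `acnm_volume` (and `acnm_mask` for masks).
#' @export
acnm_volume <- function(data, spacing = c(1, 1, 1), meta = list(format = "memory")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    acnm_error("acnm_dim_error", "volume data must be a 3D array")
  if (any(dim(data) < 1L))
    acnm_error("acnm_validation_error", "all dimensions must be >= 1")
  if (!all(is.finite(data)))
    acnm_error("acnm_validation_error", "intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    acnm_error("acnm_validation_error", "spacing must be three positive numbers")
  structure(list(data = data, spacing = spacing, meta = meta),
            class = "acnm_volume")
}

#' @rdname acnm_volume
#' @export
acnm_mask <- function(data, spacing = c(1, 1, 1), meta = list(format = "memory")) {
  storage.mode(data) <- "double"
  if (!all(data %in% c(0, 1)))
    acnm_error("acnm_validation_error", "mask values must be 0 or 1")
  v <- acnm_volume(data, spacing, meta)
  class(v) <- c("acnm_mask", class(v))
  v
}

#' @export
print.acnm_volume <- function(x, ...) {
  kind <- if (inherits(x, "acnm_mask")) "mask" else "volume"
  cat(sprintf("acnm %s: %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              kind, paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(hdr|img)(\\.gz)?$", lp)) return("analyze")
  acnm_error("acnm_format_error", sprintf("unsupported volume format: %s", path))
}

#' Read an MRI volume or mask
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) via RNifti and Analyze 7.5
#' (`.hdr`/`.img`, optionally gzipped) via oro.nifti.  Intensities are left
#' on their native scale; only 3D images are accepted.
#'
#' @param path path to the image file (for Analyze, either half of the pair).
#' @param mask logical; if `TRUE` the result is validated and returned as an
#'   `acnm_mask` (values coerced by `!= 0`).
#' @return An [acnm_volume] (or [acnm_mask]).
#' @export
read_volume <- function(path, mask = FALSE) {
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    if (!file.exists(path))
      acnm_error("acnm_io_error", sprintf("file not found: %s", path))
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    sp <- RNifti::pixdim(img)
    meta <- list(format = "nifti", path = path)
  } else {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    if (!any(file.exists(paste0(stem, c(".hdr", ".hdr.gz")))))
      acnm_error("acnm_io_error", sprintf("Analyze header not found for: %s", path))
    img <- oro.nifti::readANALYZE(stem)
    arr <- img@.Data
    # drop trailing singleton 4th dimension routinely present in Analyze
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- array(arr, dim(arr)[1:3])
    sp <- img@pixdim[2:4]
    meta <- list(format = "analyze", path = path)
  }
  if (length(dim(arr)) != 3L)
    acnm_error("acnm_dim_error",
               sprintf("expected a 3D image, got %d dimensions", length(dim(arr))))
  sp <- as.numeric(sp)[seq_len(3)]
  sp[!is.finite(sp) | sp <= 0] <- 1
  arr <- array(as.numeric(arr), dim(arr))
  if (mask) acnm_mask(array(as.numeric(arr != 0), dim(arr)), sp, meta)
  else acnm_volume(arr, sp, meta)
}

#' Write an MRI volume or mask
#'
#' Writes NIfTI-1 or Analyze 7.5 according to the file extension.  Plain
#' volumes are stored as float64 (bit-exact round trip); masks as unsigned
#' 8-bit integers.
#'
#' @param vol an [acnm_volume] or [acnm_mask].
#' @param path output path: `.nii`, `.nii.gz`, or `.hdr`/`.img` (the pair is
#'   written from the common stem; add `.gz` to gzip).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "acnm_volume"))
  fmt <- volume_format(path)
  if (!dir.exists(dirname(path)))
    acnm_error("acnm_io_error", sprintf("parent directory does not exist: %s", dirname(path)))
  is_mask <- inherits(vol, "acnm_mask")
  if (fmt == "nifti") {
    arr <- vol$data
    attr(arr, "pixdim") <- vol$spacing
    img <- RNifti::asNifti(arr, datatype = if (is_mask) "uint8" else "double")
    ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                   error = function(e) FALSE)
    if (!ok || !file.exists(path))
      acnm_error("acnm_io_error", sprintf("could not write: %s", path))
  } else {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    gz <- grepl("\\.gz$", path)
    img <- oro.nifti::anlz(if (is_mask) array(as.integer(vol$data), dim(vol$data))
                           else vol$data,
                           datatype = if (is_mask) 2L else 64L)
    img@pixdim[2:4] <- vol$spacing
    ok <- tryCatch({ oro.nifti::writeANALYZE(img, stem, gzipped = gz); TRUE },
                   error = function(e) FALSE)
    if (!ok) acnm_error("acnm_io_error", sprintf("could not write: %s", path))
  }
  invisible(path)
}

#' Robust intensity normalization to [0, 1]
#'
#' Linearly rescales intensities so that the `p_low` and `p_high` percentiles
#' map to 0 and 1, then clips to \[0, 1\].  All model statistics assume this
#' working scale (the speed function excludes the interval from the belt
#' maximum up to 1).  Rank order is preserved among non-clipped voxels, and
#' the operation is idempotent up to clipping.
#'
#' @param vol an [acnm_volume].
#' @param p_low,p_high percentiles, `0 <= p_low < p_high <= 100`.
#' @return A normalized [acnm_volume].
#' @export
normalize_intensity <- function(vol, p_low = 2, p_high = 98) {
  stopifnot(inherits(vol, "acnm_volume"))
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    acnm_error("acnm_validation_error", "need 0 <= p_low < p_high <= 100")
  # order-statistic quantiles (type 1): renormalizing an already clipped
  # volume then reproduces it exactly (idempotence up to clipping)
  q <- stats::quantile(vol$data, probs = c(p_low, p_high) / 100, names = FALSE,
                       type = 1)
  if (q[2] - q[1] <= .Machine$double.eps * max(abs(q), 1))
    acnm_error("acnm_degenerate_input", "constant-intensity volume cannot be normalized")
  out <- (vol$data - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  acnm_volume(out, vol$spacing, c(vol$meta, list(normalized = c(p_low, p_high))))
}
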