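#' Pressure image and video containers
#'
#' A `pressure_video` is a 2D+time grid of plantar pressure samples as
#' recorded by a pressure-sensing plate; a `pressure_image` is a single 2D
#' scalar field on the same kind of grid (e.g. a mean or peak pressure
#' image); a `silhouette_mask` is the binary footprint where pressure
#' exceeds a threshold.
#'
#' Grid conventions used throughout the package: matrix rows run along the
#' anterior-posterior axis (toes at high row index), columns along the
#' medial-lateral axis. The physical position of pixel `(i, j)` (1-based) is
#' `origin + (c(i, j) - 1) * spacing`, with spacing in millimetres.
#'
#' @param data numeric matrix (image) or 3D array (video, time on axis 3);
#'   pressures in kPa unless `normalized`
#' @param spacing physical pixel size in mm, length 1 (isotropic) or 2
#' @param frequency temporal sampling rate in Hz
#' @param side `"left"`, `"right"`, or `NA`
#' @param subject_id,foot_id opaque identifiers
#' @param normalized logical; `TRUE` after division by the total mean
#'   pressure (values are then dimensionless)
#' @param origin physical coordinate (mm) of pixel (1, 1)
#' @return an object of class `pressure_video` or `pressure_image`
#' @examples
#' img <- pressure_image(matrix(c(0, 10, 20, 0), 2, 2), spacing = 3)
#' range(img$data)
#' @export
pressure_image <- function(data, spacing = 3, side = NA_character_,
                           normalized = FALSE, origin = c(0, 0)) {
  data <- strip_attrs(as.matrix(data))
  stopifnot(is.numeric(data), all(is.finite(data)))
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         side = side, normalized = isTRUE(normalized)),
    class = "pressure_image"
  )
}

#' @rdname pressure_image
#' @export
pressure_video <- function(data, spacing, frequency, side = NA_character_,
                           subject_id = NA_character_, foot_id = NA_character_,
                           normalized = FALSE) {
  data <- strip_attrs(as.array(data))
  if (length(dim(data)) != 3)
    stop("not a pressure video: expected two spatial axes and one temporal axis")
  if (any(data < 0)) stop("pressure values must be >= 0")
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  if (!is.numeric(frequency) || frequency <= 0) stop("frequency must be > 0")
  structure(
    list(data = data, spacing = spacing, frequency = as.numeric(frequency),
         side = side, subject_id = subject_id, foot_id = foot_id,
         normalized = isTRUE(normalized)),
    class = "pressure_video"
  )
}

#' @rdname pressure_image
#' @param threshold pressure cutoff (kPa) that defined the mask
#' @export
silhouette_mask <- function(data, spacing = 3, threshold = 5) {
  data <- strip_attrs(as.matrix(data)) > 0
  structure(
    list(data = data, spacing = rep(as.numeric(spacing), length.out = 2),
         threshold = threshold),
    class = "silhouette_mask"
  )
}

#' @export
print.pressure_image <- function(x, ...) {
  cat(sprintf("<pressure_image> %d x %d px, %.3g x %.3g mm/px, side=%s%s\n",
              nrow(x$data), ncol(x$data), x$spacing[1], x$spacing[2],
              ifelse(is.na(x$side), "?", x$side),
              if (x$normalized) ", normalized" else " [kPa]"))
  invisible(x)
}

#' @export
print.pressure_video <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pressure_video> %d x %d px x %d frames, %.3g x %.3g mm/px, %g Hz, side=%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$frequency,
              ifelse(is.na(x$side), "?", x$side)))
  invisible(x)
}

#' @export
print.silhouette_mask <- function(x, ...) {
  cat(sprintf("<silhouette_mask> %d x %d px, %d on (threshold %g kPa)\n",
              nrow(x$data), ncol(x$data), sum(x$data), x$threshold))
  invisible(x)
}

is_isotropic <- function(x) isTRUE(all.equal(x$spacing[1], x$spacing[2]))

# Drop NIfTI pointer/header attributes picked up from RNifti arrays.
strip_attrs <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Pad or crop an image onto a reference grid
#'
#' Zero-pads (or crops) `image` at the high-index side so that it has the
#' same matrix dimensions as `reference`. Both must share the same pixel
#' spacing; this is grid conforming, not resampling.
#'
#' @param image,reference `pressure_image` objects (or `reference` a
#'   2-vector of target dimensions)
#' @return a `pressure_image` on the reference grid
#' @export
conform_grid <- function(image, reference) {
  dims <- if (is.numeric(reference)) as.integer(reference) else dim(reference$data)
  if (!is.numeric(reference) &&
      !isTRUE(all.equal(image$spacing, reference$spacing)))
    stop("grid mismatch: images have different pixel spacing")
  out <- matrix(0, dims[1], dims[2])
  nr <- min(dims[1], nrow(image$data))
  nc <- min(dims[2], ncol(image$data))
  out[seq_len(nr), seq_len(nc)] <- image$data[seq_len(nr), seq_len(nc)]
  img <- image
  img$data <- out
  img
}

#' Read and write pressure images as NIfTI
#'
#' Images are stored as 2D NIfTI volumes with pixel dimensions in mm.
#'
#' @param image a `pressure_image`
#' @param path file path (`.nii` or `.nii.gz`)
#' @return `write_pressure_image` returns `path` invisibly;
#'   `read_pressure_image` returns a `pressure_image`.
#' @export
write_pressure_image <- function(image, path) {
  RNifti::writeNifti(nifti_with_pixdim(image$data, image$spacing), path)
  invisible(path)
}

nifti_with_pixdim <- function(arr, pd) {
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- rep(pd, length.out = length(dim(arr)))
  nii
}

#' @rdname write_pressure_image
#' @param spacing optional override (mm) when the header pixdim is unreliable
#' @param side foot side recorded on the image
#' @export
read_pressure_image <- function(path, spacing = NULL, side = NA_character_) {
  nii <- RNifti::readNifti(path)
  arr <- drop(as.array(nii))
  if (length(dim(arr)) != 2) stop("not a 2D pressure image: ", path)
  if (is.null(spacing)) {
    spacing <- RNifti::pixdim(nii)[1:2]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("missing spacing metadata in NIfTI header and no override given (field: pixdim)")
  }
  pressure_image(arr, spacing = spacing, side = side)
}
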