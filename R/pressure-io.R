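#' Read a dynamic plantar pressure measurement from NIfTI
#'
#' Pressure-plate exports are stored as 3D NIfTI volumes with two spatial
#' axes (anterior-posterior, medial-lateral) and time on the third axis.
#' Header `pixdim` entries are often unreliable in plate exports, so spacing
#' and sampling frequency can be overridden from a sidecar configuration.
#'
#' @param path path to a 3D NIfTI volume (values in kPa)
#' @param spacing physical pixel size, length 2; if `NULL`, taken from the
#'   NIfTI header
#' @param spacing_units `"mm"` or `"cm"`; units of `spacing` (or of the
#'   header pixdim when no override is given). Stored spacing is always mm.
#' @param frequency sampling rate in Hz; if `NULL`, derived from the header
#'   time step when positive
#' @param side,subject_id,foot_id metadata carried on the returned object
#' @return a [pressure_video()]
#' @export
read_pressure_video <- function(path, spacing = NULL, spacing_units = c("mm", "cm"),
                                frequency = NULL, side = NA_character_,
                                subject_id = NA_character_, foot_id = NA_character_) {
  spacing_units <- match.arg(spacing_units)
  nii <- RNifti::readNifti(path)
  arr <- drop(as.array(nii))
  if (length(dim(arr)) != 3)
    stop("not a pressure video: expected two spatial axes and one temporal axis, got ",
         length(dim(arr)), " axes in ", path)
  pd <- RNifti::pixdim(nii)
  if (is.null(spacing)) {
    spacing <- pd[1:2]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("missing spacing metadata: header pixdim unusable and no override given ",
           "(field: spacing)")
  }
  if (spacing_units == "cm") spacing <- spacing * 10
  if (is.null(frequency)) {
    dt <- if (length(pd) >= 3) pd[3] else NA_real_
    if (is.finite(dt) && dt > 0) frequency <- 1 / dt
    else stop("missing frequency metadata: header time step unusable and no ",
              "override given (field: frequency)")
  }
  pressure_video(arr, spacing = spacing, frequency = frequency, side = side,
                 subject_id = subject_id, foot_id = foot_id)
}

#' @rdname read_pressure_video
#' @param video a [pressure_video()]
#' @export
write_pressure_video <- function(video, path) {
  nii <- nifti_with_pixdim(video$data, c(video$spacing, 1 / video$frequency))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Resample onto an isotropic square grid
#'
#' Plate sensors are rectangular (e.g. 7.62 x 5.08 mm), which distorts the
#' foot geometry; resampling by cubic interpolation onto an isotropic grid
#' (default 3 mm) restores it. Negative interpolation overshoot is clamped
#' to zero since pressures are non-negative.
#'
#' @param x a [pressure_video()] or [pressure_image()]
#' @param target_mm target isotropic pixel size in mm (default 3)
#' @return object of the same class on the square grid
#' @export
resample_square <- function(x, target_mm = 3) {
  stopifnot(is.numeric(target_mm), target_mm > 0)
  UseMethod("resample_square")
}

#' @export
resample_square.pressure_image <- function(x, target_mm = 3) {
  x$data <- cpp_resample(x$data, x$spacing[1], x$spacing[2], target_mm,
                         3L, TRUE)
  x$spacing <- c(target_mm, target_mm)
  x
}

#' @export
resample_square.pressure_video <- function(x, target_mm = 3) {
  frames <- lapply(seq_len(dim(x$data)[3]), function(t)
    cpp_resample(x$data[, , t], x$spacing[1], x$spacing[2], target_mm, 3L, TRUE))
  x$data <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  x$spacing <- c(target_mm, target_mm)
  x
}

#' Mean pressure image
#'
#' At each pixel, the mean of the pressure samples over the frames in which
#' that pixel is loaded (pressure strictly above `tau_kpa`); pixels never
#' loaded get zero. The spatial sum of this image is the total mean pressure
#' used for normalization.
#'
#' @param video a [pressure_video()]
#' @param tau_kpa loading threshold in kPa (default 5)
#' @return a [pressure_image()]
#' @export
mean_pressure_image <- function(video, tau_kpa = 5) {
  d <- video$data
  # thresholds are stated on the raw kPa scale; for an already-normalized
  # video the cutoff is carried through the stored divisor
  if (isTRUE(video$normalized) && !is.null(video$norm_divisor))
    tau_kpa <- tau_kpa / video$norm_divisor
  above <- d > tau_kpa
  cnt <- rowSums(above, dims = 2)
  s <- rowSums(d * above, dims = 2)
  m <- ifelse(cnt > 0, s / pmax(cnt, 1), 0)
  pressure_image(m, spacing = video$spacing, side = video$side,
                 normalized = video$normalized)
}

#' Normalize a pressure video by its total mean pressure
#'
#' Divides every sample by the spatial sum of the thresholded mean pressure
#' image, removing walking-speed effects on pressure magnitude while leaving
#' the spatial distribution intact. Output values are dimensionless.
#'
#' @inheritParams mean_pressure_image
#' @return a normalized [pressure_video()]
#' @export
normalize_video <- function(video, tau_kpa = 5) {
  m <- mean_pressure_image(video, tau_kpa)
  divisor <- sum(m$data)
  if (divisor <= 0) stop("empty measurement: no pixel exceeds the ", tau_kpa,
                         " kPa threshold")
  video$data <- video$data / divisor
  video$norm_divisor <- divisor * (if (is.null(video$norm_divisor)) 1
                                   else video$norm_divisor)
  video$normalized <- TRUE
  video
}

#' Peak pressure image
#'
#' Per-pixel maximum pressure over the stance phase.
#'
#' @param video a [pressure_video()]
#' @return a [pressure_image()]
#' @export
peak_pressure_image <- function(video) {
  p <- apply(video$data, c(1, 2), max)
  pressure_image(p, spacing = video$spacing, side = video$side,
                 normalized = video$normalized)
}

#' Mirror right-foot images into the left-foot frame
#'
#' A single left-foot model is built under the assumption that left and
#' right pressures are independent samples of the same anatomy, so right
#' feet are mirrored across the anterior-posterior axis and relabelled.
#'
#' @param image a [pressure_image()] with known `side`
#' @return a left-oriented [pressure_image()]
#' @export
flip_to_left <- function(image) {
  if (is.na(image$side) || !image$side %in% c("left", "right"))
    stop("cannot flip: image side is unknown")
  if (image$side == "right") {
    image$data <- image$data[, rev(seq_len(ncol(image$data))), drop = FALSE]
    image$side <- "left"
  }
  image
}

#' Footprint silhouette of a pressure image
#'
#' Binary mask of the pixels whose pressure strictly exceeds the threshold
#' (default 5 kPa on the raw scale). Thresholds are defined in kPa, so for
#' normalized images pass a threshold on the normalized scale or compute the
#' silhouette before normalization.
#'
#' @param image a [pressure_image()]
#' @param threshold_kpa cutoff (default 5)
#' @return a [silhouette_mask()]
#' @export
compute_silhouette <- function(image, threshold_kpa = 5) {
  silhouette_mask(image$data > threshold_kpa, spacing = image$spacing,
                  threshold = threshold_kpa)
}
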