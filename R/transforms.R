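#' Rigid 2D transforms
#'
#' A rigid transform maps physical points on the fixed (target) grid to
#' points in the moving image: `T(p) = R(angle) (p - center) + center +
#' translation`, all in mm. Warping an image by `T` samples the image at
#' `T(p)` for every fixed-grid point `p` (so the notation "image composed
#' with T" is literally `image(T(p))`).
#'
#' @param angle rotation in radians (counter-clockwise in the row/column
#'   plane)
#' @param translation length-2 numeric, mm
#' @param center rotation center, mm (defaults to the grid origin)
#' @return a `rigid_transform2d`
#' @examples
#' t1 <- rigid_transform2d(pi / 18, c(6, -9))
#' compose_rigid(t1, invert_rigid(t1))  # ~ identity
#' @export
rigid_transform2d <- function(angle = 0, translation = c(0, 0), center = c(0, 0)) {
  stopifnot(is.finite(angle), length(translation) == 2, length(center) == 2)
  structure(list(angle = as.numeric(angle),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> angle %.3f deg, translation (%.2f, %.2f) mm, center (%.1f, %.1f)\n",
              x$angle * 180 / pi, x$translation[1], x$translation[2],
              x$center[1], x$center[2]))
  invisible(x)
}

rot_mat <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}

# Affine offset d such that T(p) = R p + d
rigid_offset <- function(t) {
  as.numeric(t$center - rot_mat(t$angle) %*% t$center + t$translation)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' @rdname rigid_transform2d
#' @param t,t1,t2 `rigid_transform2d` objects
#' @export
invert_rigid <- function(t) {
  Rinv <- rot_mat(-t$angle)
  rigid_transform2d(-t$angle, as.numeric(-Rinv %*% t$translation), t$center)
}

#' @rdname rigid_transform2d
#' @export
compose_rigid <- function(t1, t2) {
  R1 <- rot_mat(t1$angle)
  d <- as.numeric(R1 %*% rigid_offset(t2) + rigid_offset(t1))
  rigid_transform2d(wrap_angle(t1$angle + t2$angle), d, c(0, 0))
}

#' @rdname rigid_transform2d
#' @param p 2-column matrix (or length-2 vector) of physical points, mm
#' @export
apply_rigid_points <- function(t, p) {
  p <- matrix(as.numeric(p), ncol = 2)
  sweep(p, 2, t$center) %*% t(rot_mat(t$angle)) +
    rep(1, nrow(p)) %o% (t$center + t$translation)
}

#' Dense deformation field
#'
#' Per-pixel displacement vectors (mm) on the fixed-image grid; warping an
#' image by the field samples it at `p + u(p)`. The minimum Jacobian
#' determinant of the map `p + u(p)` is cached as a diffeomorphism
#' diagnostic (positive everywhere for invertible fields).
#'
#' @param ux,uy displacement components (mm), matrices on the fixed grid
#' @param spacing pixel size in mm (isotropic)
#' @return a `deformation_field`
#' @export
deformation_field <- function(ux, uy, spacing = 3) {
  stopifnot(all(dim(ux) == dim(uy)))
  spacing <- as.numeric(spacing)[1]
  structure(list(ux = ux, uy = uy, spacing = spacing,
                 jacobian_min = min(cpp_jacobian(ux, uy, spacing))),
            class = "deformation_field")
}

#' @rdname deformation_field
#' @param dim grid dimensions
#' @export
identity_field <- function(dim, spacing = 3) {
  z <- matrix(0, dim[1], dim[2])
  deformation_field(z, z, spacing)
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %d x %d px, max |u| %.2f mm, min Jacobian %.3f\n",
              nrow(x$ux), ncol(x$ux), max(sqrt(x$ux^2 + x$uy^2)), x$jacobian_min))
  invisible(x)
}

#' Warp an image through a rigid transform and/or deformation field
#'
#' Resamples `image` onto the fixed grid through the composed map
#' `p -> T(p + u(p))`, i.e. the deformation applies on the fixed grid and
#' the rigid transform then maps into the moving image. Cubic interpolation
#' (with non-negativity clamping) is the default for pressures; use nearest
#' for masks.
#'
#' @param image a [pressure_image()] (isotropic spacing)
#' @param rigid a [rigid_transform2d()] or `NULL`
#' @param field a [deformation_field()] on the target grid, or `NULL`
#' @param interpolation `"cubic"`, `"linear"` or `"nearest"`
#' @param out_dim output grid dimensions (defaults to the field's grid, else
#'   the image's)
#' @return a [pressure_image()] on the fixed grid
#' @export
apply_transform <- function(image, rigid = NULL, field = NULL,
                            interpolation = c("cubic", "linear", "nearest"),
                            out_dim = NULL) {
  interpolation <- match.arg(interpolation)
  if (!is_isotropic(image)) stop("apply_transform requires an isotropic grid")
  sp <- image$spacing[1]
  if (is.null(rigid)) rigid <- rigid_transform2d()
  if (is.null(out_dim))
    out_dim <- if (!is.null(field)) dim(field$ux) else dim(image$data)
  interp <- c(cubic = 3L, linear = 1L, nearest = 0L)[[interpolation]]
  ux <- if (!is.null(field)) field$ux else NULL
  uy <- if (!is.null(field)) field$uy else NULL
  out <- cpp_warp(image$data, out_dim[1], out_dim[2],
                  rigid$angle, rigid$translation[1], rigid$translation[2],
                  rigid$center[1], rigid$center[2], ux, uy, sp, interp,
                  interpolation == "cubic")
  img <- image
  img$data <- out
  img
}

#' Average rigid transforms and deformation fields
#'
#' The rigid average takes the circular mean of the rotation angles and the
#' arithmetic mean of the affine offsets (returned with center at the
#' origin); the field average is the per-pixel arithmetic mean of the
#' displacement vectors. Used by groupwise template construction.
#'
#' @param rigids list of [rigid_transform2d()]
#' @param fields list of [deformation_field()] on a common grid, or `NULL`
#' @return list with elements `rigid` and `field` (`NULL` if no fields given)
#' @export
average_transforms <- function(rigids, fields = NULL) {
  if (length(rigids) == 0) stop("cannot average an empty list of transforms")
  ang <- atan2(mean(sin(vapply(rigids, `[[`, 0, "angle"))),
               mean(cos(vapply(rigids, `[[`, 0, "angle"))))
  offs <- vapply(rigids, rigid_offset, numeric(2))
  d <- rowMeans(offs)
  # recover translation for the center-0 parameterization: d = t when c = 0
  rigid <- rigid_transform2d(ang, d, c(0, 0))
  field <- NULL
  if (!is.null(fields) && length(fields) > 0) {
    ux <- Reduce(`+`, lapply(fields, `[[`, "ux")) / length(fields)
    uy <- Reduce(`+`, lapply(fields, `[[`, "uy")) / length(fields)
    field <- deformation_field(ux, uy, fields[[1]]$spacing)
  }
  list(rigid = rigid, field = field)
}

#' Serialize transforms
#'
#' Rigid transforms are written as JSON (angle, translation, center);
#' deformation fields as 2-component NIfTI vector images.
#'
#' @param t a [rigid_transform2d()]
#' @param path output path
#' @export
write_rigid_transform <- function(t, path) {
  jsonlite::write_json(list(angle = t$angle, translation = t$translation,
                            center = t$center),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid_transform
#' @export
read_rigid_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform2d(x$angle, x$translation, x$center)
}

#' @rdname write_rigid_transform
#' @param field a [deformation_field()]
#' @export
write_deformation_field <- function(field, path) {
  arr <- array(c(field$ux, field$uy), dim = c(dim(field$ux), 2))
  RNifti::writeNifti(nifti_with_pixdim(arr, c(field$spacing, field$spacing, 1)),
                     path)
  invisible(path)
}

#' @rdname write_rigid_transform
#' @export
read_deformation_field <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  sp <- RNifti::pixdim(nii)[1]
  deformation_field(arr[, , 1], arr[, , 2], sp)
}

#' Dice overlap of two silhouettes
#'
#' @param a,b `silhouette_mask` objects on a common grid
#' @return Dice coefficient in `[0, 1]` (1 when both masks are empty)
#' @export
dice <- function(a, b) {
  ma <- a$data
  mb <- b$data
  stopifnot(all(dim(ma) == dim(mb)))
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(1)
  2 * sum(ma & mb) / denom
}
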