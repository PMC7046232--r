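#' Build an anatomically-unbiased peak pressure template
#'
#' Iterative groupwise registration: (1) a seeded random draw picks an
#' initial template from the cohort; (2) the template is aligned, as moving
#' image, to every cohort image by rigid mutual-information registration
#' followed by diffeomorphic demons on the silhouettes; (3) the rigid
#' transforms and deformation fields are averaged; (4) the averaged
#' transform is applied to the template, moving it toward the population
#' mean shape. Steps 2-4 repeat until the template stops changing. The
#' result no longer carries the anatomy of any single foot, which removes
#' reference bias from all downstream pixel statistics.
#'
#' @param images list of `N >= 2` left-oriented [pressure_image()] objects
#'   (typically per-foot averages) on a common grid
#' @param seed seed for the initial template draw and registrations
#' @param max_iter iteration budget (default 10)
#' @param tol convergence tolerance on the relative L2 change of the
#'   template between iterations (default 1e-3)
#' @param silhouette_threshold threshold (kPa) for the template silhouette
#' @param es [es_config()] settings for the rigid registrations
#' @param demons_args list of extra arguments for [demons_register()]
#' @param init_index override the random initial-reference draw
#' @param intensity_average after geometric convergence, register every
#'   cohort image into the template frame and average their intensities
#'   (default TRUE). The iterated loop converges the template's *shape* to
#'   the population mean but keeps the initial reference's pressure
#'   amplitudes; the averaging pass removes that remaining intensity bias.
#' @return a `template_result`: list with `template` ([pressure_image()]),
#'   `silhouette` ([silhouette_mask()]), `iterations`, `drift_trace`, and
#'   `converged`
#' @export
build_template <- function(images, seed = 0, max_iter = 10, tol = 1e-3,
                           silhouette_threshold = 5, es = es_config(),
                           demons_args = list(), init_index = NULL,
                           intensity_average = TRUE) {
  n <- length(images)
  if (n < 2) stop("template construction needs at least 2 images")
  dims <- dim(images[[1]]$data)
  stopifnot(all(vapply(images, function(im) all(dim(im$data) == dims), TRUE)))
  avg_rounds <- 2L
  seeds <- derive_seeds(seed, (max_iter + avg_rounds) * n + 1L)
  init_idx <- if (!is.null(init_index)) as.integer(init_index)
              else with_seed(seeds[1], sample.int(n, 1))
  reference <- images[[init_idx]]
  sp <- reference$spacing[1]
  # the template is always a single resampling of the chosen reference
  # through the accumulated average map (composing the per-iteration average
  # transforms as displacement fields); re-warping the template itself would
  # pile up interpolation blur and stall convergence
  dx <- matrix(0, dims[1], dims[2])
  dy <- matrix(0, dims[1], dims[2])
  render <- function() {
    out <- cpp_warp(reference$data, dims[1], dims[2], 0, 0, 0, 0, 0,
                    dx, dy, sp, 3L, TRUE)
    img <- reference
    img$data <- out
    img
  }
  template <- render()
  drift <- numeric(0)
  converged <- FALSE
  sil <- function(img) compute_silhouette(img, silhouette_threshold)
  px <- (seq_len(dims[1]) - 1) * sp
  py <- (seq_len(dims[2]) - 1) * sp
  gx <- matrix(px, dims[1], dims[2])
  gy <- matrix(py, dims[1], dims[2], byrow = TRUE)
  for (it in seq_len(max_iter)) {
    rigids <- vector("list", n)
    fields <- vector("list", n)
    for (i in seq_len(n)) {
      cfg <- es
      cfg$seed <- seeds[1L + (it - 1L) * n + i]
      t_i <- rigid_register(template, images[[i]], cfg)
      warped <- apply_transform(template, t_i, out_dim = dims)
      f_i <- do.call(demons_register,
                     c(list(moving_mask = sil(warped), fixed_mask = sil(images[[i]])),
                       demons_args))
      rigids[[i]] <- t_i
      fields[[i]] <- f_i
    }
    avg <- average_transforms(rigids, fields)
    # displacement form of the average map p -> T_bar(p + u_bar(p))
    qx <- gx + avg$field$ux
    qy <- gy + avg$field$uy
    ct <- cos(avg$rigid$angle)
    st <- sin(avg$rigid$angle)
    cc <- avg$rigid$center
    step_x <- ct * (qx - cc[1]) - st * (qy - cc[2]) + cc[1] +
      avg$rigid$translation[1] - gx
    step_y <- st * (qx - cc[1]) + ct * (qy - cc[2]) + cc[2] +
      avg$rigid$translation[2] - gy
    comp <- cpp_compose_field(step_x, step_y, dx, dy, sp)
    new_dx <- comp$ux
    new_dy <- comp$uy
    old_dx <- dx
    old_dy <- dy
    dx <- new_dx
    dy <- new_dy
    new_template <- render()
    denom <- sqrt(sum(template$data^2))
    change <- if (denom > 0) sqrt(sum((new_template$data - template$data)^2)) / denom
              else Inf
    # accepted iterates must not move the template more than the previous
    # one did (with slack for optimizer jitter); a growing step means the
    # register-average-apply loop has left its contraction regime, so the
    # previous template is kept
    if (it > 1 && change > 1.25 * drift[length(drift)]) {
      dx <- old_dx
      dy <- old_dy
      break
    }
    template <- new_template
    drift <- c(drift, change)
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("template construction did not converge within ", max_iter,
            " iterations (last relative change ",
            sprintf("%.2g", drift[length(drift)]), ")")
  if (intensity_average) {
    # if the converged frame sits off the population mean by delta, the
    # image->template maps average to -delta; resampling the averaged
    # intensities through the negated mean map removes that residual bias.
    # The correction relies on the registrations themselves, so a second
    # round against the corrected template removes most of what the first
    # round's registrations under-estimated.
    for (round in seq_len(avg_rounds)) {
      acc <- matrix(0, dims[1], dims[2])
      mean_dx <- matrix(0, dims[1], dims[2])
      mean_dy <- matrix(0, dims[1], dims[2])
      tmpl_sil <- sil(template)
      for (i in seq_len(n)) {
        cfg <- es
        cfg$seed <- seeds[1L + (max_iter + round - 1L) * n + i]
        t_i <- rigid_register(images[[i]], template, cfg)
        warped <- apply_transform(images[[i]], t_i, out_dim = dims)
        f_i <- do.call(demons_register,
                       c(list(moving_mask = sil(warped), fixed_mask = tmpl_sil),
                         demons_args))
        acc <- acc + apply_transform(images[[i]], t_i, f_i, out_dim = dims)$data
        # displacement form of the image->template point map
        qx <- gx + f_i$ux
        qy <- gy + f_i$uy
        ct <- cos(t_i$angle)
        st <- sin(t_i$angle)
        cc <- t_i$center
        mean_dx <- mean_dx + (ct * (qx - cc[1]) - st * (qy - cc[2]) + cc[1] +
                                t_i$translation[1] - gx) / n
        mean_dy <- mean_dy + (st * (qx - cc[1]) + ct * (qy - cc[2]) + cc[2] +
                                t_i$translation[2] - gy) / n
      }
      template$data <- cpp_warp(acc / n, dims[1], dims[2], 0, 0, 0, 0, 0,
                                -mean_dx, -mean_dy, sp, 3L, TRUE)
    }
  }
  structure(
    list(template = template, silhouette = sil(template),
         iterations = length(drift), drift_trace = drift,
         converged = converged, initial_index = init_idx, seed = seed),
    class = "template_result"
  )
}

#' @export
print.template_result <- function(x, ...) {
  cat(sprintf("<template_result> %d x %d px, %d silhouette px, %d iterations (%s)\n",
              nrow(x$template$data), ncol(x$template$data),
              sum(x$silhouette$data), x$iterations,
              if (x$converged) "converged" else "budget hit"))
  invisible(x)
}

#' Persist a template to disk
#'
#' The template and its silhouette go to NIfTI; build provenance (seed,
#' iterations, drift trace) to a JSON sidecar.
#'
#' @param x a `template_result`
#' @param dir output directory (created if needed)
#' @export
write_template <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pressure_image(x$template, file.path(dir, "template.nii.gz"))
  write_pressure_image(
    pressure_image(x$silhouette$data * 1, spacing = x$silhouette$spacing),
    file.path(dir, "silhouette.nii.gz"))
  jsonlite::write_json(
    list(seed = x$seed, iterations = x$iterations,
         drift_trace = x$drift_trace, converged = x$converged,
         silhouette_threshold = x$silhouette$threshold),
    file.path(dir, "template.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_template
#' @export
read_template <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "template.json"),
                              simplifyVector = TRUE)
  template <- read_pressure_image(file.path(dir, "template.nii.gz"))
  template$side <- "left"
  sil <- read_pressure_image(file.path(dir, "silhouette.nii.gz"))
  structure(
    list(template = template,
         silhouette = silhouette_mask(sil$data > 0, spacing = sil$spacing,
                                      threshold = meta$silhouette_threshold),
         iterations = meta$iterations, drift_trace = meta$drift_trace,
         converged = meta$converged, seed = meta$seed),
    class = "template_result"
  )
}
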