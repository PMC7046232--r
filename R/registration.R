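#' Histogram-based mutual information between two pressure images
#'
#' Computed in nats from the joint histogram (default 50 bins per dimension)
#' over the pixels where either image is positive, with each image's
#' intensity range taken as `[0, max]`. Mutual information rewards matching
#' of homogeneous regions, including the foot/background boundary, which is
#' what makes it a robust similarity measure for footprint alignment.
#'
#' @param image_a,image_b [pressure_image()] objects with equal spacing;
#'   `image_b` is zero-padded/cropped onto `image_a`'s grid if needed
#' @param bins histogram bins per dimension (default 50)
#' @return mutual information in nats (>= 0; 0 for constant images)
#' @export
mutual_information <- function(image_a, image_b, bins = 50) {
  if (!isTRUE(all.equal(image_a$spacing, image_b$spacing)))
    stop("images must share pixel spacing")
  if (!all(dim(image_a$data) == dim(image_b$data)))
    image_b <- conform_grid(image_b, image_a)
  cpp_mi(image_a$data, image_b$data, as.integer(bins))
}

#' Center of pressure (intensity centroid) of an image
#'
#' @param image a [pressure_image()]
#' @return physical coordinates in mm, length 2
#' @export
center_of_pressure <- function(image) {
  d <- image$data
  s <- sum(d)
  if (s <= 0) return((dim(d) - 1) / 2 * image$spacing)
  i <- rowSums(d) %*% (seq_len(nrow(d)) - 1) / s
  j <- colSums(d) %*% (seq_len(ncol(d)) - 1) / s
  c(i, j) * image$spacing
}

#' Control settings for the 1+1 evolution strategy rigid registration
#'
#' The optimizer keeps a single parent parameter vector (rotation, two
#' translations) and proposes Gaussian mutations with per-parameter step
#' sizes that grow on success and shrink on failure.
#'
#' @param init_step_deg,init_step_mm initial mutation SD (2 deg, 4 mm)
#' @param grow,shrink step multipliers on success / failure
#' @param max_iter iteration budget
#' @param min_step_deg,min_step_mm convergence threshold on the step sizes
#' @param bins mutual-information histogram bins
#' @param seed RNG seed for the mutation stream
#' @param multi_start also start from rotations of +/- 10 degrees
#' @return a list of settings for [rigid_register()]
#' @export
es_config <- function(init_step_deg = 2, init_step_mm = 4, grow = 1.05,
                      shrink = 0.98, max_iter = 500, min_step_deg = 0.1,
                      min_step_mm = 0.1, bins = 50, seed = 0,
                      multi_start = FALSE) {
  as.list(environment())
}

#' Rigid registration by mutual-information maximization
#'
#' Finds the rigid transform `T` maximizing `MI(fixed, moving o T)` with a
#' (1+1) evolution strategy, rotating about the moving image's center of
#' pressure. If no candidate improves on the identity transform, the
#' identity is returned with attribute `improved = FALSE`.
#'
#' @param moving,fixed [pressure_image()] objects with equal isotropic
#'   spacing
#' @param config settings from [es_config()]
#' @return a [rigid_transform2d()] with attributes `mi` (final metric),
#'   `trace` (accepted metric values), `improved`, `converged`
#' @export
rigid_register <- function(moving, fixed, config = es_config()) {
  stopifnot(is_isotropic(moving), is_isotropic(fixed),
            isTRUE(all.equal(moving$spacing, fixed$spacing)))
  cop <- center_of_pressure(moving)
  out_dim <- dim(fixed$data)
  # linear interpolation while scoring candidates (the metric is smooth
  # enough); the final transform is applied with cubic interpolation
  score <- function(p) {
    w <- cpp_warp(moving$data, out_dim[1], out_dim[2], p[1], p[2], p[3],
                  cop[1], cop[2], NULL, NULL, moving$spacing[1], 1L, FALSE)
    cpp_mi(fixed$data, w, as.integer(config$bins))
  }
  d2r <- pi / 180
  # center-of-mass initialization bridges flat metric regions (e.g. fully
  # disjoint footprints, where mutual information has no local gradient)
  t_c <- center_of_pressure(moving) - center_of_pressure(fixed)
  starts <- list(c(0, 0, 0), c(0, t_c))
  if (isTRUE(config$multi_start))
    starts <- c(starts, list(c(10 * d2r, t_c), c(-10 * d2r, t_c)))
  id_score <- score(c(0, 0, 0))
  best <- list(p = c(0, 0, 0), s = id_score, trace = id_score, converged = FALSE)
  with_seed(config$seed, {
    for (p0 in starts) {
      res <- cpp_es_rigid(moving$data, fixed$data, cop[1], cop[2],
                          moving$spacing[1], p0,
                          c(config$init_step_deg * d2r, config$init_step_mm,
                            config$init_step_mm),
                          config$grow, config$shrink,
                          as.integer(config$max_iter),
                          c(config$min_step_deg * d2r, config$min_step_mm),
                          as.integer(config$bins))
      if (res$score > best$s)
        best <- list(p = res$p, s = res$score, trace = res$trace,
                     converged = res$converged)
    }
  })
  improved <- best$s > id_score
  t <- if (improved) rigid_transform2d(best$p[1], best$p[2:3], cop)
       else rigid_transform2d(0, c(0, 0), cop)
  structure(t, mi = best$s, trace = best$trace, improved = improved,
            converged = best$converged, class = class(t))
}

#' Diffeomorphic demons registration of footprint silhouettes
#'
#' Alternates a demons force step that pulls the warped moving silhouette
#' toward the fixed one with Gaussian regularization of the update ("fluid")
#' and of the accumulated field ("diffusion"); each update is exponentiated
#' by scaling-and-squaring so the accumulated map stays a diffeomorphism.
#' The coupling weight `lambda1` and smoothness weight `lambda2` set the
#' regularization strength through the kernel width
#' `sigma_px * sqrt(lambda2 / lambda1)`. The best accepted iterate (by Dice
#' overlap, starting from the identity) is returned, so the Dice after
#' alignment never falls below the Dice before.
#'
#' @param moving_mask,fixed_mask [silhouette_mask()] objects on a common grid
#' @param lambda1,lambda2 coupling / smoothness weights (default 2 each)
#' @param iters iteration budget (default 60)
#' @param tol stop when Dice improves by less than this over 5 iterations
#' @param sigma_px base Gaussian kernel width in pixels (default 1.5)
#' @param sigma_fluid,sigma_diff override the update ("fluid") and
#'   accumulated-field ("diffusion") kernel widths directly; by default the
#'   update uses `sigma_px * sqrt(lambda2 / lambda1)` and the accumulated
#'   field gets a light 0.3 px pass
#' @return a [deformation_field()] with attributes `dice_before`,
#'   `dice_after`, `iterations`, `converged`
#' @export
demons_register <- function(moving_mask, fixed_mask, lambda1 = 2, lambda2 = 2,
                            iters = 60, tol = 1e-4, sigma_px = 1.5,
                            sigma_fluid = NULL, sigma_diff = NULL) {
  stopifnot(all(dim(moving_mask$data) == dim(fixed_mask$data)))
  if (!any(moving_mask$data) || !any(fixed_mask$data))
    stop("demons registration requires two non-empty silhouettes")
  sp <- fixed_mask$spacing[1]
  # fluid-dominated regularization: the update is smoothed at sigma_px
  # (scaled by the lambda2/lambda1 smoothness-to-coupling ratio); the
  # accumulated field gets only a light diffusion pass, which preserves the
  # boundary displacements needed for sub-pixel silhouette overlap
  if (is.null(sigma_fluid)) sigma_fluid <- sigma_px * sqrt(lambda2 / lambda1)
  if (is.null(sigma_diff)) sigma_diff <- 0.3
  mb <- moving_mask$data * 1.0
  fb <- fixed_mask$data * 1.0
  ms <- cpp_gauss_smooth(mb, 1.0)
  fs <- cpp_gauss_smooth(fb, 1.0)
  dm <- dim(fb)
  ux <- matrix(0, dm[1], dm[2])
  uy <- matrix(0, dm[1], dm[2])
  dice_mat <- function(a, b) {
    d <- sum(a) + sum(b)
    if (d == 0) 1 else 2 * sum(a & b) / d
  }
  dice_of <- function(ux, uy) {
    w <- cpp_warp(mb, dm[1], dm[2], 0, 0, 0, 0, 0, ux, uy, sp, 0L, FALSE)
    dice_mat(w > 0.5, fb > 0.5)
  }
  exp_field <- function(vx, vy) {
    n_sq <- 6L
    vx <- vx / 2^n_sq
    vy <- vy / 2^n_sq
    for (k in seq_len(n_sq)) {
      cf <- cpp_compose_field(vx, vy, vx, vy, sp)
      vx <- cf$ux
      vy <- cf$uy
    }
    list(ux = vx, uy = vy)
  }
  dice0 <- dice_mat(mb > 0.5, fb > 0.5)
  best <- list(ux = ux, uy = uy, dice = dice0, it = 0L)
  stall <- 0L
  converged <- FALSE
  cap <- 1.5 * sp
  for (it in seq_len(iters)) {
    w <- cpp_warp(ms, dm[1], dm[2], 0, 0, 0, 0, 0, ux, uy, sp, 1L, FALSE)
    f <- cpp_demons_force(fs, w, sp, sp^2, 1e-9)
    mag <- sqrt(f$ux^2 + f$uy^2)
    scl <- ifelse(mag > cap, cap / mag, 1)
    vx <- cpp_gauss_smooth(f$ux * scl, sigma_fluid)
    vy <- cpp_gauss_smooth(f$uy * scl, sigma_fluid)
    ok <- FALSE
    for (halving in 0:3) {
      ev <- exp_field(vx / 2^halving, vy / 2^halving)
      cf <- cpp_compose_field(ev$ux, ev$uy, ux, uy, sp)
      nx <- cpp_gauss_smooth(cf$ux, sigma_diff)
      ny <- cpp_gauss_smooth(cf$uy, sigma_diff)
      if (min(cpp_jacobian(nx, ny, sp)) > 0) {
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    ux <- nx
    uy <- ny
    d_now <- dice_of(ux, uy)
    if (d_now > best$dice + tol) {
      best <- list(ux = ux, uy = uy, dice = d_now, it = it)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 5L) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged && best$it == iters)
    warning("demons registration hit the iteration budget before converging")
  field <- deformation_field(best$ux, best$uy, sp)
  if (field$jacobian_min <= 0)
    stop("internal error: accepted demons iterate is not diffeomorphic")
  structure(field, dice_before = dice0, dice_after = best$dice,
            iterations = best$it, converged = converged, class = class(field))
}

#' Align repeated measurements of one foot and average them
#'
#' One of the `K` peak pressure images is chosen as reference by a seeded
#' random draw; all others are rigidly aligned to it by
#' mutual-information registration, and the aligned images (reference
#' included, with the identity transform) are averaged pixel-wise to reduce
#' biological and measurement noise.
#'
#' @param images list of [pressure_image()] from the same foot, common grid
#' @param seed seed for the reference draw (default 0)
#' @param config [es_config()] settings for the pairwise registrations
#' @return a [pressure_image()] with attributes `reference` (index) and
#'   `transforms`
#' @export
align_and_average_foot <- function(images, seed = 0, config = es_config()) {
  k <- length(images)
  stopifnot(k >= 1)
  if (k == 1) return(images[[1]])
  ref_idx <- with_seed(seed, sample.int(k, 1))
  ref <- images[[ref_idx]]
  transforms <- vector("list", k)
  acc <- matrix(0, nrow(ref$data), ncol(ref$data))
  for (j in seq_len(k)) {
    if (j == ref_idx) {
      transforms[[j]] <- rigid_transform2d()
      acc <- acc + ref$data
    } else {
      t_j <- rigid_register(images[[j]], ref, config)
      transforms[[j]] <- t_j
      acc <- acc + apply_transform(images[[j]], t_j,
                                   out_dim = dim(ref$data))$data
    }
  }
  out <- ref
  out$data <- acc / k
  structure(out, reference = ref_idx, transforms = transforms,
            class = class(out))
}
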