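#' Synthetic foot phenotype
#'
#' Geometry and loading pattern of a synthetic foot: anatomical loci (heel,
#' midfoot, metatarsal heads 1-5, hallux, lesser toes) rendered as
#' anisotropic Gaussian pressure blobs inside a smooth foot outline. The
#' blob construction keeps the ground-truth coefficient maps, residual SD
#' and abnormality masks available in closed form, which real-image warping
#' would not.
#'
#' Coordinates are in the canonical left-foot frame: anterior-posterior
#' position as a fraction of foot length (heel at 0), medial-lateral
#' position as a fraction of foot width with the medial (big-toe) side at
#' high column fractions.
#'
#' @param length_mm,width_mm foot dimensions (default 240 x 95 mm)
#' @param arch_factor scales the midfoot amplitude (1 = normal arch; higher
#'   values emulate pes planus loading)
#' @param loci data frame of blob parameters; `NULL` for the defaults
#' @return a `foot_phenotype`
#' @export
foot_phenotype <- function(length_mm = 240, width_mm = 95, arch_factor = 1,
                           loci = NULL) {
  if (is.null(loci)) {
    loci <- tibble::tibble(
      locus = c("heel", "midfoot", "MT1", "MT2", "MT3", "MT4", "MT5",
                "hallux", "toes2_5"),
      fx = c(0.12, 0.40, 0.68, 0.72, 0.72, 0.70, 0.67, 0.88, 0.90),
      fy = c(0.50, 0.40, 0.76, 0.58, 0.44, 0.32, 0.20, 0.72, 0.40),
      sd_x = c(14, 22, 9, 8, 8, 8, 8, 8, 7),
      sd_y = c(12, 10, 8, 7, 7, 7, 7, 7, 10),
      base = c(260, 55 * arch_factor, 210, 230, 200, 160, 130, 190, 70)
    )
    # demographic effects: kPa per unit covariate (age yr, sex 0/1, weight
    # kg, height cm, shoe size EU), applied to centred covariates
    eff <- rbind(
      heel    = c(-0.40, 12, 0.90, 0.15, 0.0),
      midfoot = c( 0.00,  0, 0.45, 0.00, 0.0),
      MT1     = c( 0.25,  6, 0.70, 0.00, 0.0),
      MT2     = c( 0.30,  6, 0.80, 0.00, 0.0),
      MT3     = c( 0.25,  5, 0.60, 0.00, 0.0),
      MT4     = c( 0.00,  4, 0.40, 0.00, 0.0),
      MT5     = c( 0.00,  0, 0.30, 0.00, 0.0),
      hallux  = c( 0.00,  8, 0.50, 0.00, 1.0),
      toes2_5 = c( 0.00,  0, 0.15, 0.00, 0.5)
    )
    colnames(eff) <- c("age", "sex", "weight", "height", "shoe_size")
    loci$effects <- lapply(seq_len(nrow(eff)), function(i) eff[i, ])
  }
  stopifnot(all(loci$base >= 0), all(loci$fx >= 0 & loci$fx <= 1),
            all(loci$fy >= 0 & loci$fy <= 1))
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 arch_factor = arch_factor, loci = loci,
                 # covariate centring used by the linear amplitude model
                 z_center = c(age = 40, sex = 0.5, weight = 75,
                              height = 175, shoe_size = 41)),
            class = "foot_phenotype")
}

#' Cohort specification for synthetic pressure data
#'
#' Encodes the study design emulated by the generator: cohort size,
#' demographic distributions, per-measurement noise, number of repeated
#' measurements per foot, and the small random rigid misalignments between
#' repeats. Defaults mirror a healthy-control acquisition: 55 feet measured
#' 24 times each.
#'
#' @param n_subjects cohort size (default 55)
#' @param k_repeats measurements per foot (default 24)
#' @param age_range,weight_range,height_range,shoe_range uniform sampling
#'   ranges (years, kg, cm, EU size)
#' @param sex_ratio probability of male (default 0.5)
#' @param noise_sd per-measurement pixel noise SD in kPa (default 10)
#' @param noise_fwhm_px spatial FWHM of the noise in pixels (default 2;
#'   plate and biomechanical noise are spatially correlated)
#' @param rot_range_deg,trans_range_mm misalignment ranges between repeats
#' @param right_fraction fraction of right feet (mirrored at generation)
#' @param spacing grid spacing mm; `canvas_dim` grid size
#' @param phenotype a [foot_phenotype()]
#' @param seed master seed; the cohort is fully deterministic given it
#' @return a `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 55, k_repeats = 24,
                        age_range = c(20, 60), weight_range = c(55, 95),
                        height_range = c(155, 195), shoe_range = c(36, 46),
                        sex_ratio = 0.5, noise_sd = 10, noise_fwhm_px = 2,
                        rot_range_deg = c(-5, 5), trans_range_mm = c(-6, 6),
                        right_fraction = 0.5, spacing = 3,
                        canvas_dim = c(92, 48), phenotype = foot_phenotype(),
                        seed = 1) {
  structure(as.list(environment()), class = "cohort_spec")
}

# Smooth foot outline in the canonical frame: per-row halfwidth profile.
foot_outline <- function(phenotype, spacing, canvas_dim, margin_mm = c(20, 20)) {
  l_frac <- c(0, 0.08, 0.25, 0.42, 0.60, 0.78, 0.92, 1.0)
  halfw <- c(0.18, 0.44, 0.42, 0.33, 0.46, 0.50, 0.44, 0.12)
  hw_fun <- stats::splinefun(l_frac, halfw, method = "monoH.FC")
  nr <- canvas_dim[1]
  nc <- canvas_dim[2]
  x <- (seq_len(nr) - 1) * spacing - margin_mm[1]
  y <- (seq_len(nc) - 1) * spacing - margin_mm[2]
  lf <- x / phenotype$length_mm
  cy <- phenotype$width_mm / 2
  m <- outer(seq_along(x), seq_along(y), function(i, j) {
    ok <- lf[i] >= 0 & lf[i] <= 1
    ok & abs(y[j] - cy) <= hw_fun(pmin(pmax(lf[i], 0), 1)) * phenotype$width_mm
  })
  m
}

# Gaussian blob basis: canvas x n_loci matrix of unit-amplitude blobs.
blob_basis <- function(phenotype, spacing, canvas_dim, margin_mm = c(20, 20)) {
  nr <- canvas_dim[1]
  nc <- canvas_dim[2]
  x <- (seq_len(nr) - 1) * spacing - margin_mm[1]
  y <- (seq_len(nc) - 1) * spacing - margin_mm[2]
  loci <- phenotype$loci
  out <- array(0, c(nr, nc, nrow(loci)))
  for (k in seq_len(nrow(loci))) {
    cx <- loci$fx[k] * phenotype$length_mm
    cy <- loci$fy[k] * phenotype$width_mm
    gx <- exp(-0.5 * ((x - cx) / loci$sd_x[k])^2)
    gy <- exp(-0.5 * ((y - cy) / loci$sd_y[k])^2)
    out[, , k] <- gx %o% gy
  }
  out
}

# Per-locus amplitude as a linear function of the demographics vector.
locus_amplitudes <- function(phenotype, z) {
  z5 <- z[1:5] - phenotype$z_center
  vapply(seq_len(nrow(phenotype$loci)), function(k) {
    max(0, phenotype$loci$base[k] + sum(phenotype$loci$effects[[k]] * z5))
  }, numeric(1))
}

#' Render one synthetic peak pressure image
#'
#' Sum of demographic-dependent Gaussian pressure blobs, masked to the foot
#' outline, plus spatially-smoothed Gaussian pixel noise truncated at zero
#' (pressures are non-negative; the truncation-induced skew stays small
#' because the noise SD is well below the loaded-pixel pressures).
#'
#' @param phenotype a [foot_phenotype()]
#' @param z demographics vector from [demographics_vector()]
#' @param spec a [cohort_spec()] (noise and grid settings)
#' @param seed RNG seed; the image is bit-identical given the same seed
#' @return a left-oriented [pressure_image()] in kPa
#' @export
generate_foot_image <- function(phenotype, z, spec = cohort_spec(), seed = 0) {
  z <- as_z(z)
  basis <- blob_basis(phenotype, spec$spacing, spec$canvas_dim)
  outline <- foot_outline(phenotype, spec$spacing, spec$canvas_dim)
  amps <- locus_amplitudes(phenotype, z)
  clean <- matrix(0, spec$canvas_dim[1], spec$canvas_dim[2])
  for (k in seq_along(amps)) clean <- clean + amps[k] * basis[, , k]
  clean <- clean * outline
  noisy <- with_seed(seed, add_pressure_noise(clean, outline, spec))
  pressure_image(noisy, spacing = spec$spacing, side = "left")
}

add_pressure_noise <- function(clean, outline, spec) {
  if (spec$noise_sd <= 0) return(clean)
  e <- matrix(rnorm(length(clean)), nrow(clean), ncol(clean))
  if (spec$noise_fwhm_px > 1) {
    sigma <- spec$noise_fwhm_px / (2 * sqrt(2 * log(2)))
    e <- cpp_gauss_smooth(e, sigma)
    e <- e / sd(as.numeric(e))
  }
  pmax(clean + spec$noise_sd * e * outline, 0)
}

#' Generate a synthetic cohort with known demographic effects
#'
#' Samples demographics, renders each foot's noise-free pressure pattern,
#' and produces `k_repeats` measurements per foot under independent small
#' rigid misalignments and independent noise. Right feet are mirrored
#' images with `side = "right"`. Ground truth (coefficient maps in the
#' canonical frame, the noise-free reference at the centre demographics,
#' applied misalignments, noise SD) is returned separately from the
#' "observable" data.
#'
#' @param spec a [cohort_spec()]
#' @return list with `feet` (per foot: `foot_id`, `side`, `images`,
#'   `true_transforms`), `demographics` (tibble), `truth`, and `spec`
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(spec$n_subjects >= 2)
  n <- spec$n_subjects
  seeds <- derive_seeds(spec$seed, 2L + n)
  demo <- with_seed(seeds[1], tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    foot_id = sprintf("S%03d_F1", seq_len(n)),
    side = ifelse(runif(n) < spec$right_fraction, "right", "left"),
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    sex = as.numeric(runif(n) < spec$sex_ratio),
    weight = runif(n, spec$weight_range[1], spec$weight_range[2]),
    height = runif(n, spec$height_range[1], spec$height_range[2]),
    shoe_size = sample(seq(spec$shoe_range[1], spec$shoe_range[2], by = 0.5),
                       n, replace = TRUE)
  ))
  basis <- blob_basis(spec$phenotype, spec$spacing, spec$canvas_dim)
  outline <- foot_outline(spec$phenotype, spec$spacing, spec$canvas_dim)
  z_all <- design_matrix(demo)
  feet <- vector("list", n)
  for (i in seq_len(n)) {
    amps <- locus_amplitudes(spec$phenotype, z_all[i, ])
    clean <- matrix(0, spec$canvas_dim[1], spec$canvas_dim[2])
    for (k in seq_along(amps)) clean <- clean + amps[k] * basis[, , k]
    clean <- clean * outline
    clean_img <- pressure_image(clean, spacing = spec$spacing, side = "left")
    feet[[i]] <- with_seed(seeds[2L + i], {
      images <- vector("list", spec$k_repeats)
      trs <- vector("list", spec$k_repeats)
      for (j in seq_len(spec$k_repeats)) {
        tr <- rigid_transform2d(
          runif(1, spec$rot_range_deg[1], spec$rot_range_deg[2]) * pi / 180,
          runif(2, spec$trans_range_mm[1], spec$trans_range_mm[2]),
          center_of_pressure(clean_img))
        moved <- if (max(abs(c(tr$angle, tr$translation))) > 0)
          apply_transform(clean_img, tr) else clean_img
        img <- moved
        img$data <- add_pressure_noise(moved$data, moved$data > 0, spec)
        if (demo$side[i] == "right") {
          img$data <- img$data[, rev(seq_len(ncol(img$data))), drop = FALSE]
          img$side <- "right"
        }
        images[[j]] <- img
        trs[[j]] <- tr
      }
      list(foot_id = demo$foot_id[i], side = demo$side[i], images = images,
           true_transforms = trs)
    })
  }
  b_truth <- ground_truth_maps(spec)
  list(feet = feet, demographics = demo,
       truth = list(coefficient_maps = b_truth$maps,
                    reference = b_truth$reference, outline = outline,
                    blob_centers_px = b_truth$centers_px,
                    noise_sd = spec$noise_sd),
       spec = spec)
}

# Closed-form coefficient maps implied by the blob construction, plus the
# noise-free reference image at the centre demographics.
ground_truth_maps <- function(spec) {
  ph <- spec$phenotype
  basis <- blob_basis(ph, spec$spacing, spec$canvas_dim)
  outline <- foot_outline(ph, spec$spacing, spec$canvas_dim)
  dm <- spec$canvas_dim
  maps <- array(0, c(dm, 6),
                dimnames = list(NULL, NULL,
                                c("age", "sex", "weight", "height",
                                  "shoe_size", "intercept")))
  for (k in seq_len(nrow(ph$loci))) {
    eff <- ph$loci$effects[[k]]
    for (v in seq_len(5))
      maps[, , v] <- maps[, , v] + eff[v] * basis[, , k]
    maps[, , 6] <- maps[, , 6] +
      (ph$loci$base[k] - sum(eff * ph$z_center)) * basis[, , k]
  }
  for (v in seq_len(6)) maps[, , v] <- maps[, , v] * outline
  z_mid <- c(ph$z_center, intercept = 1)
  ref <- matrix(0, dm[1], dm[2])
  for (v in seq_len(6)) ref <- ref + z_mid[v] * maps[, , v]
  margin_px <- 20 / spec$spacing
  centers_px <- cbind(
    row = ph$loci$fx * ph$length_mm / spec$spacing + margin_px + 1,
    col = ph$loci$fy * ph$width_mm / spec$spacing + margin_px + 1)
  rownames(centers_px) <- ph$loci$locus
  list(maps = maps,
       reference = pressure_image(pmax(ref, 0), spacing = spec$spacing,
                                  side = "left"),
       centers_px = centers_px)
}

#' Inject a localized abnormality into a pressure image
#'
#' Adds `magnitude * s(x)` (the model's pixel-wise residual SD) inside a
#' Gaussian-tapered disc: full magnitude within `radius_px`, Gaussian
#' falloff (SD 1 px) beyond. Negative magnitudes create pressure deficits.
#'
#' @param image a [pressure_image()] on the model grid
#' @param center_px length-2 pixel coordinates (row, col) of the disc center
#' @param radius_px disc radius in pixels
#' @param magnitude abnormality size in units of the model residual SD
#' @param model a `pixelwise_model` providing `s(x)` and the domain
#' @return the modified image, with attribute `truth_mask` (logical matrix
#'   of the pixels at full magnitude, inside the model domain)
#' @export
inject_abnormality <- function(image, center_px, radius_px, magnitude, model) {
  dm <- dim(image$data)
  stopifnot(all(dm == dim(model$domain$data)))
  s_map <- model_image(model, model$residual_sd)$data
  rr <- sqrt(outer((seq_len(dm[1]) - center_px[1])^2,
                   (seq_len(dm[2]) - center_px[2])^2, `+`))
  w <- ifelse(rr <= radius_px, 1, exp(-0.5 * (rr - radius_px)^2))
  out <- image
  out$data <- pmax(image$data + magnitude * s_map * w, 0)
  truth <- rr <= radius_px & model$domain$data
  if (!any(truth)) stop("abnormality region lies outside the model domain")
  structure(out, truth_mask = truth, class = class(out))
}

#' Wrap a peak image as a short pressure video
#'
#' Builds a synthetic stance-phase video whose per-frame pressures are the
#' image scaled by a smooth temporal envelope peaking at 1, so the peak
#' pressure image of the video reproduces the input. Used to exercise the
#' video preprocessing path (resampling, normalization, peak extraction).
#'
#' @param image a [pressure_image()] in kPa
#' @param n_frames frames in the video (default 20)
#' @param frequency sampling rate Hz (default 500)
#' @return a [pressure_video()]
#' @export
as_pressure_video <- function(image, n_frames = 20, frequency = 500) {
  env <- sin(pi * seq(0.5 / n_frames, 1 - 0.5 / n_frames, length.out = n_frames))
  env <- env / max(env)
  arr <- array(0, c(dim(image$data), n_frames))
  for (t in seq_len(n_frames)) arr[, , t] <- image$data * env[t]
  pressure_video(arr, spacing = image$spacing, frequency = frequency,
                 side = image$side)
}

#' Write a synthetic cohort in the NIfTI + CSV layout the readers expect
#'
#' One NIfTI per measurement under `dir/images/`, a `demographics.csv`, and
#' the ground truth in a separate `truth/` bundle (kept apart from the
#' observable data).
#'
#' @param cohort a [generate_cohort()] result
#' @param dir output directory
#' @export
write_cohort <- function(cohort, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (foot in cohort$feet)
    for (j in seq_along(foot$images))
      write_pressure_image(foot$images[[j]],
                           file.path(img_dir, sprintf("%s_rep%02d.nii.gz",
                                                      foot$foot_id, j)))
  write.csv(as.data.frame(cohort$demographics),
            file.path(dir, "demographics.csv"), row.names = FALSE)
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  RNifti::writeNifti(nifti_with_pixdim(cohort$truth$coefficient_maps,
                                       c(cohort$spec$spacing,
                                         cohort$spec$spacing, 1)),
                     file.path(truth_dir, "coefficient_maps.nii.gz"))
  write_pressure_image(cohort$truth$reference,
                       file.path(truth_dir, "reference.nii.gz"))
  jsonlite::write_json(list(noise_sd = cohort$truth$noise_sd,
                            seed = cohort$spec$seed),
                       file.path(truth_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
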