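#' Demographic design vectors
#'
#' The pixel-wise regression uses a fixed covariate order:
#' `[age, sex, weight, height, shoe_size, 1]` with age in years, sex coded
#' 0 = female / 1 = male, weight in kg, height in cm, shoe size EU, and a
#' trailing intercept.
#'
#' @param age,sex,weight,height,shoe_size scalar demographics; `sex` may be
#'   0/1, logical, or a two-level factor/character (`"female"`/`"male"`)
#' @return named numeric vector of length 6
#' @export
demographics_vector <- function(age, sex, weight, height, shoe_size) {
  c(age = as.numeric(age), sex = normalize_sex(sex),
    weight = as.numeric(weight), height = as.numeric(height),
    shoe_size = as.numeric(shoe_size), intercept = 1)
}

normalize_sex <- function(sex) {
  if (is.numeric(sex) || is.logical(sex)) {
    s <- as.numeric(sex)
    if (!all(s %in% c(0, 1))) stop("sex must be coded 0/1")
    return(s)
  }
  s <- tolower(as.character(sex))
  map <- c(f = 0, female = 0, m = 1, male = 1)
  if (!all(s %in% names(map))) stop("unrecognized sex coding: ", paste(unique(s), collapse = ", "))
  unname(map[s])
}

#' @rdname demographics_vector
#' @param demographics data frame with columns `age`, `sex`, `weight`,
#'   `height`, `shoe_size` (one row per foot/subject)
#' @return `design_matrix()`: an `N x 6` numeric matrix
#' @export
design_matrix <- function(demographics) {
  need <- c("age", "sex", "weight", "height", "shoe_size")
  miss <- setdiff(need, names(demographics))
  if (length(miss)) stop("demographics table lacks columns: ", paste(miss, collapse = ", "))
  z <- cbind(age = as.numeric(demographics$age),
             sex = normalize_sex(demographics$sex),
             weight = as.numeric(demographics$weight),
             height = as.numeric(demographics$height),
             shoe_size = as.numeric(demographics$shoe_size),
             intercept = 1)
  rownames(z) <- NULL
  z
}

#' Fit the pixel-wise linear model of healthy peak pressures
#'
#' At every pixel inside the model domain (the template silhouette), peak
#' pressures across the healthy cohort are regressed on the demographic
#' design matrix by ordinary least squares, and the residuals are modelled
#' as zero-mean normal with pixel-specific variance. Residual vectors are
#' retained for normality diagnostics and smoothness estimation.
#'
#' @param aligned_images list of `N` [pressure_image()] objects aligned to
#'   the template grid
#' @param demographics data frame (see [design_matrix()]) or precomputed
#'   `N x 6` design matrix, rows matching `aligned_images`
#' @param domain [silhouette_mask()] of the template; the model exists only
#'   inside it
#' @param template optional [pressure_image()], carried for prediction and
#'   reporting
#' @param variance_divisor `"n-p"` (default; unbiased under the regression
#'   model, p = 6) or `"n-1"`
#' @return a `pixelwise_model`
#' @export
fit_pixelwise_model <- function(aligned_images, demographics, domain,
                                template = NULL,
                                variance_divisor = c("n-p", "n-1")) {
  variance_divisor <- match.arg(variance_divisor)
  z <- if (is.matrix(demographics)) demographics else design_matrix(demographics)
  n <- length(aligned_images)
  p <- ncol(z)
  if (nrow(z) != n) stop("demographics rows must match the number of images")
  if (n <= p) stop("need more subjects than regressors (N > ", p, ")")
  qz <- qr(z)
  if (qz$rank < p) {
    bad <- colnames(z)[qz$pivot[seq(qz$rank + 1, p)]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  dm <- dim(domain$data)
  stopifnot(all(vapply(aligned_images, function(im) all(dim(im$data) == dm), TRUE)))
  idx <- which(domain$data)
  y <- t(vapply(aligned_images, function(im) im$data[idx], numeric(length(idx))))
  b <- qr.coef(qz, y)
  resid <- y - z %*% b
  df_resid <- if (variance_divisor == "n-p") n - p else n - 1
  s2 <- colSums(resid^2) / df_resid
  structure(
    list(coefficients = b, residual_sd = sqrt(s2), residual_matrix = resid,
         domain = domain, domain_idx = idx, template = template,
         design = z, n_subjects = n, n_terms = p, df_resid = n - p,
         xtx_inv = solve(crossprod(z)), variance_divisor = variance_divisor,
         terms = colnames(z)),
    class = "pixelwise_model"
  )
}

#' @export
print.pixelwise_model <- function(x, ...) {
  cat(sprintf("<pixelwise_model> %d pixels, N = %d subjects, %d terms, dof = %d\n",
              length(x$domain_idx), x$n_subjects, x$n_terms, x$df_resid))
  invisible(x)
}

# Build an image on the model grid from a vector over domain pixels.
model_image <- function(model, values, spacing = NULL) {
  m <- matrix(0, nrow(model$domain$data), ncol(model$domain$data))
  m[model$domain_idx] <- values
  pressure_image(m, spacing = if (is.null(spacing)) model$domain$spacing else spacing,
                 side = "left")
}

#' Predict a personalized baseline peak pressure image
#'
#' Evaluates the fitted linear model at a new demographics vector:
#' `I_predict(x) = z_new . b(x)` inside the model domain, zero outside.
#' Negative predictions are clamped to zero (count reported in attribute
#' `n_clamped`). Demographics outside the training ranges trigger an
#' extrapolation warning.
#'
#' @param model a [fit_pixelwise_model()] result
#' @param z_new length-6 vector from [demographics_vector()] (or a 1-row
#'   demographics data frame)
#' @return a [pressure_image()] on the model grid
#' @export
predict_pressures <- function(model, z_new) {
  z_new <- as_z(z_new)
  rng_lo <- apply(model$design, 2, min)
  rng_hi <- apply(model$design, 2, max)
  outside <- z_new < rng_lo | z_new > rng_hi
  if (any(outside))
    warning("extrapolating beyond training demographics for: ",
            paste(model$terms[outside], collapse = ", "))
  pred <- as.numeric(z_new %*% model$coefficients)
  n_clamped <- sum(pred < 0)
  pred[pred < 0] <- 0
  img <- model_image(model, pred)
  structure(img, n_clamped = n_clamped, class = class(img))
}

as_z <- function(z_new) {
  if (is.data.frame(z_new)) {
    stopifnot(nrow(z_new) == 1)
    z_new <- design_matrix(z_new)[1, ]
  }
  stopifnot(length(z_new) == 6)
  as.numeric(z_new)
}

#' Normality diagnostics for the pixel-wise residual model
#'
#' One-sample Kolmogorov-Smirnov test, per pixel, of the stored residuals
#' against the fitted `Normal(0, s^2(x))`, with Benjamini-Hochberg false
#' discovery rate control across the model domain. Pixels with a degenerate
#' perfect fit (`s = 0`) get `p = 1` and are flagged.
#'
#' @param model a `pixelwise_model` (residuals retained)
#' @param alpha FDR level (default 0.05)
#' @return a `normality_report`: list with `p_map`, `rejected` (matrices on
#'   the model grid), `p_values`, `corrected_alpha` (largest p-value
#'   declared significant; 0 if none), `fraction_rejected`, `degenerate`
#' @export
check_normality <- function(model, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  s <- model$residual_sd
  pvals <- vapply(seq_along(s), function(k) {
    if (s[k] <= 0) return(1)
    suppressWarnings(ks.test(model$residual_matrix[, k], "pnorm", 0, s[k])$p.value)
  }, numeric(1))
  padj <- p.adjust(pvals, method = "BH")
  rej <- padj <= alpha
  corrected_alpha <- if (any(rej)) max(pvals[rej]) else 0
  structure(
    list(p_map = model_image(model, pvals)$data,
         rejected = model_image(model, as.numeric(rej))$data > 0,
         p_values = pvals, p_adjusted = padj,
         corrected_alpha = corrected_alpha,
         fraction_rejected = mean(rej),
         degenerate = s <= 0, alpha = alpha),
    class = "normality_report"
  )
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> %d pixels, %.1f%% rejected (FDR %g, realized cutoff %.2g)\n",
              length(x$p_values), 100 * x$fraction_rejected, x$alpha,
              x$corrected_alpha))
  invisible(x)
}

#' @export
tidy.pixelwise_model <- function(x, ...) {
  b <- x$coefficients
  tibble::tibble(
    term = x$terms,
    estimate_mean = rowMeans(b),
    estimate_sd = apply(b, 1, sd),
    estimate_min = apply(b, 1, min),
    estimate_max = apply(b, 1, max)
  )
}

#' @export
glance.pixelwise_model <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_terms = x$n_terms,
    n_pixels = length(x$domain_idx),
    df_residual = x$df_resid,
    mean_residual_sd = mean(x$residual_sd)
  )
}

#' Persist a fitted pixel-wise model
#'
#' Coefficient maps, residual SD map, domain and residual matrix go to
#' NIfTI; the design matrix to CSV; metadata to JSON.
#'
#' @param model a `pixelwise_model`
#' @param dir output directory
#' @export
write_pixelwise_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- dim(model$domain$data)
  sp <- model$domain$spacing
  coef_arr <- array(0, c(dm, model$n_terms))
  for (k in seq_len(model$n_terms)) {
    m <- matrix(0, dm[1], dm[2])
    m[model$domain_idx] <- model$coefficients[k, ]
    coef_arr[, , k] <- m
  }
  RNifti::writeNifti(nifti_with_pixdim(coef_arr, c(sp, 1)),
                     file.path(dir, "coefficients.nii.gz"))
  write_pressure_image(model_image(model, model$residual_sd),
                       file.path(dir, "residual_sd.nii.gz"))
  write_pressure_image(pressure_image(model$domain$data * 1, spacing = sp),
                       file.path(dir, "domain.nii.gz"))
  resid_arr <- array(0, c(dm, model$n_subjects))
  for (i in seq_len(model$n_subjects)) {
    m <- matrix(0, dm[1], dm[2])
    m[model$domain_idx] <- model$residual_matrix[i, ]
    resid_arr[, , i] <- m
  }
  RNifti::writeNifti(nifti_with_pixdim(resid_arr, c(sp, 1)),
                     file.path(dir, "residuals.nii.gz"))
  write.csv(as.data.frame(model$design), file.path(dir, "design.csv"),
            row.names = FALSE)
  if (!is.null(model$template))
    write_pressure_image(model$template, file.path(dir, "template.nii.gz"))
  jsonlite::write_json(
    list(n_subjects = model$n_subjects, terms = model$terms,
         variance_divisor = model$variance_divisor,
         silhouette_threshold = model$domain$threshold),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_pixelwise_model
#' @export
read_pixelwise_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  dom_img <- read_pressure_image(file.path(dir, "domain.nii.gz"))
  domain <- silhouette_mask(dom_img$data > 0, spacing = dom_img$spacing,
                            threshold = meta$silhouette_threshold)
  z <- as.matrix(read.csv(file.path(dir, "design.csv")))
  colnames(z) <- meta$terms
  idx <- which(domain$data)
  coefs <- as.array(RNifti::readNifti(file.path(dir, "coefficients.nii.gz")))
  b <- t(vapply(seq_along(meta$terms), function(k) coefs[, , k][idx],
                numeric(length(idx))))
  rownames(b) <- meta$terms
  resid_arr <- as.array(RNifti::readNifti(file.path(dir, "residuals.nii.gz")))
  resid <- t(vapply(seq_len(meta$n_subjects), function(i) resid_arr[, , i][idx],
                    numeric(length(idx))))
  template <- NULL
  if (file.exists(file.path(dir, "template.nii.gz"))) {
    template <- read_pressure_image(file.path(dir, "template.nii.gz"))
    template$side <- "left"
  }
  n <- meta$n_subjects
  p <- length(meta$terms)
  df_resid <- if (meta$variance_divisor == "n-p") n - p else n - 1
  structure(
    list(coefficients = b,
         residual_sd = sqrt(colSums(resid^2) / df_resid),
         residual_matrix = resid, domain = domain, domain_idx = idx,
         template = template, design = z, n_subjects = n, n_terms = p,
         df_resid = n - p, xtx_inv = chol2inv(chol(crossprod(z))),
         variance_divisor = meta$variance_divisor, terms = meta$terms),
    class = "pixelwise_model"
  )
}
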