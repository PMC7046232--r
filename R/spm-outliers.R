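#' Residual map between a patient's aligned pressures and their baseline
#'
#' `R(x) = I_patient(x) - I_predict(x)` inside the model domain, zero
#' outside. Positive residuals mean measured pressure above the personalized
#' healthy baseline.
#'
#' @param aligned_patient,predicted [pressure_image()] objects on the
#'   template grid
#' @param domain optional [silhouette_mask()] restricting the map
#' @return a [pressure_image()]
#' @export
residual_map <- function(aligned_patient, predicted, domain = NULL) {
  if (!all(dim(aligned_patient$data) == dim(predicted$data)))
    stop("grid mismatch between patient image and prediction")
  r <- aligned_patient$data - predicted$data
  if (!is.null(domain)) r[!domain$data] <- 0
  out <- predicted
  out$data <- r
  out
}

#' Single-case t-statistic map
#'
#' Converts a residual map into a statistical parametric map of
#' t-statistics against the pixel-wise residual model. The default
#' `"crawford"` variant is the Crawford-Howell / DisCo-Z prediction-interval
#' form `t = R / (s * sqrt(1 + z' (Z'Z)^-1 z))` with `N - p` degrees of
#' freedom, which has calibrated single-case type-I behavior. The `"naive"`
#' (`R / s`) and `"literal"` (`R / (s / sqrt(N))`) variants are available
#' for sensitivity analysis.
#'
#' @param residuals a [residual_map()] on the model grid
#' @param model a [fit_pixelwise_model()] result
#' @param z_new the patient's demographics vector (length 6)
#' @param variant `"crawford"`, `"naive"`, or `"literal"`
#' @param t_cap magnitude cap for degenerate pixels (`s = 0`, `R != 0`)
#' @return a `t_map` object: `t` (matrix, zero outside the domain),
#'   `t_values` (vector over domain pixels), `dof`, `variant`, `flagged`
#' @export
t_map <- function(residuals, model, z_new, variant = c("crawford", "naive", "literal"),
                  t_cap = 100) {
  variant <- match.arg(variant)
  z_new <- as_z(z_new)
  if (!all(dim(residuals$data) == dim(model$domain$data)))
    stop("grid mismatch between residual map and model domain")
  r <- residuals$data[model$domain_idx]
  s <- model$residual_sd
  se <- switch(variant,
    crawford = s * sqrt(1 + as.numeric(t(z_new) %*% model$xtx_inv %*% z_new)),
    naive = s,
    literal = s / sqrt(model$n_subjects))
  t_vals <- ifelse(se > 0, r / ifelse(se > 0, se, 1), 0)
  flagged <- which(se == 0 & r != 0)
  t_vals[flagged] <- sign(r[flagged]) * t_cap
  structure(
    list(t = model_image(model, t_vals)$data, t_values = t_vals,
         dof = model$df_resid, variant = variant, flagged = flagged,
         spacing = model$domain$spacing),
    class = "t_map"
  )
}

#' @export
print.t_map <- function(x, ...) {
  cat(sprintf("<t_map> %d pixels, dof = %d, variant = %s, range [%.2f, %.2f]\n",
              length(x$t_values), x$dof, x$variant, min(x$t_values),
              max(x$t_values)))
  invisible(x)
}

#' Estimate residual field smoothness for random field theory
#'
#' FWHM of the effective spatial autocorrelation kernel, estimated from the
#' spatial partial derivatives of the normalized residual fields (each
#' pixel's residual vector scaled to unit sum of squares, the standard
#' resel formulation). The resel count is the domain area divided by
#' `FWHM_x * FWHM_y`, plus boundary terms from the domain perimeter.
#'
#' @param model a `pixelwise_model` with residuals retained
#' @return list with `fwhm` (per-axis and geometric mean, pixels),
#'   `resels` (length-3 resel counts for EC dimensions 0-2), `area_px`,
#'   `perimeter_px`
#' @export
estimate_smoothness <- function(model) {
  dom <- model$domain$data
  idx <- model$domain_idx
  bb <- range(which(rowSums(dom) > 0))
  bb2 <- range(which(colSums(dom) > 0))
  if (diff(bb) + 1 < 4 || diff(bb2) + 1 < 4)
    stop("model domain too small for smoothness estimation (< 4 pixels wide)")
  dm <- dim(dom)
  n <- model$n_subjects
  ss <- sqrt(colSums(model$residual_matrix^2))
  keep <- ss > 0
  # normalized residual fields, one matrix per subject
  lam <- c(0, 0)
  u <- matrix(0, dm[1], dm[2])
  dx_ok <- dom[-dm[1], ] & dom[-1, ]
  dy_ok <- dom[, -dm[2]] & dom[, -1]
  # the residual vectors are normalized to unit sum of squares across
  # subjects, so summing squared derivatives over subjects (not averaging)
  # estimates the derivative variance of a unit-variance field
  for (i in seq_len(n)) {
    u[] <- 0
    u[idx[keep]] <- model$residual_matrix[i, keep] / ss[keep]
    dx <- (u[-1, ] - u[-dm[1], ])[dx_ok]
    dy <- (u[, -1] - u[, -dm[2]])[dy_ok]
    lam <- lam + c(sum(dx^2), sum(dy^2))
  }
  lam <- lam / c(sum(dx_ok), sum(dy_ok))
  fwhm <- sqrt(4 * log(2) / pmax(lam, 1e-12))
  fwhm <- pmax(fwhm, 1)  # cannot resolve smoothness below the pixel size
  area <- length(idx)
  # 4-neighborhood boundary edge count = perimeter in pixel units
  pad <- matrix(FALSE, dm[1] + 2, dm[2] + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1)] <- dom
  perim <- sum(pad & !pad[c(2:nrow(pad), 1), ]) + sum(pad & !pad[c(nrow(pad), 1:(nrow(pad) - 1)), ]) +
    sum(pad & !pad[, c(2:ncol(pad), 1)]) + sum(pad & !pad[, c(ncol(pad), 1:(ncol(pad) - 1))])
  resels <- c(1,
              (perim / 2) / mean(fwhm),
              area / (fwhm[1] * fwhm[2]))
  list(fwhm = c(x = fwhm[1], y = fwhm[2], geometric = sqrt(prod(fwhm))),
       resels = resels, area_px = area, perimeter_px = perim)
}

# Expected Euler characteristic of a thresholded 2D t-field.
ec_expected <- function(t, dof, resels) {
  rho0 <- pt(t, dof, lower.tail = FALSE)
  base <- (1 + t^2 / dof)^(-(dof - 1) / 2)
  rho1 <- sqrt(4 * log(2)) / (2 * pi) * base
  rho2 <- (4 * log(2)) / (2 * pi)^1.5 *
    exp(lgamma((dof + 1) / 2) - lgamma(dof / 2)) / sqrt(dof / 2) * t * base
  resels[1] * rho0 + resels[2] * rho1 + resels[3] * rho2
}

#' Random-field-theory threshold and cluster extraction
#'
#' Solves for the critical t at which the expected Euler characteristic of
#' the thresholded t-field equals the significance level (two-sided by
#' default: `alpha/2` per tail), zeroes sub-threshold pixels, and extracts
#' 8-connected suprathreshold clusters with sign, extent and peak.
#'
#' @param tmap a [t_map()]
#' @param smoothness result of [estimate_smoothness()] (or a list with
#'   elements `fwhm` and `resels`)
#' @param alpha family-wise significance level (default 0.05)
#' @param two_sided test both tails (default TRUE)
#' @return an `abnormality_map`: `thresholded_t`, `critical_t`, `clusters`
#'   (tibble: id, sign, extent_px, peak_t, peak_p), `fwhm`, `resels`
#' @export
rft_threshold <- function(tmap, smoothness, alpha = 0.05, two_sided = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (tmap$dof < 1) stop("degrees of freedom must be >= 1")
  resels <- smoothness$resels
  if (resels[3] <= 0) stop("resel count must be positive")
  target <- if (two_sided) alpha / 2 else alpha
  f <- function(t) ec_expected(t, tmap$dof, resels) - target
  crit <- if (f(1) <= 0) {
    1
  } else if (f(1000) > 0) {
    # with very few degrees of freedom the t-field EC density has tails too
    # heavy for any finite threshold to reach alpha
    warning("no finite RFT threshold controls alpha at ", tmap$dof,
            " degrees of freedom; all pixels are sub-threshold")
    Inf
  } else {
    uniroot(f, c(1, 1000), tol = 1e-8)$root
  }
  thr <- tmap$t
  keep <- if (two_sided) abs(thr) >= crit else thr >= crit
  thr[!keep] <- 0
  clusters <- extract_clusters(thr, crit, tmap$dof, resels, two_sided)
  structure(
    list(thresholded_t = thr, critical_t = crit, clusters = clusters,
         fwhm = smoothness$fwhm, resels = resels, alpha = alpha,
         two_sided = two_sided, dof = tmap$dof, spacing = tmap$spacing,
         stationarity_note = paste("stationary-field EC densities assumed;",
                                   "approximate on non-stationary lattices")),
    class = "abnormality_map"
  )
}

# 8-connected component labelling of a logical matrix (iterative BFS).
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- matrix(0L, dm[1], dm[2])
  cur <- 0L
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      k <- queue[[1]]
      queue <- queue[-1]
      i <- (k - 1L) %% dm[1] + 1L
      j <- (k - 1L) %/% dm[1] + 1L
      ni <- i + offs$di
      nj <- j + offs$dj
      ok <- ni >= 1 & ni <= dm[1] & nj >= 1 & nj <= dm[2]
      nk <- (nj[ok] - 1L) * dm[1] + ni[ok]
      nk <- nk[mask[nk] & lab[nk] == 0L]
      lab[nk] <- cur
      queue <- c(queue, nk)
    }
  }
  lab
}

extract_clusters <- function(thr, crit, dof, resels, two_sided) {
  out <- list()
  for (sgn in c(1, -1)) {
    m <- if (sgn > 0) thr >= crit else thr <= -crit
    if (!any(m)) next
    lab <- label_components(m)
    for (id in seq_len(max(lab))) {
      px <- which(lab == id)
      peak <- max(abs(thr[px]))
      peak_p <- min(1, (if (two_sided) 2 else 1) * ec_expected(peak, dof, resels))
      out[[length(out) + 1]] <- tibble::tibble(
        sign = sgn, extent_px = length(px), peak_t = sgn * peak,
        peak_p = peak_p, pixels = list(px))
    }
  }
  if (!length(out))
    return(tibble::tibble(id = integer(), sign = numeric(),
                          extent_px = integer(), peak_t = numeric(),
                          peak_p = numeric(), pixels = list()))
  cl <- do.call(rbind, out)
  cl <- cl[order(-cl$extent_px), ]
  tibble::tibble(id = seq_len(nrow(cl)), cl)
}

#' @export
print.abnormality_map <- function(x, ...) {
  cat(sprintf("<abnormality_map> critical |t| = %.2f (alpha %g%s), %d suprathreshold px in %d cluster(s)\n",
              x$critical_t, x$alpha, if (x$two_sided) ", two-sided" else "",
              sum(x$thresholded_t != 0), nrow(x$clusters)))
  invisible(x)
}

#' @export
glance.abnormality_map <- function(x, ...) {
  tibble::tibble(
    critical_t = x$critical_t, alpha = x$alpha, two_sided = x$two_sided,
    n_suprathreshold = sum(x$thresholded_t != 0),
    n_clusters = nrow(x$clusters),
    fwhm_px = unname(x$fwhm["geometric"]), resels = x$resels[3]
  )
}

#' Anatomical region mask on the template grid
#'
#' Partitions the template silhouette into five merged regions -- heel,
#' midfoot, metatarsal 1, metatarsals 2-5, toes -- using fractional bands
#' of foot length along the anterior-posterior axis, with a medial split of
#' the metatarsal band for MT1. The band fractions follow standard
#' pedobarographic masking conventions and are configurable.
#'
#' @param template a `template_result` or [silhouette_mask()]
#' @param bands cumulative band upper bounds as fractions of foot length
#'   (heel, midfoot, metatarsals; toes take the rest)
#' @param mt1_width_frac medial fraction of forefoot width assigned to MT1
#' @param medial which column side is medial on a left foot (`"high"` is
#'   the package's left-foot convention)
#' @return a `region_mask`: integer label matrix plus region names
#' @export
build_region_mask <- function(template, bands = c(heel = 0.31, midfoot = 0.55,
                                                  metatarsal = 0.81),
                              mt1_width_frac = 0.36,
                              medial = c("high", "low")) {
  medial <- match.arg(medial)
  sil <- if (inherits(template, "template_result")) template$silhouette else template
  if (!any(sil$data)) stop("cannot build regions: silhouette is empty")
  dom <- sil$data
  rows <- range(which(rowSums(dom) > 0))
  len <- diff(rows) + 1
  # heel at low row index, toes at high row index
  cuts <- rows[1] + len * c(bands, toes = 1)
  labels <- matrix(0L, nrow(dom), ncol(dom))
  region_names <- c("heel", "midfoot", "MT1", "MT2_5", "toes")
  idx <- which(dom, arr.ind = TRUE)
  frac_row <- idx[, 1]
  band <- findInterval(frac_row, cuts[1:3], left.open = TRUE) + 1L
  lab <- integer(nrow(idx))
  lab[band == 1] <- 1L  # heel
  lab[band == 2] <- 2L  # midfoot
  lab[band == 4] <- 5L  # toes
  mt <- band == 3
  if (any(mt)) {
    cols <- range(idx[mt, 2])
    width <- diff(cols) + 1
    if (medial == "high") {
      mt1_cut <- cols[2] - mt1_width_frac * width
      lab[mt] <- ifelse(idx[mt, 2] > mt1_cut, 3L, 4L)
    } else {
      mt1_cut <- cols[1] + mt1_width_frac * width
      lab[mt] <- ifelse(idx[mt, 2] < mt1_cut, 3L, 4L)
    }
  }
  labels[idx] <- lab
  structure(list(labels = labels, region_names = region_names,
                 spacing = sil$spacing, medial = medial, bands = bands,
                 mt1_width_frac = mt1_width_frac),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  counts <- table(factor(x$labels[x$labels > 0], levels = 1:5,
                         labels = x$region_names))
  cat("<region_mask> px per region:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Classify an abnormality map into region patterns
#'
#' A pattern flag is raised when a significant cluster overlaps its region
#' by at least `min_overlap_px` pixels. The MT1 and midfoot (pes planus)
#' patterns require pressure increases (positive clusters); toes, MT2-5 and
#' heel accept either sign. "No abnormality" is true exactly when no flag
#' is raised.
#'
#' @param abmap an [rft_threshold()] result
#' @param regions a [build_region_mask()] result on the same grid
#' @param min_overlap_px minimum cluster-region overlap (default 4)
#' @return a `pattern_report`: named logical `patterns`, `no_abnormality`,
#'   and an `overlaps` tibble (cluster x region signed overlaps)
#' @export
classify_patterns <- function(abmap, regions, min_overlap_px = 4) {
  stopifnot(all(dim(abmap$thresholded_t) == dim(regions$labels)))
  flags <- c(mt1_increase = FALSE, toes_abnormal = FALSE,
             midfoot_increase = FALSE, mt2_5_abnormal = FALSE,
             heel_abnormal = FALSE)
  overlaps <- list()
  cl <- abmap$clusters
  for (k in seq_len(nrow(cl))) {
    px <- cl$pixels[[k]]
    regs <- regions$labels[px]
    for (r in setdiff(unique(regs), 0L)) {
      ov <- sum(regs == r)
      overlaps[[length(overlaps) + 1]] <- tibble::tibble(
        cluster = cl$id[k], region = regions$region_names[r],
        sign = cl$sign[k], overlap_px = ov)
      if (ov >= min_overlap_px) {
        rn <- regions$region_names[r]
        if (rn == "MT1" && cl$sign[k] > 0) flags["mt1_increase"] <- TRUE
        if (rn == "toes") flags["toes_abnormal"] <- TRUE
        if (rn == "midfoot" && cl$sign[k] > 0) flags["midfoot_increase"] <- TRUE
        if (rn == "MT2_5") flags["mt2_5_abnormal"] <- TRUE
        if (rn == "heel") flags["heel_abnormal"] <- TRUE
      }
    }
  }
  overlaps <- if (length(overlaps)) do.call(rbind, overlaps)
              else tibble::tibble(cluster = integer(), region = character(),
                                  sign = numeric(), overlap_px = integer())
  structure(list(patterns = flags, no_abnormality = !any(flags),
                 overlaps = overlaps, min_overlap_px = min_overlap_px),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  on <- names(x$patterns)[x$patterns]
  cat("<pattern_report>",
      if (x$no_abnormality) "no abnormality" else paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.pattern_report <- function(x, ...) {
  tibble::tibble(!!!as.list(x$patterns), no_abnormality = x$no_abnormality)
}

#' End-to-end personalized analysis of one patient's pressures
#'
#' Runs the full single-case workflow: preprocess a pressure video (square
#' resampling, total-mean-pressure normalization, peak image) or take a
#' prepared peak image; predict the personalized baseline from the model;
#' rigidly and deformably align the patient image to the prediction;
#' compute residuals, the single-case t-map, the random-field-theory
#' threshold; and classify region patterns. An alignment Dice below
#' `dice_floor` flags the result as unreliable (severe deformity can defeat
#' the registration, making pixel correspondence meaningless).
#'
#' @param patient a [pressure_video()] or peak [pressure_image()]
#' @param z_new the patient's demographics (vector or 1-row data frame)
#' @param model a fitted `pixelwise_model`
#' @param regions optional [build_region_mask()] result for pattern
#'   classification
#' @param variant t-statistic variant (see [t_map()])
#' @param alpha significance level (default 0.05)
#' @param two_sided two-sided testing (default TRUE)
#' @param silhouette_threshold threshold for alignment silhouettes, in the
#'   image's pressure units
#' @param dice_floor minimum acceptable alignment Dice (default 0.85)
#' @param register set `FALSE` if the patient image is already on the
#'   template grid (e.g. simulation studies)
#' @param normalize_video divide video input by its total mean pressure
#' @param seed seed for the registration optimizer
#' @param smoothness optional precomputed [estimate_smoothness()] result
#' @return a `patient_analysis` list: `abnormality`, `patterns`, `qc`,
#'   plus the intermediate images (`measured`, `predicted`, `aligned`,
#'   `residuals`, `tmap`)
#' @export
analyze_patient <- function(patient, z_new, model, regions = NULL,
                            variant = "crawford", alpha = 0.05,
                            two_sided = TRUE, silhouette_threshold = 5,
                            dice_floor = 0.85, register = TRUE,
                            normalize_video = TRUE, seed = 0,
                            smoothness = NULL) {
  z_new <- as_z(z_new)
  img <- patient
  if (inherits(patient, "pressure_video")) {
    v <- patient
    if (!is_isotropic(v) ||
        !isTRUE(all.equal(v$spacing[1], model$domain$spacing[1])))
      v <- resample_square(v, model$domain$spacing[1])
    if (normalize_video) v <- normalize_video(v)
    img <- peak_pressure_image(v)
  }
  if (!is.na(img$side) && identical(img$side, "right")) img <- flip_to_left(img)
  predicted <- predict_pressures(model, z_new)
  dm <- dim(model$domain$data)
  img <- conform_grid(img, predicted)
  rigid <- NULL
  field <- NULL
  if (register) {
    cfg <- es_config(seed = seed)
    rigid <- rigid_register(img, predicted, cfg)
    warped <- apply_transform(img, rigid, out_dim = dm)
    field <- demons_register(compute_silhouette(warped, silhouette_threshold),
                             compute_silhouette(predicted, silhouette_threshold))
    aligned <- apply_transform(img, rigid, field, out_dim = dm)
  } else {
    aligned <- img
  }
  d <- dice(compute_silhouette(aligned, silhouette_threshold),
            compute_silhouette(predicted, silhouette_threshold))
  unreliable <- d < dice_floor
  if (unreliable)
    warning(sprintf("alignment Dice %.3f below floor %.2f: result flagged unreliable",
                    d, dice_floor))
  resid <- residual_map(aligned, predicted, model$domain)
  tm <- t_map(resid, model, z_new, variant = variant)
  if (is.null(smoothness)) smoothness <- estimate_smoothness(model)
  abmap <- rft_threshold(tm, smoothness, alpha = alpha, two_sided = two_sided)
  patterns <- if (!is.null(regions)) classify_patterns(abmap, regions) else NULL
  structure(
    list(abnormality = abmap, patterns = patterns,
         qc = list(dice = d, unreliable = unreliable,
                   n_clamped = attr(predicted, "n_clamped"),
                   registered = register,
                   mi = if (!is.null(rigid)) attr(rigid, "mi") else NA_real_,
                   jacobian_min = if (!is.null(field)) field$jacobian_min
                                  else NA_real_),
         measured = img, predicted = predicted, aligned = aligned,
         residuals = resid, tmap = tm, rigid = rigid, field = field),
    class = "patient_analysis"
  )
}

#' @export
print.patient_analysis <- function(x, ...) {
  cat(sprintf("<patient_analysis> dice %.3f%s, critical |t| %.2f, %d cluster(s)\n",
              x$qc$dice, if (x$qc$unreliable) " (UNRELIABLE)" else "",
              x$abnormality$critical_t, nrow(x$abnormality$clusters)))
  if (!is.null(x$patterns)) print(x$patterns)
  invisible(x)
}

#' @export
glance.patient_analysis <- function(x, ...) {
  base <- tibble::tibble(dice = x$qc$dice, unreliable = x$qc$unreliable,
                         critical_t = x$abnormality$critical_t,
                         n_clusters = nrow(x$abnormality$clusters),
                         n_suprathreshold = sum(x$abnormality$thresholded_t != 0))
  if (!is.null(x$patterns)) base <- cbind(base, tidy(x$patterns))
  tibble::as_tibble(base)
}
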