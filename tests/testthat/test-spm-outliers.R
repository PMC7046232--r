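test_that("residual maps subtract prediction inside the domain only", {
  m <- fixture_model()
  z <- demographics_vector(40, 1, 75, 175, 42)
  pred <- predict_pressures(m, z)
  expect_true(all(residual_map(pred, pred, m$domain)$data == 0))
  zero <- pred
  zero$data[] <- 0
  r <- residual_map(pred, zero, m$domain)
  expect_equal(r$data[m$domain_idx], pred$data[m$domain_idx])
  expect_true(all(r$data[-m$domain_idx] == 0))
  # random pair equals the element-wise oracle
  pat <- null_patient(m, z, seed = 1)
  r2 <- residual_map(pat, pred, m$domain)
  oracle <- (pat$data - pred$data)
  oracle[!m$domain$data] <- 0
  expect_equal(r2$data, oracle, tolerance = 1e-15)
  bad <- pressure_image(matrix(0, 3, 3), spacing = 3)
  expect_error(residual_map(bad, pred), "grid mismatch")
})

test_that("t-map variants match their scalar formulas exactly", {
  m <- fixture_model()
  z <- demographics_vector(35, 0, 62, 160, 37)
  pat <- null_patient(m, z, seed = 2)
  pred <- predict_pressures(m, z)
  r <- residual_map(pat, pred, m$domain)
  rv <- r$data[m$domain_idx]
  s <- m$residual_sd
  lev <- as.numeric(t(as_z <- plantarmap:::as_z(z)) %*% m$xtx_inv %*% as_z)
  for (variant in c("crawford", "naive", "literal")) {
    tm <- t_map(r, m, z, variant = variant)
    oracle <- switch(variant,
      crawford = rv / (s * sqrt(1 + lev)),
      naive = rv / s,
      literal = rv / (s / sqrt(m$n_subjects)))
    expect_equal(tm$t_values, oracle, tolerance = 1e-12)
    expect_equal(tm$dof, m$n_subjects - 6)
  }
  # the leverage form is strictly smaller in magnitude than the naive form
  t_cr <- t_map(r, m, z, variant = "crawford")$t_values
  t_na <- t_map(r, m, z, variant = "naive")$t_values
  nz <- abs(t_na) > 1e-12
  expect_true(all(abs(t_cr[nz]) < abs(t_na[nz])))
  # zero residuals give a zero map for every variant
  r0 <- residual_map(pred, pred, m$domain)
  expect_true(all(t_map(r0, m, z)$t_values == 0))
  # positive t means measured above the personalized baseline
  up <- pred
  up$data[m$domain_idx[10]] <- up$data[m$domain_idx[10]] + 5
  expect_gt(t_map(residual_map(up, pred, m$domain), m, z)$t_values[10], 0)
})

test_that("degenerate pixels (s = 0) are capped and flagged", {
  m <- fixture_model()
  m$residual_sd[3] <- 0
  z <- demographics_vector(40, 1, 75, 175, 42)
  pred <- predict_pressures(m, z)
  up <- pred
  up$data[m$domain_idx[3]] <- up$data[m$domain_idx[3]] + 1
  tm <- t_map(residual_map(up, pred, m$domain), m, z, t_cap = 50)
  expect_equal(tm$t_values[3], 50)
  expect_equal(tm$flagged, 3L)
  # s = 0 with R = 0 stays 0
  tm0 <- t_map(residual_map(pred, pred, m$domain), m, z)
  expect_equal(tm0$t_values[3], 0)
})

test_that("smoothness estimation tracks the true noise correlation", {
  m <- fixture_model()
  sm <- estimate_smoothness(m)
  # generator noise has FWHM 2 px; estimate within +/- 20%
  expect_gt(sm$fwhm["geometric"], 2 * 0.8)
  expect_lt(sm$fwhm["geometric"], 2 * 1.2)
  expect_equal(sm$resels[3], sm$area_px / (sm$fwhm[1] * sm$fwhm[2]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # white-noise residuals sit near the 1-px lower bound
  coh <- fixture_cohort()
  spec_w <- cohort_spec(n_subjects = 20, k_repeats = 1, noise_fwhm_px = 1,
                        rot_range_deg = c(0, 0), trans_range_mm = c(0, 0),
                        right_fraction = 0, seed = 77)
  coh_w <- generate_cohort(spec_w)
  m_w <- fit_pixelwise_model(lapply(coh_w$feet, function(f) f$images[[1]]),
                             coh_w$demographics,
                             compute_silhouette(coh_w$truth$reference, 5))
  expect_lt(estimate_smoothness(m_w)$fwhm["geometric"], 1.5)

  # a larger domain at fixed smoothness carries proportionally more resels
  half <- m$domain
  rows_on <- which(rowSums(half$data) > 0)
  half$data[rows_on[seq_len(floor(length(rows_on) / 2))], ] <- FALSE
  m_half <- m
  m_half$domain <- half
  keep <- m$domain$data[m$domain_idx] & half$data[m$domain_idx]
  m_half$domain_idx <- which(half$data)
  sel <- match(m_half$domain_idx, m$domain_idx)
  m_half$residual_matrix <- m$residual_matrix[, sel]
  m_half$residual_sd <- m$residual_sd[sel]
  sm_half <- estimate_smoothness(m_half)
  expect_equal(sm$resels[3] / sm_half$resels[3],
               sm$area_px / sm_half$area_px, tolerance = 0.25)
})

test_that("random-field thresholding is monotone and conservative on nulls", {
  m <- fixture_model()
  sm <- fixture_smoothness()
  z <- demographics_vector(40, 1, 75, 175, 42)
  pred <- predict_pressures(m, z)
  tm <- t_map(residual_map(pred, pred, m$domain), m, z)
  ab <- rft_threshold(tm, sm)
  expect_equal(nrow(ab$clusters), 0L)
  expect_true(all(ab$thresholded_t == 0))
  # critical t decreases with alpha, increases with resels
  crits_a <- vapply(c(0.01, 0.05, 0.2),
                    function(a) rft_threshold(tm, sm, alpha = a)$critical_t, 0)
  expect_true(all(diff(crits_a) < 0))
  sm_big <- sm
  sm_big$resels <- sm$resels * c(1, 2, 4)
  expect_gt(rft_threshold(tm, sm_big)$critical_t, ab$critical_t)
  expect_error(rft_threshold(tm, sm, alpha = 1.2), "alpha")
})

test_that("thresholding only removes pixels and clusters partition the rest", {
  m <- fixture_model()
  sm <- fixture_smoothness()
  z <- demographics_vector(40, 1, 75, 175, 42)
  ctr <- fixture_cohort()$truth$blob_centers_px
  pat <- null_patient(m, z, seed = 5)
  pat <- inject_abnormality(pat, ctr["MT1", ], 4, 8, m)
  pat <- inject_abnormality(pat, ctr["heel", ], 3, -8, m)
  tm <- t_map(residual_map(pat, predict_pressures(m, z), m$domain), m, z)
  ab <- rft_threshold(tm, sm)
  nz <- which(ab$thresholded_t != 0)
  expect_true(all(abs(ab$thresholded_t[nz]) >= ab$critical_t))
  expect_true(all(ab$thresholded_t[nz] == tm$t[nz]))
  # cluster extents sum to the suprathreshold pixel count; pixels disjoint
  expect_equal(sum(ab$clusters$extent_px), length(nz))
  allpx <- unlist(ab$clusters$pixels)
  expect_equal(sort(allpx), sort(nz))
  expect_true(any(ab$clusters$sign > 0) && any(ab$clusters$sign < 0))
})

test_that("region mask partitions the silhouette with MT1 on the medial side", {
  m <- fixture_model()
  rg <- fixture_regions()
  expect_equal(sum(rg$labels > 0), sum(m$domain$data))
  expect_true(all(rg$labels[!m$domain$data] == 0))
  coh <- fixture_cohort()
  ctr <- round(coh$truth$blob_centers_px)
  lab_at <- function(locus) rg$labels[ctr[locus, 1], ctr[locus, 2]]
  expect_equal(rg$region_names[lab_at("heel")], "heel")
  expect_equal(rg$region_names[lab_at("midfoot")], "midfoot")
  expect_equal(rg$region_names[lab_at("MT1")], "MT1")
  expect_equal(rg$region_names[lab_at("MT3")], "MT2_5")
  expect_equal(rg$region_names[lab_at("toes2_5")], "toes")
  expect_equal(rg$region_names[lab_at("hallux")], "toes")

  # mirroring the silhouette mirrors the MT1 region to the opposite side
  sil_m <- m$domain
  sil_m$data <- sil_m$data[, rev(seq_len(ncol(sil_m$data)))]
  rg_m <- build_region_mask(sil_m, medial = "low")
  expect_equal(rg_m$labels[, rev(seq_len(ncol(rg_m$labels)))], rg$labels)
  expect_error(build_region_mask(silhouette_mask(matrix(0, 5, 5), 3)),
               "empty")
})

test_that("pattern classification follows region overlap and sign rules", {
  m <- fixture_model()
  sm <- fixture_smoothness()
  rg <- fixture_regions()
  z <- demographics_vector(40, 1, 75, 175, 42)
  pred <- predict_pressures(m, z)
  # empty abnormality map: no abnormality
  ab0 <- rft_threshold(t_map(residual_map(pred, pred, m$domain), m, z), sm)
  rep0 <- classify_patterns(ab0, rg)
  expect_true(rep0$no_abnormality)
  expect_false(any(rep0$patterns))

  # a strong positive MT1 blob raises only the MT1 flag
  coh <- fixture_cohort()
  ctr <- coh$truth$blob_centers_px
  pat <- inject_abnormality(pred, ctr["MT1", ], 3.2, 10, m)
  ab1 <- rft_threshold(t_map(residual_map(pat, pred, m$domain), m, z), sm)
  rep1 <- classify_patterns(ab1, rg)
  expect_true(rep1$patterns["mt1_increase"])
  expect_false(rep1$patterns["heel_abnormal"])
  expect_false(rep1$no_abnormality)

  # a negative MT1 blob must NOT raise the increase-only MT1 flag
  pat_n <- inject_abnormality(pred, ctr["MT1", ], 3.2, -10, m)
  ab2 <- rft_threshold(t_map(residual_map(pat_n, pred, m$domain), m, z), sm)
  rep2 <- classify_patterns(ab2, rg)
  expect_false(rep2$patterns["mt1_increase"])

  # a cluster straddling heel and midfoot raises both flags
  hc <- ctr["heel", ]
  mc <- ctr["midfoot", ]
  pat3 <- pred
  for (f in seq(0, 1, by = 0.1)) {
    c_px <- round(hc + f * (mc - hc))
    pat3 <- inject_abnormality(pat3, c_px, 3, 10, m)
  }
  ab3 <- rft_threshold(t_map(residual_map(pat3, pred, m$domain), m, z), sm)
  rep3 <- classify_patterns(ab3, rg)
  expect_true(rep3$patterns["heel_abnormal"])
  expect_true(rep3$patterns["midfoot_increase"])
  expect_equal(tidy(rep3)$no_abnormality, FALSE)
})

test_that("analyze_patient is self-consistent and flags misalignment", {
  m <- fixture_model()
  rg <- fixture_regions()
  z <- demographics_vector(40, 1, 75, 175, 42)
  pred <- predict_pressures(m, z)
  res <- analyze_patient(pred, z, m, regions = rg, register = FALSE)
  expect_true(res$patterns$no_abnormality)
  expect_equal(sum(res$abnormality$thresholded_t != 0), 0)
  expect_false(res$qc$unreliable)

  # a patient that cannot be aligned is flagged unreliable
  junk <- pressure_image(matrix(c(100, rep(0, 8)), 3, 3), spacing = 3)
  expect_warning(
    res_bad <- analyze_patient(junk, z, m, regions = rg, register = FALSE),
    "unreliable")
  expect_true(res_bad$qc$unreliable)
})

test_that("the full single-case workflow detects a strong injected deficit", {
  m <- fixture_model()
  rg <- fixture_regions()
  coh <- fixture_cohort()
  z <- demographics_vector(44, 0, 68, 168, 39)
  pat <- null_patient(m, z, seed = 9)
  pat <- inject_abnormality(pat, coh$truth$blob_centers_px["hallux", ], 3, -9, m)
  # misalign the patient; the pipeline must register it back
  tr <- rigid_transform2d(0.05, c(4, -5), center_of_pressure(pat))
  pat_m <- apply_transform(pat, tr)
  res <- analyze_patient(pat_m, z, m, regions = rg, seed = 4)
  expect_gte(res$qc$dice, 0.85)
  expect_true(any(res$abnormality$clusters$sign < 0))
  expect_true(res$patterns$patterns["toes_abnormal"])
})
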