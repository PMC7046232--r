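make_design <- function(n, seed = 1) {
  with_seed(seed, tibble::tibble(
    age = runif(n, 20, 60), sex = as.numeric(runif(n) < 0.5),
    weight = runif(n, 55, 95), height = runif(n, 155, 195),
    shoe_size = sample(36:46, n, replace = TRUE)
  ))
}

test_that("design matrix uses the fixed covariate order and sex coding", {
  d <- tibble::tibble(age = 30, sex = "female", weight = 60, height = 165,
                      shoe_size = 38)
  z <- design_matrix(d)
  expect_equal(colnames(z),
               c("age", "sex", "weight", "height", "shoe_size", "intercept"))
  expect_equal(as.numeric(z), c(30, 0, 60, 165, 38, 1))
  expect_equal(design_matrix(transform(d, sex = "M"))[, "sex"], 1,
               ignore_attr = TRUE)
  expect_error(design_matrix(transform(d, sex = 2)), "sex")
  expect_error(design_matrix(d[, -1]), "age")
})

test_that("noiseless data are recovered exactly, matching the OLS oracle", {
  n <- 12
  demo <- make_design(n)
  z <- design_matrix(demo)
  dm <- c(6, 5)
  domain <- silhouette_mask(matrix(TRUE, dm[1], dm[2]), spacing = 3)
  b_true <- with_seed(2, matrix(rnorm(6 * prod(dm), 0, 0.5), 6))
  y <- z %*% b_true
  imgs <- lapply(seq_len(n), function(i)
    pressure_image(matrix(y[i, ], dm[1], dm[2]), spacing = 3))
  m <- fit_pixelwise_model(imgs, demo, domain)
  expect_lt(max(abs(m$coefficients - b_true)), 1e-8)
  expect_lt(max(m$residual_sd), 1e-8)
  # residuals sum to zero per pixel (intercept in the design)
  expect_lt(max(abs(colSums(m$residual_matrix))), 1e-8)
})

test_that("per-pixel solutions equal the normal-equations oracle", {
  n <- 30
  demo <- make_design(n, seed = 3)
  z <- design_matrix(demo)
  dm <- c(5, 4)
  domain <- silhouette_mask(matrix(TRUE, dm[1], dm[2]), spacing = 3)
  y <- with_seed(4, matrix(rnorm(n * prod(dm), 100, 20), n))
  imgs <- lapply(seq_len(n), function(i)
    pressure_image(matrix(y[i, ], dm[1], dm[2]), spacing = 3))
  m <- fit_pixelwise_model(imgs, demo, domain)
  oracle <- solve(crossprod(z)) %*% t(z) %*% y
  expect_equal(m$coefficients, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  # residual orthogonality to every design column
  ortho <- abs(t(z) %*% m$residual_matrix) / sqrt(colSums(z^2))
  expect_lt(max(ortho), 1e-6)
  # residual_sd^2 is the stated sample variance of the stored residuals
  expect_equal(m$residual_sd^2,
               colSums(m$residual_matrix^2) / (n - 6), tolerance = 1e-12)
})

test_that("degenerate designs fail loudly", {
  demo <- make_design(10)
  demo$sex <- 1  # collinear with the intercept
  dm <- c(3, 3)
  domain <- silhouette_mask(matrix(TRUE, 3, 3), spacing = 3)
  imgs <- lapply(1:10, function(i)
    pressure_image(matrix(runif(9), 3, 3), spacing = 3))
  expect_error(fit_pixelwise_model(imgs, demo, domain), "sex|intercept")
  expect_error(fit_pixelwise_model(imgs[1:6], make_design(6), domain),
               "more subjects than regressors")
})

test_that("prediction reproduces exact fits and is linear in demographics", {
  m <- fixture_model()
  coh <- fixture_cohort()
  z1 <- design_matrix(coh$demographics)[3, ]
  z2 <- design_matrix(coh$demographics)[7, ]
  p1 <- predict_pressures(m, z1)
  p2 <- predict_pressures(m, z2)
  a <- 0.3
  pz <- predict_pressures(m, a * z1 + (1 - a) * z2)
  lin <- a * p1$data + (1 - a) * p2$data
  # linearity holds wherever the non-negativity clamp did not fire
  raw <- function(z) as.numeric(z %*% m$coefficients)
  unclamped <- raw(z1) > 0 & raw(z2) > 0 & raw(a * z1 + (1 - a) * z2) > 0
  expect_equal(pz$data[m$domain_idx][unclamped],
               lin[m$domain_idx][unclamped], tolerance = 1e-9)
  # prediction at the mean demographics equals the mean training image
  zbar <- colMeans(m$design)
  pbar <- predict_pressures(m, zbar)
  ybar <- Reduce(`+`, lapply(coh$feet, function(f) f$images[[1]]$data)) /
    length(coh$feet)
  expect_equal(pbar$data[m$domain_idx], ybar[m$domain_idx], tolerance = 1e-8)
  # extrapolation warns but still predicts
  expect_warning(predict_pressures(m, demographics_vector(95, 1, 80, 180, 43)),
                 "extrapolat")
})

test_that("exact noiseless interpolation reproduces a training subject", {
  n <- 10
  demo <- make_design(n, seed = 5)
  z <- design_matrix(demo)
  dm <- c(4, 4)
  domain <- silhouette_mask(matrix(TRUE, 4, 4), spacing = 3)
  b_true <- with_seed(6, matrix(runif(6 * 16, 0, 2), 6))
  y <- z %*% b_true
  imgs <- lapply(seq_len(n), function(i)
    pressure_image(matrix(y[i, ], 4, 4), spacing = 3))
  m <- fit_pixelwise_model(imgs, demo, domain)
  pred <- predict_pressures(m, z[4, ])
  expect_equal(pred$data, imgs[[4]]$data, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("normality diagnostics are calibrated and detect skewed pixels", {
  m <- fixture_model()
  rep0 <- check_normality(m)
  # correctly specified model: essentially nothing survives FDR
  expect_lte(rep0$fraction_rejected, 0.01)

  # replace one pixel's residuals by a (positive, skewed) exponential sample
  m2 <- m
  hits <- 0
  for (k in 1:10) {
    m2$residual_matrix[, 17] <- with_seed(70 + k, rexp(m$n_subjects)) *
      m$residual_sd[17] * 3
    m2$residual_sd[17] <- sqrt(sum(m2$residual_matrix[, 17]^2) / m$df_resid)
    rep1 <- check_normality(m2)
    if (rep1$rejected[m$domain_idx[17]]) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # degenerate perfect fit gets p = 1 and a flag
  m3 <- m
  m3$residual_matrix[, 5] <- 0
  m3$residual_sd[5] <- 0
  rep3 <- check_normality(m3)
  expect_equal(rep3$p_values[5], 1)
  expect_true(rep3$degenerate[5])
})

test_that("tidy and glance summarize the fitted model", {
  m <- fixture_model()
  td <- tidy(m)
  expect_equal(td$term,
               c("age", "sex", "weight", "height", "shoe_size", "intercept"))
  gl <- glance(m)
  expect_equal(gl$n_subjects, m$n_subjects)
  expect_equal(gl$n_pixels, length(m$domain_idx))
})

test_that("models persist to disk and reload with identical statistics", {
  m <- fixture_model()
  dir <- withr::local_tempdir()
  write_pixelwise_model(m, dir)
  m2 <- read_pixelwise_model(dir)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(m2$residual_sd, m$residual_sd, tolerance = 1e-6)
  expect_equal(m2$n_subjects, m$n_subjects)
  z <- demographics_vector(45, 0, 70, 170, 39)
  expect_equal(predict_pressures(m2, z)$data, predict_pressures(m, z)$data,
               tolerance = 1e-5)
})
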