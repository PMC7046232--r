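# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A small, fast synthetic foot (kPa peak image, left-oriented).
small_foot <- function(seed = 1, noise_sd = 10) {
  spec <- cohort_spec(noise_sd = noise_sd, seed = seed)
  generate_foot_image(foot_phenotype(), demographics_vector(40, 1, 80, 180, 43),
                      spec, seed = seed)
}

# Aligned cohort (no misalignment, K = 1) plus fitted pixel-wise model.
fixture_cohort <- function() fixture("cohort", function() {
  spec <- cohort_spec(n_subjects = 40, k_repeats = 1,
                      rot_range_deg = c(0, 0), trans_range_mm = c(0, 0),
                      right_fraction = 0, seed = 42)
  generate_cohort(spec)
})

fixture_model <- function() fixture("model", function() {
  coh <- fixture_cohort()
  domain <- compute_silhouette(coh$truth$reference, 5)
  fit_pixelwise_model(lapply(coh$feet, function(f) f$images[[1]]),
                      coh$demographics, domain,
                      template = coh$truth$reference)
})

fixture_smoothness <- function() fixture("smoothness", function() {
  estimate_smoothness(fixture_model())
})

fixture_regions <- function() fixture("regions", function() {
  build_region_mask(fixture_model()$domain)
})

# Draw a null patient image from the fitted model at demographics z
# (spatially smooth noise matching the generator's noise structure).
null_patient <- function(model, z, seed, noise_fwhm_px = 2) {
  pred <- predict_pressures(model, z)
  s_map <- matrix(0, nrow(pred$data), ncol(pred$data))
  s_map[model$domain_idx] <- model$residual_sd
  with_seed(seed, {
    e <- matrix(rnorm(length(pred$data)), nrow(pred$data))
    sigma <- noise_fwhm_px / (2 * sqrt(2 * log(2)))
    e <- plantarmap:::cpp_gauss_smooth(e, sigma)
    e <- e / sd(as.numeric(e))
    pred$data <- pmax(pred$data + e * s_map, 0)
  })
  pred
}

with_seed <- plantarmap:::with_seed
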