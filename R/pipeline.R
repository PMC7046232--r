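#' Pipeline run configuration
#'
#' Collects every tunable of the modelling and testing pipeline with its
#' default. The resolved configuration is written next to each stage's
#' outputs so that runs are reproducible from (inputs, config, seed).
#'
#' @param ... overrides of the defaults
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  defaults <- list(
    tau_kpa = 5,                 # loading threshold for mean image / silhouettes
    target_mm = 3,               # square grid spacing
    silhouette_threshold = 5,    # silhouette cutoff, kPa
    mi_bins = 50,                # mutual information histogram bins
    es_init_step_deg = 2, es_init_step_mm = 4,
    es_grow = 1.05, es_shrink = 0.98, es_max_iter = 500,
    lambda1 = 2, lambda2 = 2,    # demons coupling / smoothness weights
    demons_sigma_px = 1.5,
    template_max_iter = 10, template_tol = 1e-3,
    alpha = 0.05, two_sided = TRUE,
    t_variant = "crawford",
    dice_floor = 0.85,
    region_bands = c(heel = 0.31, midfoot = 0.55, metatarsal = 0.81),
    mt1_width_frac = 0.36,
    min_overlap_px = 4,
    seed = 0
  )
  modifyList(defaults, list(...))
}

#' @rdname run_config
#' @param path YAML or JSON config file
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$region_bands)) cfg$region_bands <- unlist(cfg$region_bands)
  do.call(run_config, cfg)
}

write_resolved_config <- function(config, dir) {
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
}

cfg_es <- function(config, seed = config$seed) {
  es_config(init_step_deg = config$es_init_step_deg,
            init_step_mm = config$es_init_step_mm,
            grow = config$es_grow, shrink = config$es_shrink,
            max_iter = config$es_max_iter, bins = config$mi_bins,
            seed = seed)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact ", path, ": run the '", produced_by,
         "' command first", call. = FALSE)
  path
}

read_cohort_dir <- function(data_dir) {
  demo <- tibble::as_tibble(
    read.csv(require_artifact(file.path(data_dir, "demographics.csv"),
                              "simulate")))
  img_dir <- require_artifact(file.path(data_dir, "images"), "simulate")
  feet <- lapply(seq_len(nrow(demo)), function(i) {
    paths <- sort(list.files(img_dir, sprintf("^%s_rep", demo$foot_id[i]),
                             full.names = TRUE))
    if (!length(paths)) stop("no images found for foot ", demo$foot_id[i])
    list(foot_id = demo$foot_id[i], side = demo$side[i],
         images = lapply(paths, read_pressure_image, side = demo$side[i]))
  })
  list(feet = feet, demographics = demo)
}

# Per-foot preprocessing: orient left and average the aligned repeats.
foot_averages <- function(feet, config) {
  seeds <- derive_seeds(config$seed, length(feet))
  lapply(seq_along(feet), function(i) {
    imgs <- lapply(feet[[i]]$images, flip_to_left)
    align_and_average_foot(imgs, seed = seeds[i],
                           config = cfg_es(config, seeds[i]))
  })
}

#' Pipeline stages
#'
#' Filesystem-level orchestration of the full workflow; each stage reads
#' the artifacts of the previous one and writes its own outputs plus the
#' resolved configuration. `run_pipeline()` dispatches on the command name
#' (the interface used by the `plantarmap` command-line script).
#'
#' @param command one of `"simulate"`, `"build-template"`, `"fit-model"`,
#'   `"analyze"`, `"report"`
#' @param config a [run_config()]
#' @param ... stage arguments (see the individual stage functions)
#' @return the stage's primary artifact directory, invisibly
#' @export
run_pipeline <- function(command, config = run_config(), ...) {
  switch(command,
    "simulate" = stage_simulate(config = config, ...),
    "build-template" = stage_build_template(config = config, ...),
    "fit-model" = stage_fit_model(config = config, ...),
    "analyze" = stage_analyze(config = config, ...),
    "report" = stage_report(...),
    stop("unknown command '", command,
         "' (expected simulate, build-template, fit-model, analyze, report)")
  )
}

#' @rdname run_pipeline
#' @param out_dir output directory
#' @param spec a [cohort_spec()] for the simulated cohort
#' @export
stage_simulate <- function(out_dir, spec = NULL, config = run_config()) {
  if (is.null(spec)) spec <- cohort_spec(seed = config$seed)
  cohort <- generate_cohort(spec)
  write_cohort(cohort, out_dir)
  write_resolved_config(config, out_dir)
  invisible(out_dir)
}

#' @rdname run_pipeline
#' @param data_dir cohort directory (`images/` + `demographics.csv`)
#' @export
stage_build_template <- function(data_dir, out_dir, config = run_config()) {
  cohort <- read_cohort_dir(data_dir)
  avgs <- foot_averages(cohort$feet, config)
  tr <- build_template(avgs, seed = config$seed,
                       max_iter = config$template_max_iter,
                       tol = config$template_tol,
                       silhouette_threshold = config$silhouette_threshold,
                       es = cfg_es(config),
                       demons_args = list(lambda1 = config$lambda1,
                                          lambda2 = config$lambda2,
                                          sigma_px = config$demons_sigma_px))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_template(tr, out_dir)
  for (i in seq_along(avgs))
    write_pressure_image(avgs[[i]],
                         file.path(out_dir, sprintf("avg_%s.nii.gz",
                                                    cohort$feet[[i]]$foot_id)))
  write_resolved_config(config, out_dir)
  invisible(out_dir)
}

#' @rdname run_pipeline
#' @param template_dir output of the build-template stage
#' @export
stage_fit_model <- function(data_dir, template_dir, out_dir,
                            config = run_config()) {
  cohort <- read_cohort_dir(data_dir)
  tmpl <- read_template(require_artifact(template_dir, "build-template"))
  avg_paths <- file.path(template_dir,
                         sprintf("avg_%s.nii.gz", cohort$demographics$foot_id))
  avgs <- if (all(file.exists(avg_paths)))
    lapply(avg_paths, read_pressure_image)
  else foot_averages(cohort$feet, config)
  seeds <- derive_seeds(config$seed + 1L, length(avgs))
  aligned <- lapply(seq_along(avgs), function(i) {
    t_i <- rigid_register(avgs[[i]], tmpl$template, cfg_es(config, seeds[i]))
    warped <- apply_transform(avgs[[i]], t_i, out_dim = dim(tmpl$template$data))
    f_i <- demons_register(
      compute_silhouette(warped, config$silhouette_threshold),
      tmpl$silhouette, lambda1 = config$lambda1, lambda2 = config$lambda2,
      sigma_px = config$demons_sigma_px)
    apply_transform(avgs[[i]], t_i, f_i, out_dim = dim(tmpl$template$data))
  })
  model <- fit_pixelwise_model(aligned, cohort$demographics, tmpl$silhouette,
                               template = tmpl$template)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pixelwise_model(model, out_dir)
  norm <- check_normality(model, alpha = config$alpha)
  jsonlite::write_json(
    list(fraction_rejected = norm$fraction_rejected,
         corrected_alpha = norm$corrected_alpha),
    file.path(out_dir, "normality.json"), auto_unbox = TRUE, digits = NA)
  write_resolved_config(config, out_dir)
  invisible(out_dir)
}

#' @rdname run_pipeline
#' @param model_dir output of the fit-model stage
#' @param patients data frame with demographics columns plus `image`
#'   (path to the peak pressure NIfTI) and optionally `foot_id`, `side`
#' @export
stage_analyze <- function(model_dir, patients, out_dir,
                          config = run_config()) {
  model <- read_pixelwise_model(require_artifact(model_dir, "fit-model"))
  regions <- build_region_mask(model$domain, bands = config$region_bands,
                               mt1_width_frac = config$mt1_width_frac)
  smoothness <- estimate_smoothness(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  any_unreliable <- FALSE
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    fid <- if ("foot_id" %in% names(p)) p$foot_id else sprintf("P%03d", i)
    img <- read_pressure_image(p$image,
                               side = if ("side" %in% names(p)) p$side else NA)
    res <- withCallingHandlers(
      analyze_patient(img, p, model, regions = regions,
                      variant = config$t_variant, alpha = config$alpha,
                      two_sided = config$two_sided,
                      silhouette_threshold = config$silhouette_threshold,
                      dice_floor = config$dice_floor, seed = config$seed + i,
                      smoothness = smoothness),
      warning = function(w) invokeRestart("muffleWarning"))
    any_unreliable <- any_unreliable || res$qc$unreliable
    tmap_img <- pressure_image(res$abnormality$thresholded_t,
                               spacing = model$domain$spacing)
    write_pressure_image(tmap_img,
                         file.path(out_dir, sprintf("%s_thresholded_t.nii.gz", fid)))
    ggplot2::ggsave(file.path(out_dir, sprintf("%s_panels.png", fid)),
                    plot_patient_panels(res), width = 10, height = 7, dpi = 120)
    jsonlite::write_json(res$qc,
                         file.path(out_dir, sprintf("%s_qc.json", fid)),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- cbind(tibble::tibble(foot_id = fid), glance(res))
  }
  patterns <- do.call(rbind, rows)
  write.csv(as.data.frame(patterns), file.path(out_dir, "patterns.csv"),
            row.names = FALSE)
  write_resolved_config(config, out_dir)
  structure(invisible(out_dir), unreliable = any_unreliable)
}

#' @rdname run_pipeline
#' @param analysis_dir output of the analyze stage
#' @export
stage_report <- function(analysis_dir, out_dir = analysis_dir) {
  pat <- read.csv(require_artifact(file.path(analysis_dir, "patterns.csv"),
                                   "analyze"))
  flags <- c("mt1_increase", "toes_abnormal", "midfoot_increase",
             "mt2_5_abnormal", "heel_abnormal", "no_abnormality")
  present <- intersect(flags, names(pat))
  summary <- tibble::tibble(
    pattern = present,
    n_feet = vapply(present, function(f) sum(pat[[f]]), integer(1)),
    fraction = vapply(present, function(f) mean(pat[[f]]), numeric(1))
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(summary), file.path(out_dir, "pattern_summary.csv"),
            row.names = FALSE)
  md <- c("# Cohort abnormality pattern summary", "",
          sprintf("%d feet analyzed; %d flagged unreliable.",
                  nrow(pat), sum(pat$unreliable)),
          "",
          "| pattern | feet | fraction |", "|---|---|---|",
          sprintf("| %s | %d | %.1f%% |", summary$pattern, summary$n_feet,
                  100 * summary$fraction))
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(summary)
}
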