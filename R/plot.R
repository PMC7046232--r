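img_df <- function(m, spacing = c(1, 1)) {
  data.frame(
    ap_mm = rep((seq_len(nrow(m)) - 1) * spacing[1], ncol(m)),
    ml_mm = rep((seq_len(ncol(m)) - 1) * spacing[2], each = nrow(m)),
    value = as.numeric(m)
  )
}

#' Plot methods for pressure images and result maps
#'
#' `autoplot()` renders pressure images, t-maps and thresholded abnormality
#' maps as heat maps in physical coordinates (anterior-posterior axis
#' vertical, toes up).
#'
#' @param object the object to plot
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pressure_image <- function(object, ...) {
  df <- img_df(object$data, object$spacing)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (object$normalized) "pressure (norm.)" else "pressure (kPa)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "medial-lateral (mm)", y = "anterior-posterior (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pressure_image
#' @export
autoplot.t_map <- function(object, ...) {
  df <- img_df(object$t, object$spacing)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "t", low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "medial-lateral (mm)", y = "anterior-posterior (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pressure_image
#' @export
autoplot.abnormality_map <- function(object, ...) {
  df <- img_df(object$thresholded_t, object$spacing)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      name = sprintf("t (|t| > %.2f)", object$critical_t),
      low = "#2166ac", mid = "grey95", high = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "medial-lateral (mm)", y = "anterior-posterior (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pressure_image
#' @export
autoplot.region_mask <- function(object, ...) {
  df <- img_df(object$labels, object$spacing)
  df$region <- factor(df$value, levels = 0:5,
                      labels = c("background", object$region_names))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "medial-lateral (mm)", y = "anterior-posterior (mm)") +
    ggplot2::theme_minimal()
}

#' Alignment QC overlay
#'
#' Superimposes the reference image (red) and an aligned image (blue);
#' accurate alignment shows as overlapping purple footprints.
#'
#' @param fixed,moving [pressure_image()] objects on a common grid
#' @return a ggplot
#' @export
plot_alignment_overlay <- function(fixed, moving) {
  a <- fixed$data / max(fixed$data, 1e-12)
  b <- moving$data / max(moving$data, 1e-12)
  df <- img_df(a, fixed$spacing)
  df$blue <- as.numeric(b)
  df$col <- grDevices::rgb(pmin(df$value, 1), 0, pmin(df$blue, 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm)) +
    ggplot2::geom_raster(fill = df$col) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "medial-lateral (mm)", y = "anterior-posterior (mm)",
                  title = "fixed (red) vs aligned (blue)") +
    ggplot2::theme_minimal()
}

#' Six-panel patient QC figure
#'
#' Measured, aligned and predicted images, the alignment overlay, the raw
#' t-map and the thresholded abnormality map for one analyzed patient.
#'
#' @param analysis an [analyze_patient()] result
#' @return a ggplot (faceted)
#' @export
plot_patient_panels <- function(analysis) {
  sp <- analysis$predicted$spacing
  panels <- list(
    "1 measured" = analysis$measured$data,
    "2 aligned" = analysis$aligned$data,
    "3 predicted" = analysis$predicted$data,
    "4 residual" = analysis$residuals$data,
    "5 t-map" = analysis$tmap$t,
    "6 thresholded t" = analysis$abnormality$thresholded_t
  )
  df <- do.call(rbind, lapply(names(panels), function(nm) {
    d <- img_df(panels[[nm]] / max(abs(panels[[nm]]), 1e-12), sp)
    d$panel <- nm
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel, nrow = 2) +
    ggplot2::scale_fill_gradient2(name = "scaled value", low = "#2166ac",
                                  mid = "grey98", high = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "medial-lateral (mm)", y = "anterior-posterior (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
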