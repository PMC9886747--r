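# ggplot2 display methods. Rendering is for inspection and QC only;
# quantitation never flows through these.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_df <- function(img, spacing = c(1, 1)) {
  d <- dim(img)
  tibble::tibble(
    x = rep((seq_len(d[1]) - 1) * spacing[1], times = d[2]),
    y = rep((seq_len(d[2]) - 1) * spacing[2], each = d[1]),
    value = as.vector(img))
}

#' Plot a thin-slab MIP
#'
#' @param object a `ctha_mip` from [mip_slab()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot ctha_mip
autoplot.ctha_mip <- function(object, ...) {
  df <- raster_df(object$values, object$in_plane_spacing)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "HU") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s MIP, %.0f mm slab at %.1f mm",
                                  object$plane, object$slab_thickness_mm,
                                  object$slab_center_mm),
                  x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' Plot an enhancement-map slice in conventional (inverted) gray scale
#'
#' @param object a `ctha_em`.
#' @param plane,slice_mm,window,inverted see [render_em()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot ctha_em
autoplot.ctha_em <- function(object, plane = "axial", slice_mm = NULL,
                             window = c(0, 100), inverted = TRUE, ...) {
  img <- render_em(object, window = window, inverted = inverted,
                   plane = plane, slice_mm = slice_mm)
  ax <- plane_axis(plane)
  sp <- object$spacing[setdiff(1:3, ax)]
  df <- raster_df(img, sp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = NULL, guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s enhancement map (%s)",
                                  object$phase_pair %||% "", plane),
                  x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of diagnostic metrics with confidence intervals
#'
#' @param object a `ctha_diag` from [diagnostic_metrics()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot ctha_diag
autoplot.ctha_diag <- function(object, ...) {
  m <- object$metrics
  m$metric <- factor(m$metric, levels = rev(m$metric))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$estimate, y = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("estimate (%d%% CI, %s)",
                              round(100 * (1 - object$alpha)), object$ci_method),
                  y = NULL) +
    ggplot2::theme_minimal()
}
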