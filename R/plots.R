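#' Plot a point cloud
#'
#' Side (xz) or top (xy) scatter of a (sub)sampled cloud, coloured by
#' class label or tree id.
#'
#' @param pc point-cloud tibble.
#' @param view `"side"` (x against height) or `"top"`.
#' @param colour `"label"`, `"tree"` or `NULL`.
#' @param max_points subsample cap for responsiveness.
#' @return A ggplot object.
#' @export
plot_point_cloud <- function(pc, view = c("side", "top"), colour = "label",
                             max_points = 50000) {
  view <- match.arg(view)
  check_point_cloud(pc)
  if (nrow(pc) > max_points)
    pc <- dplyr::slice_sample(pc, n = max_points)
  aes <- if (view == "side") ggplot2::aes(x = .data$x, y = .data$z)
  else ggplot2::aes(x = .data$x, y = .data$y)
  g <- ggplot2::ggplot(pc, aes) + ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (m)", y = if (view == "side") "height (m)" else "y (m)")
  if (!is.null(colour) && colour %in% names(pc))
    g + ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colour]])),
                            size = 0.2, alpha = 0.6) +
    ggplot2::labs(colour = colour)
  else g + ggplot2::geom_point(size = 0.2, alpha = 0.6)
}

#' Raster heat map
#'
#' @param object a [ca_raster] (DTM, CHM or label map).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_raster <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() + ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "transparent") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Plot a taper curve with its circle-fit knots
#'
#' @param taper a `taper_curve`.
#' @param H optional tree height; extends the curve with the linear tip.
#' @return A ggplot object.
#' @export
plot_taper_curve <- function(taper, H = NULL) {
  hmax <- if (is.null(H)) taper$h_hi else H
  h <- seq(max(0, taper$h_lo - 1), hmax, length.out = 200)
  d <- as.numeric(taper_diameter(taper, h, H = H))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = tibble::tibble(h = h, d = 100 * d),
                       ggplot2::aes(x = .data$d, y = .data$h)) +
    ggplot2::geom_point(data = taper$knots,
                        ggplot2::aes(x = 100 * .data$diameter,
                                     y = .data$height)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "stem diameter (cm)", y = "height (m)")
}

#' Treatment effects of a fitted nested LMM
#'
#' Fixed treatment means with 95% confidence intervals.
#'
#' @param object a `crownarch_lmm`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.crownarch_lmm <- function(object, ...) {
  td <- tidy(object)
  td$lo <- td$estimate - 1.96 * td$std.error
  td$hi <- td$estimate + 1.96 * td$std.error
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = object$trait)
}

#' Trait distribution by thinning treatment
#'
#' @param table trait table with `treatment` and the trait column.
#' @param trait trait column name.
#' @return A ggplot object.
#' @export
plot_trait_by_treatment <- function(table, trait) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$treatment,
                                      y = .data[[trait]])) +
    ggplot2::geom_boxplot() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = trait)
}
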