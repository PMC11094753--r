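# ggplot2 visualizations of fields and scan tables

#' Plot a distance or access field
#'
#' Raster views of the per-pixel fields: distance to the nearest plastid
#' element (the interaction-region picture) or plastid access from angular
#' raytracing.
#'
#' @param object A `<distance_field>` or `<access_field>`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distance_field
#' @export
autoplot.distance_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "distance (µm)") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Distance to nearest plastid element")
}

#' @rdname autoplot.distance_field
#' @method autoplot access_field
#' @export
autoplot.access_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$access)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "access", limits = c(0, 1)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Plastid access (D = %g µm)",
                                  attr(object, "D")))
}

#' Plot a pair-separation scan
#'
#' Mean union interaction area of a plastid pair against center separation.
#'
#' @param scan Output of [pair_separation_scan()].
#' @return A ggplot.
#' @export
plot_pair_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$separation_um,
                                     y = .data$mean_area_um2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "center separation (µm)",
                  y = "mean union interaction area (µm²)",
                  title = "Pair interaction area vs separation")
}

#' Plot a branch-angle scan
#'
#' Interaction area of a Y-shaped stromule against branch angle, with the
#' maximizing angle marked.
#'
#' @param scan Output of [branch_angle_scan()].
#' @return A ggplot.
#' @export
plot_branch_angle_scan <- function(scan) {
  opt <- attr(scan, "optimal_angle")
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$angle_deg,
                                     y = .data$area_um2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$optimum)) +
    ggplot2::geom_vline(xintercept = opt, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::labs(x = "branch angle (degrees)",
                  y = "interaction area (µm²)",
                  title = sprintf("Branch-angle scan (optimum %g°)", opt))
}
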