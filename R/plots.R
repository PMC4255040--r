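#' Plot methods
#'
#' Every result type has an [ggplot2::autoplot()] method returning a ggplot:
#' density profiles and histograms as line plots, 2D density maps as raster
#' tiles, order profiles per carbon and region, thickness distributions,
#' area-per-lipid time series and MSD curves.
#'
#' @param object a result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-npbilayer
NULL

#' @rdname autoplot-npbilayer
#' @export
autoplot.density_profile <- function(object, ...) {
  ylab <- if (attr(object, "mode") == "mass") "density (kg/m³)" else "density (nm⁻³)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = ylab, title = attr(object, "label"))
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.md_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance (nm)", y = "probability density")
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.density_map_2d <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "z (nm)", fill = "ρ (nm⁻³)")
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.order_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$carbon, y = .data$minus_scd,
                                       group = .data$region,
                                       colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "carbon", y = expression(-S[CD]))
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.angle_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$density,
                                       colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "angle (deg)", y = "probability density")
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.dihedral_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$density,
                                       colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dihedral (deg)", y = "probability density")
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.thickness_field <- function(object, ...) {
  autoplot(object$distribution) +
    ggplot2::labs(x = "thickness (nm)",
                  title = sprintf("%s-region bilayer thickness", object$region))
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.apl_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$area_per_lipid)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "mean"), linetype = 2) +
    ggplot2::labs(x = "time (ns)", y = "area per lipid (nm²)")
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ns)", y = expression(MSD ~ (nm^2)),
                  title = sprintf("%s MSD, %s", attr(object, "mode"),
                                  attr(object, "subset")))
}

#' @rdname autoplot-npbilayer
#' @export
autoplot.rdf_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "r (nm)", y = "g(r)")
}
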