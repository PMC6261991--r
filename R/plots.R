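# ggplot2 visualisations for the main result types.

#' Plot a kymograph
#'
#' Space (um along the path) on x, time (s) running downward on y, as
#' kymographs are conventionally displayed.
#'
#' @param object A `kymograph` from [build_kymograph()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    time_s = (seq_len(nrow(object)) - 1) * attr(object, "time_pitch_s"),
    position_um = (seq_len(ncol(object)) - 1) *
      attr(object, "space_pitch_nm") / 1000)
  df$intensity <- as.numeric(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$position_um, .data$time_s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "counts") +
    ggplot2::labs(x = "position along path (µm)", y = "time (s)") +
    ggplot2::theme_minimal()
}

#' Plot a colocalisation fraction table
#'
#' Stacked bars per region and motion class; the fractions over both
#' regions total 100%.
#'
#' @param object A `fraction_table` from [build_fraction_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fraction_table
#' @export
autoplot.fraction_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$motion_class, .data$fraction_pct,
                               fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$region) +
    ggplot2::labs(x = NULL, y = "fraction of cluster records (%)") +
    ggplot2::theme_minimal()
}

#' Overlay cluster tracks on the cell geometry
#'
#' @param tracks [link_tracks()] output (optionally joined with
#'   classification columns; a `motion_class` column is used for
#'   colour when present).
#' @param geometry Optional [cell_geometry()] drawn as boundary and
#'   centre ellipses.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, geometry = NULL) {
  p <- ggplot2::ggplot(tracks, ggplot2::aes(.data$x, .data$y,
                                            group = .data$track_id)) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  p <- if ("motion_class" %in% names(tracks)) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$motion_class))
  } else {
    p + ggplot2::geom_path()
  }
  if (!is.null(geometry)) {
    th <- seq(0, 2 * pi, length.out = 181)
    ell <- function(f) {
      rot <- geometry$rotation_deg * pi / 180
      ux <- f * geometry$semi_axes[1] * cos(th)
      uy <- f * geometry$semi_axes[2] * sin(th)
      tibble(x = geometry$centre[1] + cos(rot) * ux - sin(rot) * uy,
             y = geometry$centre[2] + sin(rot) * ux + cos(rot) * uy,
             track_id = NA_integer_)
    }
    p <- p +
      ggplot2::geom_path(data = ell(1), linetype = 1, colour = "grey40") +
      ggplot2::geom_path(data = ell(geometry$centre_fraction),
                         linetype = 2, colour = "grey40")
  }
  p
}
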