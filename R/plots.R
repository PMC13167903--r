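#' Plot a tumor snapshot
#'
#' Draws the lattice positions of a snapshot. With `color_by = "genome"`
#' (the default) each distinct genome is hashed to a hue so genetic
#' variation reads as color variation; clonal sweeps appear monochrome,
#' fractal tumors speckled. CTLs are overdrawn as black points.
#'
#' @param cells A snapshot cell table.
#' @param color_by `"genome"`, `"type"` or `"n_drivers"`.
#' @param map Driver map (for `"n_drivers"`).
#' @param cell_size Point size.
#' @return A ggplot object.
#' @export
plot_tumor <- function(cells, color_by = c("genome", "type", "n_drivers"),
                       map = driver_map(), cell_size = 0.4) {
  color_by <- match.arg(color_by)
  mel <- cells[cells$type != "CTL", ]
  ctl <- cells[cells$type == "CTL", ]
  mel <- switch(color_by,
    genome = dplyr::mutate(mel, .col = factor(genome_hue(.data$genome))),
    type = dplyr::mutate(mel, .col = .data$type),
    n_drivers = dplyr::mutate(annotate_cells(mel, map = map),
                              .col = factor(.data$n_drivers)))
  p <- ggplot2::ggplot(mel, ggplot2::aes(x = .data$col, y = .data$row,
                                         colour = .data$.col)) +
    ggplot2::geom_point(size = cell_size, shape = 15) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = color_by) +
    ggplot2::theme_minimal()
  if (color_by == "genome")
    p <- p + ggplot2::scale_colour_hue() +
      ggplot2::guides(colour = "none")
  if (nrow(ctl) > 0)
    p <- p + ggplot2::geom_point(data = ctl, colour = "black",
                                 size = cell_size, shape = 16)
  p
}

# stable small-integer hue index per genome string
genome_hue <- function(genome, buckets = 64L) {
  vapply(genome, function(g) {
    if (is.na(g)) return(0L)
    sum(utf8ToInt(g) * seq_len(nchar(g))) %% buckets
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
autoplot.tumor_sim <- function(object, ...) {
  plot_tumor(final_cells(object), ...)
}

#' @export
autoplot.cross_pcf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid, y = .data$pcf)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance r", y = "cross-PCF") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rank_pcf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid, y = .data$pcf,
                                       colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance r", y = "cross-PCF",
                  colour = "target rank") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.morris_moat <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mu_star, y = .data$sigma,
                                       label = .data$parameter)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mu_star_lo,
                                         xmax = .data$mu_star_hi),
                            height = 0, alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(x = expression(mu^"*"), y = expression(sigma)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a sweep metric over the (r0, f) grid
#'
#' @param sweep Output of [run_sweep()].
#' @param metric Column to average per grid point (e.g. `"epsilon"`,
#'   `"beta"`, `"clustered_fd"`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = "epsilon") {
  agg <- dplyr::summarise(
    dplyr::group_by(sweep, .data$r0, .data$f),
    value = mean(.data[[metric]], na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$r0),
                                    y = factor(.data$f),
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "r0", y = "f", fill = metric) +
    ggplot2::theme_minimal()
}
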