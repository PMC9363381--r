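#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_errorbar
#'   geom_raster geom_ribbon scale_fill_viridis_c labs theme_minimal autoplot
#'   facet_wrap position_dodge geom_text
NULL

#' @export
ggplot2::autoplot

#' Plot an intensity profile (position vs intensity per stain)
#'
#' The profile-plot view used to score aggregate co-localisation: one line
#' per stain along the line drawn through the aggregate.
#'
#' @param object an `intensity_profile` from [extract_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.intensity_profile <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$position, y = .data$intensity, colour = .data$channel)) +
    geom_line(linewidth = 0.7) +
    labs(x = "position along line (px)", y = "intensity (a.u.)",
         colour = "stain",
         title = sprintf("Intensity profile through aggregate %s",
                         attr(object, "aggregate_id"))) +
    theme_minimal()
}

#' Bar chart of a condition summary (mean +/- SEM with significance flags)
#'
#' @param object a `condition_summary` from [fold_change()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.condition_summary <- function(object, ...) {
  d <- as_tibble(unclass(object))
  ggplot(d, aes(x = .data$condition, y = .data$mean)) +
    geom_col(fill = "grey70", width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    geom_text(aes(label = ifelse(is.na(.data$signif), "", .data$signif),
                  y = .data$mean + .data$sem), vjust = -0.5) +
    labs(x = NULL, y = d$measurement[1],
         title = sprintf("%s (mean ± SEM over replicates)",
                         d$measurement[1])) +
    theme_minimal()
}

#' Stress-granule recovery curve plot
#'
#' Normalised granule counts against recovery time with an SEM ribbon.
#'
#' @param object a `recovery_curve` from [recovery_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.recovery_curve <- function(object, ...) {
  d <- as_tibble(unclass(object))
  ggplot(d, aes(x = .data$timepoint, y = .data$normalised)) +
    geom_ribbon(aes(ymin = .data$normalised - .data$sem_normalised,
                    ymax = .data$normalised + .data$sem_normalised),
                fill = "grey80") +
    geom_line() + geom_point() +
    labs(x = "recovery time (min)",
         y = "granules per cell (normalised to t = 0)",
         title = "Stress granule disassembly") +
    theme_minimal()
}

#' Intensity heat map of one channel
#'
#' The heat-map rendering used to visualise G3BP1 granulation.
#'
#' @param image a [micrograph()] or numeric matrix.
#' @param stain stain to display when a micrograph is given.
#' @return a ggplot.
#' @export
plot_heatmap <- function(image, stain = "g3bp1") {
  m <- if (inherits(image, "micrograph")) get_channel(image, stain) else image
  d <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$intensity <- as.numeric(m)
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    labs(x = NULL, y = NULL, fill = "intensity",
         title = if (is.character(stain)) sprintf("%s intensity", stain) else NULL) +
    theme_minimal()
}

#' Intensity surface plot of one channel
#'
#' Perspective surface rendering of a channel (granularity shows as spikes).
#' Draws on the current graphics device.
#'
#' @param image a [micrograph()] or numeric matrix.
#' @param stain stain to display when a micrograph is given.
#' @param downsample keep every k-th pixel to keep the mesh light.
#' @param theta,phi view angles passed to [graphics::persp()].
#' @return invisibly, the perspective transformation matrix.
#' @export
plot_surface <- function(image, stain = "g3bp1", downsample = 2,
                         theta = 30, phi = 30) {
  m <- if (inherits(image, "micrograph")) get_channel(image, stain) else image
  idx_r <- seq(1, nrow(m), by = downsample)
  idx_c <- seq(1, ncol(m), by = downsample)
  invisible(graphics::persp(idx_r, idx_c, m[idx_r, idx_c], theta = theta,
                            phi = phi, border = NA, col = "grey80",
                            shade = 0.6, xlab = "row", ylab = "col",
                            zlab = "intensity"))
}
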