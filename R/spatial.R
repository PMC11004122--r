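#' Default gene palette
#'
#' Fixed ordered palette assigned to targets in configuration order, so the
#' same gene keeps its colour across images and figures. Colour-blind safe
#' (Okabe-Ito).
#' @param n Number of colours.
#' @return Character vector of hex colours.
#' @export
gene_palette <- function(n) {
  pal <- c(
    "#E69F00", "#56B4E9", "#009E73", "#F0E442",
    "#0072B2", "#D55E00", "#CC79A7", "#999999"
  )
  if (n > length(pal)) pal <- rep_len(pal, n)
  pal[seq_len(n)]
}

#' Build the point layer of a transcript-distribution plot
#'
#' One point per (cell, gene) passing the positivity threshold, at the cell
#' centroid, carrying the transcript count and a precomputed marker size.
#' Marker AREA grows linearly with transcript count above a configurable
#' minimum, so perceived ink is proportional to expression; the size value is
#' the corresponding diameter and is strictly increasing in count.
#'
#' @param data A `study_dataset` or `cell_profiles` tibble.
#' @param image_id Image to plot (must be in the dataset).
#' @param threshold Minimum transcripts for a (cell, gene) point (default 1).
#' @param min_size Marker diameter at one transcript (plot units).
#' @param size_scale Area increment per additional transcript, in units of
#'   the minimum marker's area.
#' @param extent Physical extent `c(width, height)` in micrometres; defaults
#'   to the bounding box of the image's cell centroids.
#' @return A `distribution_points` tibble: `x`, `y` (micrometres), `gene`,
#'   `count`, `size`; attribute `extent` = c(width, height) covering the
#'   points, `image_id`, `threshold`.
#' @export
distribution_points <- function(data, image_id, threshold = 1L,
                                min_size = 1.5, size_scale = 0.5, extent = NULL) {
  check_threshold(threshold)
  images <- attr(data, "images")
  if (is.null(images)) images <- unique(data$image_id)
  if (!image_id %in% images) {
    stop("distribution_points: unknown image '", image_id, "'", call. = FALSE)
  }
  gs <- genes(dataset_targets(data))
  pts <- tibble::as_tibble(data) |>
    dplyr::filter(.data$image_id == .env$image_id, .data$count >= .env$threshold) |>
    dplyr::transmute(
      x = .data$centroid_x, y = .data$centroid_y,
      gene = factor(.data$gene, levels = gs),
      count = .data$count,
      size = marker_size(.data$count, min_size, size_scale)
    ) |>
    dplyr::arrange(dplyr::desc(.data$count)) # big points drawn first, small on top
  if (nrow(pts) == 0) {
    warning("distribution_points: no (cell, gene) pair passes threshold ", threshold,
      " in image '", image_id, "'",
      call. = FALSE
    )
  }
  if (is.null(extent)) {
    all_img <- tibble::as_tibble(data) |>
      dplyr::filter(.data$image_id == .env$image_id)
    extent <- c(
      width = max(all_img$centroid_x, 0), height = max(all_img$centroid_y, 0)
    )
  }
  attr(pts, "extent") <- unname(extent)
  attr(pts, "image_id") <- image_id
  attr(pts, "threshold") <- as.integer(threshold)
  class(pts) <- c("distribution_points", class(pts))
  pts
}

# Area-linear size coding: area = a_min * (1 + size_scale * (count - 1)),
# diameter = min_size * sqrt(1 + size_scale * (count - 1)).
marker_size <- function(count, min_size, size_scale) {
  min_size * sqrt(1 + size_scale * (pmax(count, 1) - 1))
}

#' Plot the spatial transcript distribution of one image
#'
#' Scatter of cell centroids, coloured by gene and sized by transcript count
#' — a schematic rendering of the quantified image that can be compared or
#' overlaid with the source micrograph. The y axis follows the image
#' convention by default (origin top-left, y increasing downward) so overlays
#' need no flip; `y_axis = "math_up"` restores the mathematical orientation.
#'
#' @inheritParams distribution_points
#' @param y_axis `"image_down"` (default) or `"math_up"`.
#' @param palette Colours per gene, in target-configuration order.
#' @param ... Passed on to [distribution_points()] (marker sizing, extent).
#' @return A ggplot object; the underlying `distribution_points` tibble is in
#'   `$data`.
#' @export
plot_transcript_distribution <- function(data, image_id, threshold = 1L,
                                         y_axis = c("image_down", "math_up"),
                                         palette = NULL, ...) {
  y_axis <- match.arg(y_axis)
  pts <- distribution_points(data, image_id, threshold, ...)
  autoplot.distribution_points(pts, y_axis = y_axis, palette = palette)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_transcript_distribution
#' @param object A `distribution_points` tibble.
#' @method autoplot distribution_points
#' @export
autoplot.distribution_points <- function(object, y_axis = c("image_down", "math_up"),
                                         palette = NULL, ...) {
  y_axis <- match.arg(y_axis)
  gs <- levels(object$gene)
  if (is.null(palette)) palette <- gene_palette(length(gs))
  extent <- attr(object, "extent")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
    colour = .data$gene, size = .data$size
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_colour_manual(values = stats::setNames(palette, gs), drop = FALSE) +
    ggplot2::coord_fixed(xlim = c(0, extent[1])) +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)", colour = "Gene",
      title = attr(object, "image_id"),
      subtitle = paste0("threshold ≥ ", attr(object, "threshold"), " transcript(s)")
    ) +
    ggplot2::theme_minimal()
  if (y_axis == "image_down") {
    p <- p + ggplot2::scale_y_reverse(limits = c(extent[2], 0))
  } else {
    p <- p + ggplot2::ylim(0, extent[2])
  }
  p
}

#' Map plot points to micrograph pixel coordinates
#'
#' A centroid at (x, y) micrometres maps to pixel (x / sx, y / sy), where sx
#' and sy are the micrometres-per-pixel scales implied by the micrograph's
#' physical extent — no axis flip, since both the plot (image convention) and
#' the raster have origin top-left.
#'
#' @param points A `distribution_points` tibble.
#' @param extent_um Physical extent `c(width, height)` of the micrograph in
#'   micrometres.
#' @param dim_px Raster dimension `c(width, height)` in pixels.
#' @return The points tibble with added `px` and `py` columns.
#' @export
points_to_pixels <- function(points, extent_um, dim_px) {
  sx <- extent_um[1] / dim_px[1]
  sy <- extent_um[2] / dim_px[2]
  dplyr::mutate(tibble::as_tibble(points), px = .data$x / sx, py = .data$y / sy)
}

#' Overlay a transcript-distribution plot on its source micrograph
#'
#' Renders the micrograph as the plot background and the distribution points
#' on top at matching physical scale, for direct visual validation of the
#' harvest against the raw image. The micrograph extent must cover the plot
#' extent.
#'
#' @param points A `distribution_points` tibble.
#' @param micrograph Numeric matrix (grayscale, values in \[0, 1\], rows = y)
#'   or raster-compatible array.
#' @param extent_um Physical extent `c(width, height)` of the micrograph in
#'   micrometres.
#' @inheritParams plot_transcript_distribution
#' @return A ggplot object.
#' @export
overlay_micrograph <- function(points, micrograph, extent_um, palette = NULL) {
  plot_extent <- attr(points, "extent")
  if (plot_extent[1] > extent_um[1] + 1e-9 || plot_extent[2] > extent_um[2] + 1e-9) {
    stop(
      "overlay_micrograph: plot extent (", plot_extent[1], " x ", plot_extent[2],
      " µm) exceeds micrograph extent (", extent_um[1], " x ", extent_um[2],
      " µm)",
      call. = FALSE
    )
  }
  gs <- levels(points$gene)
  if (is.null(palette)) palette <- gene_palette(length(gs))
  ggplot2::ggplot(points, ggplot2::aes(.data$x, .data$y,
    colour = .data$gene, size = .data$size
  )) +
    ggplot2::annotation_raster(
      grDevices::as.raster(micrograph),
      xmin = 0, xmax = extent_um[1],
      # y reversed axis: ymin/ymax given on the reversed scale
      ymin = -extent_um[2], ymax = 0
    ) +
    ggplot2::geom_point(alpha = 0.9, fill = NA, shape = 21, stroke = 1) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_colour_manual(values = stats::setNames(palette, gs), drop = FALSE) +
    ggplot2::scale_y_reverse(limits = c(extent_um[2], 0)) +
    ggplot2::coord_fixed(xlim = c(0, extent_um[1])) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "Gene") +
    ggplot2::theme_minimal()
}
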