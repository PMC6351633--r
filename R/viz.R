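#' Plot style for similarity-matrix and TIC figures
#'
#' One style object is meant to be shared by all figures of a report so the
#' value-to-color mapping is identical across plots and panels are directly
#' comparable. The value range is fixed to `[0, 1]`: cosine values live
#' there natively and negative Pearson values are clamped to 0 at display
#' time only (stored matrices are never clamped).
#'
#' @param colormap palette name understood by [grDevices::hcl.colors()];
#'   the default `"viridis"` is perceptually uniform.
#' @param n_colors number of palette levels.
#' @param separator_col color of the group-boundary lines.
#' @param dpi raster resolution for PNG output.
#' @return An object of class `plot_style`.
#' @export
plot_style <- function(colormap = "viridis", n_colors = 256L,
                       separator_col = "white", dpi = 96L) {
  structure(list(colormap = colormap, n_colors = as.integer(n_colors),
                 range = c(0, 1), separator_col = separator_col,
                 dpi = as.integer(dpi), palette =
                   grDevices::hcl.colors(n_colors, colormap)),
            class = "plot_style")
}

#' Map similarity values to colors
#'
#' Pure function behind the heatmaps: values are clamped to the style's
#' `[0, 1]` range and mapped linearly onto the palette.
#'
#' @param v numeric vector of similarity values.
#' @param style a [plot_style()].
#' @return Character vector of colors, same length as `v`.
#' @export
value_to_color <- function(v, style = plot_style()) {
  v <- pmin(pmax(v, style$range[1]), style$range[2])
  idx <- 1L + as.integer(round((v - style$range[1]) /
                                 diff(style$range) * (style$n_colors - 1L)))
  style$palette[idx]
}

#' Render a similarity matrix as a heatmap
#'
#' One pixel per scan pair, origin at the top-left so scans run left to
#' right and top to bottom in acquisition order, with group boundaries
#' drawn between measurements. Low-similarity scans appear as full
#' row-plus-column bands. Negative Pearson values are clamped to 0 for
#' display only.
#'
#' @param m a [similarity_matrix()].
#' @param path output PNG path.
#' @param style a [plot_style()].
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
plot_similarity_matrix <- function(m, path, style = plot_style(),
                                   width = 800L, height = 800L) {
  stopifnot(inherits(m, "similarity_matrix"))
  n <- nrow(m$values)
  vals <- pmin(pmax(m$values, style$range[1]), style$range[2])
  grDevices::png(path, width = width, height = height, res = style$dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(2.5, 2.5, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  # flip rows so scan 1 is the top row (origin top-left)
  graphics::image(
    x = seq_len(n), y = seq_len(n),
    z = t(vals[n:1, , drop = FALSE]),
    zlim = style$range, col = style$palette,
    useRaster = TRUE, axes = FALSE, xlab = "", ylab = "",
    main = sprintf("%s similarity", m$metric)
  )
  graphics::box()
  g <- m$groups
  if (nrow(g) > 1L) {
    for (k in seq_len(nrow(g) - 1L)) {
      cut <- g$end[k] + 0.5
      graphics::abline(v = cut, col = style$separator_col, lwd = 1.5)
      graphics::abline(h = n - cut + 1, col = style$separator_col, lwd = 1.5)
    }
  }
  mid <- (g$start + g$end) / 2
  graphics::axis(1, at = mid, labels = g$label, tick = FALSE, line = -0.5)
  graphics::axis(2, at = n - mid + 1, labels = g$label, tick = FALSE,
                 line = -0.5)
  invisible(path)
}

#' Plot a TIC trace with rejected scans marked
#'
#' Total ion current against scan index; if a thresholded QC result is
#' supplied, rejected scans are marked. Anomalous local maxima or minima in
#' the TIC typically correspond to the unstable-spray artifact scans the QC
#' filter rejects.
#'
#' @param m an [ms_measurement()].
#' @param path output PNG path.
#' @param qc optional thresholded `scan_qc` for `m`.
#' @param style a [plot_style()].
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
plot_tic <- function(m, path, qc = NULL, style = plot_style(),
                     width = 900L, height = 300L) {
  stopifnot(inherits(m, "ms_measurement"))
  tr <- tic_trace(m)
  grDevices::png(path, width = width, height = height, res = style$dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(tr$scan_index, tr$tic, type = if (nrow(tr) > 1) "l" else "p",
                 xlab = "scan index", ylab = "TIC",
                 main = sprintf("TIC — %s", m$label))
  if (!is.null(qc)) {
    stopifnot(inherits(qc, "scan_qc"))
    rej <- which(!qc$keep)
    if (length(rej) > 0L) {
      graphics::points(tr$scan_index[rej], tr$tic[rej], col = "red",
                       pch = 4, lwd = 2)
      graphics::legend("topright", legend = "rejected", col = "red",
                       pch = 4, bty = "n")
    }
  }
  invisible(path)
}

#' @export
plot.similarity_matrix <- function(x, path = tempfile(fileext = ".png"),
                                   ...) {
  plot_similarity_matrix(x, path, ...)
}
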