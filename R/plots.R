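# Figure renderers used by run_pipeline()/write_results(). All take data and
# return a function(path) so write_results can hash what it wrote.

png_device <- function(path, width, height) {
  grDevices::png(path, width = width, height = height, res = 96,
                 type = if (capabilities("cairo")) "cairo" else "Xlib")
}

#' Render the ROI x time heatmap
#'
#' Mirrors the ROI heatmap layout: one horizontal intensity strip per ROI
#' (numbered), with the whole-image row "W" at the bottom.
#'
#' @param traces A [extract_traces()] matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(traces, path) {
  stopifnot(inherits(traces, "roi_trace_matrix"))
  v <- traces$values
  png_device(path, 900, 120 + 18 * nrow(v))
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(4, 5, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  # rows top-to-bottom: ROI 1 first, W last
  z <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
  graphics::image(x = traces$labels, y = seq_len(nrow(v)), z = z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (min)", ylab = "", yaxt = "n")
  graphics::axis(2, at = seq_len(nrow(v)), labels = rev(rownames(v)),
                 las = 1, cex.axis = 0.7)
  graphics::abline(v = 0, col = "white", lty = 2)
  invisible(path)
}

#' Render group mean +/- SD bars with significance stars
#'
#' @param report A [significance_report()] data frame.
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
render_group_bars <- function(report, path, main = "") {
  png_device(path, 900, 500)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(5, 5, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  ylim <- range(c(0, report$mean - report$sd, report$mean + report$sd))
  ylim <- ylim + c(-0.1, 0.2) * diff(ylim)
  bp <- graphics::barplot(report$mean,
                          names.arg = ifelse(report$label == 0, "pre",
                                             report$label),
                          ylim = ylim, xlab = "interval end (min)",
                          ylab = expression(paste(Delta, "F/F"[0], " (%)")),
                          main = main, las = 2)
  nz <- report$sd > 1e-6 * diff(ylim)  # drawable error bars only
  if (any(nz)) {
    graphics::arrows(bp[nz], report$mean[nz] - report$sd[nz], bp[nz],
                     report$mean[nz] + report$sd[nz], angle = 90, code = 3,
                     length = 0.03)
  }
  lab_y <- report$mean + report$sd + 0.05 * diff(ylim)
  graphics::text(bp, lab_y, report$stars)
  invisible(path)
}

#' Render interval-averaged images as a montage
#'
#' @param series An [average_intervals()] result in image mode.
#' @param path Output PNG path.
#' @param ncol Panels per row.
#' @return `path`, invisibly.
#' @export
render_interval_images <- function(series, path, ncol = 8) {
  stopifnot(inherits(series, "interval_series"), !is.null(series$images))
  n <- length(series$labels)
  nrow <- ceiling(n / ncol)
  png_device(path, 160 * ncol, 110 * nrow)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(nrow, ncol), mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  zlim <- range(series$images, na.rm = TRUE)
  for (i in seq_len(n)) {
    img <- series$images[i, , ]
    graphics::image(t(img[rev(seq_len(nrow(img))), , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "viridis"), zlim = zlim,
                    axes = FALSE, asp = nrow(img) / ncol(img))
    graphics::title(sprintf("%g min", series$labels[i]), cex.main = 0.8)
  }
  invisible(path)
}

#' Render ROI outlines over the occupancy map
#'
#' @param rois A [detect_rois()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_roi_overlay <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  png_device(path, 900, 450)
  on.exit(grDevices::dev.off())
  occ <- rois$occupancy
  graphics::image(x = seq_len(ncol(occ)), y = seq_len(nrow(occ)),
                  z = t(occ[rev(seq_len(nrow(occ))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "column (px)", ylab = "row (px)")
  for (r in rois$rois) {
    graphics::text(r$centroid[2], nrow(occ) + 1 - r$centroid[1],
                   labels = r$id, col = "white", font = 2)
  }
  invisible(path)
}
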