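#' ROI detection parameters
#'
#' Parameters of the adaptive-binarization + morphology ROI detector.
#' A pixel of a dF/F0 frame is active when it exceeds the mean of its
#' `block_size` x `block_size` neighbourhood (edge-replicated) by more than
#' `offset` percentage points. Each binarized frame is cleaned by a
#' morphological opening then closing with diamond (cross-shaped) structuring
#' elements. Pixels active in at least a fraction `occupancy_min` of the
#' analyzed frames form the ROI support, which is split into connected
#' components and filtered by area.
#'
#' @param block_size Odd neighbourhood width in pixels, >= 3.
#' @param offset Threshold offset above the local mean, dF/F0 percentage
#'   points.
#' @param open_radius,close_radius Structuring-element radii in pixels
#'   (radius r = diamond of half-width r; 0 disables the step).
#' @param occupancy_min Minimum fraction of analyzed frames a pixel must be
#'   active in, in `[0, 1]`.
#' @param min_area,max_area Component area bounds in pixels; `max_area = NULL`
#'   defaults to a quarter of the frame.
#' @param connectivity Pixel connectivity for component labelling, 4 or 8.
#' @return An object of class `roi_params`.
#' @export
roi_params <- function(block_size = 11, offset = 1.0, open_radius = 1,
                       close_radius = 1, occupancy_min = 0.05, min_area = 6,
                       max_area = NULL, connectivity = 8) {
  if (!is.numeric(block_size) || length(block_size) != 1L || block_size < 3 ||
      block_size %% 2 != 1) {
    stop("`block_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (occupancy_min < 0 || occupancy_min > 1) {
    stop("`occupancy_min` must be in [0, 1]", call. = FALSE)
  }
  if (min_area < 1) stop("`min_area` must be >= 1", call. = FALSE)
  if (!is.null(max_area) && max_area < min_area) {
    stop("`max_area` must be >= `min_area`", call. = FALSE)
  }
  if (open_radius < 0 || close_radius < 0) {
    stop("structuring-element radii must be >= 0", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  structure(
    list(block_size = as.integer(block_size), offset = offset,
         open_radius = as.integer(open_radius),
         close_radius = as.integer(close_radius),
         occupancy_min = occupancy_min, min_area = as.integer(min_area),
         max_area = if (is.null(max_area)) NULL else as.integer(max_area),
         connectivity = as.integer(connectivity)),
    class = "roi_params"
  )
}

# Local mean with an integral image over an edge-replicated padding.
local_mean <- function(frame, block_size) {
  r <- (block_size - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  if (block_size > nr + 2 * r || block_size > nc + 2 * r) {
    stop("`block_size` exceeds the padded image extent", call. = FALSE)
  }
  ri <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  p <- frame[ri, ci, drop = FALSE]
  # summed-area table with a zero first row/column
  s <- matrix(0, nr + 2L * r + 1L, nc + 2L * r + 1L)
  s[-1, -1] <- apply(apply(p, 2, cumsum), 1, cumsum) |> t()
  b <- block_size
  i <- seq_len(nr); j <- seq_len(nc)
  (s[i + b, j + b, drop = FALSE] - s[i, j + b, drop = FALSE] -
     s[i + b, j, drop = FALSE] + s[i, j, drop = FALSE]) / (b * b)
}

#' Adaptive binarization of a single dF/F0 frame
#'
#' A pixel is active iff its value exceeds the local mean of its
#' `block_size` neighbourhood (computed with edge-replicated padding) by more
#' than `offset`. Non-finite (invalid) pixels are never active and are
#' replaced by the frame mean of the valid pixels before the local mean is
#' taken, so an invalid pixel does not bias its neighbours' thresholds.
#'
#' @param frame Numeric matrix of dF/F0 percent values (may contain `NA`).
#' @param params A [roi_params()].
#' @return Logical matrix of the same dimensions.
#' @export
binarize_frame <- function(frame, params) {
  stopifnot(is.matrix(frame), inherits(params, "roi_params"))
  if (params$block_size > max(dim(frame))) {
    stop("`block_size` larger than the image extent", call. = FALSE)
  }
  bad <- !is.finite(frame)
  f <- frame
  if (any(bad)) {
    fill <- mean(frame[!bad])
    if (!is.finite(fill)) fill <- 0
    f[bad] <- fill
  }
  lm <- local_mean(f, params$block_size)
  act <- f > lm + params$offset
  act[bad] <- FALSE
  act
}

# Offsets (dr, dc) of a diamond structuring element of the given radius.
diamond_offsets <- function(radius) {
  if (radius == 0) return(matrix(0L, 1, 2))
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  as.matrix(g[abs(g$dr) + abs(g$dc) <= radius, , drop = FALSE])
}

# Shift a logical matrix by (dr, dc), filling vacated cells with `fill`.
shift_mask <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}

# Erosion and dilation with the frame as the universe: neighbours falling
# outside the frame are ignored (not counted as active or inactive). With a
# symmetric element these operators are adjoint, so opening and closing are
# idempotent, anti-extensive and extensive respectively.
erode_mask <- function(m, radius) {
  if (radius == 0) return(m)
  off <- diamond_offsets(radius)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) {
    out <- out & shift_mask(m, off[k, 1], off[k, 2], fill = TRUE)
  }
  out
}

dilate_mask <- function(m, radius) {
  if (radius == 0) return(m)
  off <- diamond_offsets(radius)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) {
    out <- out | shift_mask(m, off[k, 1], off[k, 2], fill = FALSE)
  }
  out
}

#' Morphological cleaning of a binary frame
#'
#' Opening (erosion then dilation) with a diamond element of
#' `open_radius` removes speckle smaller than the element, then closing
#' (dilation then erosion) with `close_radius` fills small holes.
#' Applying the cleaning twice gives the same result as applying it once.
#'
#' @param mask Logical matrix from [binarize_frame()].
#' @param params A [roi_params()].
#' @return Logical matrix.
#' @export
morph_clean <- function(mask, params) {
  stopifnot(is.logical(mask), is.matrix(mask), inherits(params, "roi_params"))
  opened <- dilate_mask(erode_mask(mask, params$open_radius),
                        params$open_radius)
  erode_mask(dilate_mask(opened, params$close_radius), params$close_radius)
}

# Connected-component labelling by flood fill at 4- or 8-connectivity.
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      qr <- pr + nb[, "dr"]; qc <- pc + nb[, "dc"]
      ok <- qr >= 1 & qr <= nr & qc >= 1 & qc <= nc
      q <- (qc[ok] - 1L) * nr + qr[ok]
      q <- q[mask[q] & lab[q] == 0L]
      lab[q] <- cur
      queue <- c(queue, q)
    }
  }
  lab
}

#' Detect regions of interest from a dF/F0 stack
#'
#' Runs the full detector: every analyzed frame is adaptively binarized
#' ([binarize_frame()]) and morphologically cleaned ([morph_clean()]); the
#' per-pixel fraction of frames in which a pixel was active (the occupancy
#' map) is thresholded at `occupancy_min`; the surviving support is split
#' into connected components at the configured connectivity and filtered to
#' `[min_area, max_area]`. ROI ids are assigned consecutively from 1 in
#' raster order of the component centroids (top-to-bottom, then
#' left-to-right). The detector is deterministic for fixed input and
#' parameters.
#'
#' @param dff A [compute_dff()] stack with at least one post-injection frame.
#' @param params A [roi_params()].
#' @param frames Which frames to analyze: `"post"` (default, timestamps
#'   after the injection) or `"all"`.
#' @return An object of class `roi_set`: a list with `rois` (each a list
#'   with `id`, `pixels` (n x 2 matrix of row/col), `centroid`, `area`),
#'   `occupancy` (matrix), `dim`, and `params`.
#' @export
detect_rois <- function(dff, params = roi_params(), frames = c("post", "all")) {
  frames <- match.arg(frames)
  stopifnot(inherits(dff, "dff_stack"), inherits(params, "roi_params"))
  idx <- if (frames == "post") which(dff$timestamps > 0) else
    seq_along(dff$timestamps)
  if (length(idx) == 0) stop("no frames to analyze", call. = FALSE)
  d <- dim(dff$values)
  occ <- matrix(0, d[2], d[3])
  for (f in idx) {
    act <- morph_clean(binarize_frame(dff$values[f, , ], params), params)
    occ <- occ + act
  }
  occ <- occ / length(idx)
  support <- occ >= params$occupancy_min & occ > 0
  lab <- label_components(support, params$connectivity)
  max_area <- params$max_area %||% as.integer(floor(d[2] * d[3] / 4))
  rois <- list()
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      if (nrow(px) < params$min_area || nrow(px) > max_area) next
      rois[[length(rois) + 1L]] <- list(
        pixels = unname(px),
        centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
        area = nrow(px))
    }
  }
  if (length(rois) > 0) {
    ord <- order(vapply(rois, function(r) r$centroid[1], numeric(1)),
                 vapply(rois, function(r) r$centroid[2], numeric(1)))
    rois <- rois[ord]
    for (i in seq_along(rois)) rois[[i]]$id <- i
    rois <- lapply(rois, function(r) r[c("id", "pixels", "centroid", "area")])
  }
  structure(list(rois = rois, occupancy = occ, dim = d[2:3], params = params),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs on a %d x %d frame\n", length(x$rois),
              x$dim[1], x$dim[2]))
  for (r in x$rois) {
    cat(sprintf("  ROI %d: area %d px, centroid (%.1f, %.1f)\n",
                r$id, r$area, r$centroid[1], r$centroid[2]))
  }
  invisible(x)
}

#' Interval-averaged ROI traces (the heatmap matrix)
#'
#' For each ROI, the per-frame mean dF/F0 over its mask pixels is averaged
#' into `interval_width`-minute bins (same binning convention as
#' [average_intervals()]). A final row labelled `"W"` holds the identically
#' binned whole-image trace.
#'
#' @param dff A [compute_dff()] stack.
#' @param rois A [detect_rois()] result.
#' @param interval_width Bin width in minutes.
#' @return An object of class `roi_trace_matrix`: list with `values`
#'   (matrix, rows = ROI ids then `"W"`, columns = interval end labels),
#'   `labels` and `width`.
#' @export
extract_traces <- function(dff, rois, interval_width = 15) {
  stopifnot(inherits(dff, "dff_stack"), inherits(rois, "roi_set"))
  d <- dim(dff$values)
  if (!all(rois$dim == d[2:3])) {
    stop("ROI set does not match the stack dimensions", call. = FALSE)
  }
  m <- matrix(dff$values, d[1], d[2] * d[3])
  series <- matrix(NA_real_, length(rois$rois) + 1L, d[1])
  for (i in seq_along(rois$rois)) {
    px <- rois$rois[[i]]$pixels
    if (nrow(px) == 0) stop("empty ROI mask", call. = FALSE)
    lin <- (px[, 2] - 1L) * d[2] + px[, 1]
    series[i, ] <- rowMeans(m[, lin, drop = FALSE])
  }
  series[nrow(series), ] <- whole_image_trace(dff)
  binned <- bin_series(series, dff$timestamps, interval_width)
  vals <- binned$values
  rownames(vals) <- c(vapply(rois$rois, function(r) as.character(r$id),
                             character(1)), "W")
  colnames(vals) <- format(binned$labels, trim = TRUE)
  structure(list(values = vals, labels = binned$labels,
                 width = interval_width),
            class = "roi_trace_matrix")
}

#' Drug-response profile metrics of an interval trace
#'
#' Summarises an interval-averaged dF/F0 trace by: the post-injection
#' interval with the maximal value (`peak_label`, earliest on ties) and its
#' value; the first post-injection label whose value reaches half the peak
#' (`time_to_half_rise`); the first post-peak label at or below zero
#' (`baseline_crossing`, `NA` if the trace never returns to baseline); and
#' the minimum post-peak value (`undershoot_min`).
#'
#' @param trace Numeric vector of interval values, or an `interval_series`
#'   in trace mode, or a single row of a [extract_traces()] matrix.
#' @param labels Interval end labels in minutes (ignored when `trace` is an
#'   `interval_series`).
#' @return A list of class `profile_metrics`.
#' @export
profile_metrics <- function(trace, labels = NULL) {
  if (inherits(trace, "interval_series")) {
    labels <- trace$labels
    trace <- trace$values
  }
  stopifnot(is.numeric(trace), length(trace) == length(labels))
  post <- labels > 0
  if (sum(post) < 2) {
    stop("trace needs at least two post-injection intervals", call. = FALSE)
  }
  pv <- trace[post]; pl <- labels[post]
  pk <- which.max(pv)   # earliest on ties
  peak_label <- pl[pk]; peak_value <- pv[pk]
  half <- which(pv >= peak_value / 2)
  time_to_half_rise <- pl[half[1]]
  after <- seq_along(pv) > pk
  crossing <- pl[after & pv <= 0][1]
  undershoot_min <- if (any(after)) min(pv[after]) else peak_value
  structure(
    list(peak_label = peak_label, peak_value = peak_value,
         time_to_half_rise = time_to_half_rise,
         baseline_crossing = if (length(crossing) && !is.na(crossing))
           crossing else NA_real_,
         undershoot_min = undershoot_min),
    class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf(
    "<profile_metrics> peak %.3f%% at %g min; half-rise %g min; baseline crossing %s; undershoot min %.3f%%\n",
    x$peak_value, x$peak_label, x$time_to_half_rise,
    ifelse(is.na(x$baseline_crossing), "none",
           paste0(x$baseline_crossing, " min")), x$undershoot_min))
  invisible(x)
}
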