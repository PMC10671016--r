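#' Subtract a background recording
#'
#' Removes the dark/background level measured before the excitation LEDs are
#' switched on. Accepts a scalar level or a per-pixel background image;
#' results are clipped at zero so counts stay non-negative.
#'
#' @param recording A [session_recording()].
#' @param background_level Scalar count level, or a matrix matching the frame
#'   dimensions. Must be >= 0.
#' @return A [session_recording()] with the background removed.
#' @export
subtract_background <- function(recording, background_level) {
  stopifnot(inherits(recording, "session_recording"))
  d <- dim(recording$frames)
  if (is.matrix(background_level)) {
    if (!all(dim(background_level) == d[2:3])) {
      stop(sprintf("background image is %d x %d but frames are %d x %d",
                   nrow(background_level), ncol(background_level),
                   d[2], d[3]), call. = FALSE)
    }
    if (any(background_level < 0)) {
      stop("`background_level` must be >= 0", call. = FALSE)
    }
    bg <- rep(as.vector(background_level), each = d[1])
  } else {
    if (!is.numeric(background_level) || length(background_level) != 1L ||
        background_level < 0) {
      stop("`background_level` must be a non-negative scalar or matrix",
           call. = FALSE)
    }
    if (background_level == 0) return(recording)
    bg <- background_level
  }
  recording$frames <- array(pmax(as.vector(recording$frames) - bg, 0), dim = d)
  recording
}

#' Per-pixel baseline fluorescence
#'
#' Computes F0 as the per-pixel arithmetic mean over the frames whose
#' timestamps fall in `[window[1], window[2])`. The window must lie before
#' the injection. Pixels whose mean is not strictly positive are flagged
#' invalid: dF/F0 would be unbounded there, so they are excluded from all
#' downstream averages rather than clipped.
#'
#' The default window is the 15 minutes immediately preceding the injection,
#' matching the analysis span of the recordings; pass an explicit window to
#' baseline against an earlier part of the acclimation period instead.
#'
#' @param recording A [session_recording()].
#' @param window Length-2 numeric `(start, end)` in minutes relative to
#'   injection; `end` must not exceed the injection time.
#' @return An object of class `baseline_image` with fields `f0` (matrix),
#'   `valid` (logical matrix) and `window`.
#' @export
compute_f0 <- function(recording, window = c(-15, 0)) {
  stopifnot(inherits(recording, "session_recording"),
            is.numeric(window), length(window) == 2L)
  if (window[2] > recording$injection_time) {
    stop("baseline window must end at or before the injection", call. = FALSE)
  }
  idx <- which(recording$timestamps >= window[1] &
               recording$timestamps < window[2])
  if (length(idx) == 0) {
    stop("baseline window contains no frames", call. = FALSE)
  }
  f0 <- colMeans(recording$frames[idx, , , drop = FALSE], dims = 1)
  structure(list(f0 = f0, valid = f0 > 0, window = window),
            class = "baseline_image")
}

#' Per-pixel dF/F0 stack
#'
#' Applies the normalization `(F - F0) / F0 * 100` to every pixel of every
#' frame, in percent. Pixels flagged invalid in the baseline propagate as
#' `NA` and are excluded from all averages downstream.
#'
#' @param recording A [session_recording()].
#' @param f0 A `baseline_image` from [compute_f0()].
#' @return An object of class `dff_stack` with fields `values`
#'   (`n_frames x n_rows x n_cols`, percent), `timestamps`, `valid` and
#'   `geometry`.
#' @export
compute_dff <- function(recording, f0) {
  stopifnot(inherits(recording, "session_recording"),
            inherits(f0, "baseline_image"))
  d <- dim(recording$frames)
  if (!all(dim(f0$f0) == d[2:3])) {
    stop("baseline image dimensions do not match the recording",
         call. = FALSE)
  }
  f0v <- as.vector(f0$f0)
  f0v[!as.vector(f0$valid)] <- NA_real_
  m <- matrix(recording$frames, d[1], d[2] * d[3])
  vals <- sweep(100 * sweep(m, 2, f0v, `-`), 2, f0v, `/`)
  structure(
    list(values = array(vals, dim = d), timestamps = recording$timestamps,
         valid = f0$valid, geometry = recording$geometry),
    class = "dff_stack")
}

#' @export
print.dff_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dff_stack> %d frames of %d x %d px (%d valid px), t = [%.2f, %.2f] min\n",
              d[1], d[2], d[3], sum(x$valid), min(x$timestamps),
              max(x$timestamps)))
  invisible(x)
}

# Interval index for each timestamp: intervals tile time as
# ((k-1)*w, k*w] anchored at the injection and mirrored before it; the
# label of interval k is its end time k*w (signed).
interval_label <- function(t, width) ceiling(t / width) * width

# Nominal recorded span: frame centres extended by half a frame period at
# each end, so an interval exactly tiled by frames counts as complete.
nominal_span <- function(ts) {
  half <- if (length(ts) > 1) diff(ts[1:2]) / 2 else 0
  c(ts[1] - half, ts[length(ts)] + half)
}

# Labels of the intervals considered complete: the recorded span must cover
# the interval up to at most half a frame period of slack (so a bin exactly
# tiled by frames is complete, but a partial leading/trailing bin is not).
complete_labels <- function(ts, width) {
  labs <- sort(unique(interval_label(ts, width)))
  span <- nominal_span(ts)
  half <- if (length(ts) > 1) diff(ts[1:2]) / 2 else 0
  covered <- pmin(labs, span[2]) - pmax(labs - width, span[1])
  labs[covered >= width - half - 1e-9]
}

#' Average a dF/F0 stack over fixed time intervals
#'
#' Tiles time into `width`-minute intervals `((k-1) * width, k * width]`
#' anchored at the injection (and mirrored before it) and averages within
#' each interval. Each reported interval is labelled by its signed end time,
#' so the "30-min mark" at 15-min width is the average over `(15, 30]`.
#' Intervals not fully covered by the recording (at either end) are dropped.
#'
#' @param dff A [compute_dff()] stack.
#' @param width Interval width in minutes.
#' @param mode `"images"` returns one averaged frame per interval;
#'   `"trace"` additionally averages over valid pixels, returning one scalar
#'   per interval.
#' @return An object of class `interval_series` with fields `labels`
#'   (interval end times, minutes), `width`, and `images` (array
#'   `n_intervals x n_rows x n_cols`) or `values` (numeric vector).
#' @export
average_intervals <- function(dff, width, mode = c("images", "trace")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dff, "dff_stack"))
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  ts <- dff$timestamps
  if (width > max(ts) - min(ts)) {
    stop("`width` exceeds the recording span", call. = FALSE)
  }
  labs <- interval_label(ts, width)
  keep_lab <- complete_labels(ts, width)
  if (length(keep_lab) == 0) stop("no complete interval in span", call. = FALSE)
  d <- dim(dff$values)
  if (mode == "images") {
    imgs <- array(NA_real_, dim = c(length(keep_lab), d[2], d[3]))
    for (i in seq_along(keep_lab)) {
      idx <- which(labs == keep_lab[i])
      imgs[i, , ] <- colMeans(dff$values[idx, , , drop = FALSE], dims = 1)
    }
    structure(list(labels = keep_lab, width = width, images = imgs,
                   valid = dff$valid),
              class = "interval_series")
  } else {
    tr <- whole_image_trace(dff)
    vals <- vapply(keep_lab, function(l) mean(tr[labs == l]), numeric(1))
    structure(list(labels = keep_lab, width = width, values = vals),
              class = "interval_series")
  }
}

#' Whole-image dF/F0 trace
#'
#' Per-frame mean of dF/F0 over all valid pixels -- the "W" row of the ROI
#' heatmap and the whole-field drug-response readout.
#'
#' @param dff A [compute_dff()] stack.
#' @return Numeric vector, one percent value per frame.
#' @export
whole_image_trace <- function(dff) {
  stopifnot(inherits(dff, "dff_stack"))
  if (!any(dff$valid)) stop("no valid pixels", call. = FALSE)
  d <- dim(dff$values)
  m <- matrix(dff$values, d[1], d[2] * d[3])
  rowMeans(m[, as.vector(dff$valid), drop = FALSE])
}

# Bin an arbitrary per-frame series by the interval rule; shared by
# extract_traces. Returns list(labels, values matrix series x intervals).
bin_series <- function(series, timestamps, width) {
  labs <- interval_label(timestamps, width)
  keep <- complete_labels(timestamps, width)
  m <- if (is.matrix(series)) series else matrix(series, nrow = 1)
  out <- vapply(keep, function(l) rowMeans(m[, labs == l, drop = FALSE]),
                numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m))
  list(labels = keep, values = out)
}
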