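#' Session metadata
#'
#' Validated sidecar metadata for a stored session stack.
#'
#' @param fps Frame rate of the stored stack, frames per second.
#' @param injection_time Injection time in minutes (0 by convention).
#' @param baseline_window Length-2 `(start, end)` minutes used (or intended)
#'   for F0; `end` must not exceed `injection_time`.
#' @param drug_label Free-text drug label.
#' @param animal_id Free-text animal identifier.
#' @param pre_min Minutes of recording before the injection.
#' @param seed Optional integer generator seed, for provenance.
#' @return An object of class `session_metadata`.
#' @export
session_metadata <- function(fps, injection_time = 0,
                             baseline_window = c(-15, 0), drug_label = "",
                             animal_id = "", pre_min = -baseline_window[1],
                             seed = NULL) {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (length(baseline_window) != 2L ||
      baseline_window[1] >= baseline_window[2]) {
    stop("`baseline_window` must be an increasing (start, end) pair",
         call. = FALSE)
  }
  if (baseline_window[2] > injection_time) {
    stop("`baseline_window` must end at or before `injection_time`",
         call. = FALSE)
  }
  if (pre_min <= 0) stop("`pre_min` must be > 0", call. = FALSE)
  structure(
    list(fps = fps, injection_time = injection_time,
         baseline_window = baseline_window, drug_label = drug_label,
         animal_id = animal_id, pre_min = pre_min,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "session_metadata"
  )
}

#' Write a session to a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per frame, stored as 32-bit samples after division by a
#' power-of-two full-scale factor recorded in the sidecar; round-trip error
#' is below `2^-32` of full scale (far below one count at sensor noise
#' levels). The sidecar carries the geometry, frame rate, injection time,
#' timestamp policy (uniform frame centres), metadata, and, when supplied,
#' the simulation ground truth.
#'
#' @param recording A [session_recording()].
#' @param dir Output directory (created if missing).
#' @param metadata A [session_metadata()]; defaults are derived from the
#'   recording.
#' @param truth Optional `simulation_truth` from [simulate_session()].
#' @return Invisibly, the paths written (`stack`, `metadata`).
#' @export
write_session <- function(recording, dir, metadata = NULL, truth = NULL) {
  stopifnot(inherits(recording, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- recording$timestamps
  fps <- if (length(ts) > 1) 1 / (60 * diff(ts[1:2])) else
    recording$geometry$fps
  if (is.null(metadata)) {
    pre <- -nominal_span(ts)[1]
    metadata <- session_metadata(fps = fps,
                                 injection_time = recording$injection_time,
                                 baseline_window = c(-pre, 0),
                                 drug_label = recording$label,
                                 pre_min = pre)
  }
  stopifnot(inherits(metadata, "session_metadata"))
  scale <- 2^ceiling(log2(max(recording$frames, 1)))
  d <- dim(recording$frames)
  pages <- lapply(seq_len(d[1]), function(f) recording$frames[f, , ] / scale)
  stack_path <- file.path(dir, "stack.tif")
  tiff::writeTIFF(pages, stack_path, bits.per.sample = 32,
                  compression = "none")
  meta <- list(
    format = "cmosdff-session-1",
    geometry = list(n_rows = recording$geometry$n_rows,
                    n_cols = recording$geometry$n_cols,
                    pixel_pitch = recording$geometry$pixel_pitch,
                    fps = recording$geometry$fps),
    stack_fps = metadata$fps,
    timestamp_policy = "uniform frame centres: -pre_min + (k + 0.5)/(60 * fps), k = 0..n-1",
    pre_min = metadata$pre_min,
    injection_time = metadata$injection_time,
    baseline_window = metadata$baseline_window,
    drug_label = metadata$drug_label,
    animal_id = metadata$animal_id,
    seed = metadata$seed,
    intensity_scale = scale,
    n_frames = d[1]
  )
  if (!is.null(truth)) {
    meta$truth <- list(
      sites = lapply(truth$sites, function(s)
        list(center_row = s$center_row, center_col = s$center_col,
             sigma = s$sigma, gain = s$gain)),
      kinetic_curve = truth$kinetic_curve
    )
  }
  metadata_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(stack = stack_path, metadata = metadata_path))
}

#' Read a session written by [write_session()]
#'
#' Pages are reordered by page index, rescaled by the sidecar's intensity
#' scale, and timestamps are reconstructed from the stored frame rate and
#' pre-injection duration.
#'
#' @param stack_path Path to the multi-page TIFF.
#' @param metadata_path Path to the JSON sidecar; defaults to
#'   `metadata.json` next to the stack.
#' @return A [session_recording()]; the sidecar metadata is attached as
#'   attribute `"metadata"` and any stored ground truth as `"truth"`.
#' @export
read_session <- function(stack_path,
                         metadata_path = file.path(dirname(stack_path),
                                                   "metadata.json")) {
  if (!file.exists(stack_path)) {
    stop(sprintf("stack file not found: %s", stack_path), call. = FALSE)
  }
  if (!file.exists(metadata_path)) {
    stop(sprintf("metadata file not found: %s", metadata_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (key in c("geometry", "stack_fps", "pre_min", "injection_time",
                "intensity_scale")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("metadata is missing required field `%s`", key),
           call. = FALSE)
    }
  }
  if (meta$stack_fps <= 0) {
    stop("metadata field `stack_fps` must be > 0", call. = FALSE)
  }
  pages <- tiff::readTIFF(stack_path, all = TRUE)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("ragged TIFF pages: all pages must share one dimension",
         call. = FALSE)
  }
  geom <- sensor_geometry(meta$geometry$n_rows, meta$geometry$n_cols,
                          meta$geometry$pixel_pitch, meta$geometry$fps)
  if (dims[1, 1] != geom$n_rows || dims[2, 1] != geom$n_cols) {
    stop("TIFF page dimensions do not match the metadata geometry",
         call. = FALSE)
  }
  n <- length(pages)
  frames <- array(NA_real_, dim = c(n, geom$n_rows, geom$n_cols))
  for (f in seq_len(n)) frames[f, , ] <- pages[[f]] * meta$intensity_scale
  ts <- meta$injection_time - meta$pre_min +
    (seq_len(n) - 0.5) / (60 * meta$stack_fps)
  rec <- session_recording(frames, ts, geom,
                           injection_time = meta$injection_time,
                           label = meta$drug_label %||% "")
  attr(rec, "metadata") <- meta
  if (!is.null(meta$truth)) attr(rec, "truth") <- meta$truth
  rec
}

#' Write analysis tables, JSON results and figures with a manifest
#'
#' Writes each element of `tables` as CSV, each element of `results` as
#' JSON, and calls each element of `figures` (a function taking a file path)
#' to render a PNG. Returns a manifest data frame listing every artifact
#' with its MD5 content hash; identical inputs produce identical hashes.
#'
#' @param out_dir Output directory (created if needed).
#' @param tables Named list of data frames or matrices.
#' @param results Named list of JSON-serialisable objects.
#' @param figures Named list of functions `function(path)` that render a
#'   figure to `path`.
#' @return Data frame with columns `file` and `md5`.
#' @export
write_results <- function(out_dir, tables = list(), results = list(),
                          figures = list()) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    x <- tables[[nm]]
    if (is.matrix(x)) x <- as.data.frame(x)
    utils::write.csv(x, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(results[[nm]], p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", force = TRUE)
    paths <- c(paths, p)
  }
  for (nm in names(figures)) {
    p <- file.path(out_dir, paste0(nm, ".png"))
    figures[[nm]](p)
    paths <- c(paths, p)
  }
  data.frame(file = basename(paths),
             md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Serialise an ROI set to a plain list (for JSON output)
#'
#' @param rois A [detect_rois()] result.
#' @return A list with one entry per ROI: id, pixel list (row/col pairs),
#'   centroid and area.
#' @export
roi_set_to_list <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  lapply(rois$rois, function(r) list(
    id = r$id,
    pixels = apply(r$pixels, 1, function(p) list(row = p[1], col = p[2]),
                   simplify = FALSE),
    centroid = list(row = unname(r$centroid[1]), col = unname(r$centroid[2])),
    area = r$area))
}
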