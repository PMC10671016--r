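#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Every parameter is checked
#' at construction, before any computation or I/O. Defaults mirror the
#' analysis conventions used throughout the package: 5-min interval images,
#' 15-min interval traces, F0 from the 15 minutes immediately before the
#' injection.
#'
#' @param out_dir Output directory for all artifacts.
#' @param sessions Data frame with columns `drug`
#'   (`morphine_like`/`cocaine_like`/`saline`), `seed` (integer) and
#'   optionally `animal_id`; one row per session to simulate and analyze.
#' @param geometry A [sensor_geometry()].
#' @param sim Named list of overrides passed to [simulation_params()]
#'   (e.g. `pre_min`, `post_min`, `sim_fps`, noise levels).
#' @param f0_window Baseline window `(start, end)` in minutes.
#' @param image_interval Width of the averaged-image intervals, minutes.
#' @param trace_interval Width of the trace/stats intervals, minutes.
#' @param roi A [roi_params()].
#' @param p_adjust Post-hoc adjustment (see [rm_anova()]).
#' @param write_figures Render PNG figures (disable for speed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sessions = data.frame(
                              drug = rep(c("morphine_like", "cocaine_like",
                                           "saline"), each = 3),
                              seed = rep(1:3, 3)),
                            geometry = sensor_geometry(),
                            sim = list(),
                            f0_window = c(-15, 0),
                            image_interval = 5,
                            trace_interval = 15,
                            roi = roi_params(),
                            p_adjust = "holm",
                            write_figures = TRUE) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  if (!is.data.frame(sessions) ||
      !all(c("drug", "seed") %in% names(sessions)) || nrow(sessions) < 1) {
    stop("`sessions` must be a data frame with columns drug, seed",
         call. = FALSE)
  }
  if (!all(sessions$drug %in% c("morphine_like", "cocaine_like", "saline"))) {
    stop("unknown drug class in `sessions`", call. = FALSE)
  }
  if (is.null(sessions$animal_id)) {
    sessions$animal_id <- paste0(sub("_like", "", sessions$drug), "_",
                                 sessions$seed)
  }
  if (anyDuplicated(sessions$animal_id)) {
    stop("`animal_id` values must be unique", call. = FALSE)
  }
  if (image_interval <= 0 || trace_interval <= 0) {
    stop("interval widths must be > 0", call. = FALSE)
  }
  stopifnot(inherits(geometry, "sensor_geometry"),
            inherits(roi, "roi_params"), is.list(sim))
  p_adjust <- match.arg(p_adjust, c("holm", "bonferroni", "none"))
  structure(
    list(out_dir = out_dir, sessions = sessions, geometry = geometry,
         sim = sim, f0_window = f0_window, image_interval = image_interval,
         trace_interval = trace_interval, roi = roi, p_adjust = p_adjust,
         write_figures = write_figures),
    class = "pipeline_config")
}

# Simulate, preprocess and analyze one configured session.
analyze_session <- function(config, row) {
  drug <- config$sessions$drug[row]
  seed <- config$sessions$seed[row]
  args <- c(list(geometry = config$geometry,
                 kinetics = kinetic_profile(drug), seed = seed), config$sim)
  sim <- simulate_session(do.call(simulation_params, args))
  f0 <- compute_f0(sim$recording, config$f0_window)
  dff <- compute_dff(sim$recording, f0)
  rois <- detect_rois(dff, config$roi)
  traces <- extract_traces(dff, rois, config$trace_interval)
  trace <- average_intervals(dff, config$trace_interval, mode = "trace")
  images <- average_intervals(dff, config$image_interval, mode = "images")
  list(sim = sim, f0 = f0, dff = dff, rois = rois, roi_traces = traces,
       whole_trace = trace, interval_images = images,
       metrics = profile_metrics(trace))
}

#' Run the full simulate-process-ROI-stats pipeline
#'
#' For every configured session: simulate it, write the stack and sidecar,
#' compute per-pixel dF/F0 against the configured baseline window, average
#' into interval images and traces, detect ROIs, extract the ROI heatmap
#' matrix and profile metrics. Then, per drug group with at least two
#' animals, build the repeated-measures table and run [rm_anova()] with
#' post-hoc comparisons against the pre-injection control. All tables,
#' JSON results and figures are written under `config$out_dir` together
#' with a manifest of content hashes and a run log; identical configs give
#' identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `sessions` (per-session results),
#'   `groups` (per-drug stats), `manifest` (file hash table) and
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  config_hash <- substr(md5_string(cfg_json), 1, 12)
  log_lines <- c(sprintf("run_pipeline config %s at %s", config_hash,
                         format(t0, "%Y-%m-%d %H:%M:%S")),
                 sprintf("R %s, cmosdff %s", getRversion(),
                         as.character(utils::packageVersion("cmosdff"))))

  sessions <- list()
  for (row in seq_len(nrow(config$sessions))) {
    id <- config$sessions$animal_id[row]
    res <- tryCatch(analyze_session(config, row), error = function(e) {
      stop(sprintf("stage `analyze` failed for session `%s`: %s", id,
                   conditionMessage(e)), call. = FALSE)
    })
    sdir <- file.path(config$out_dir, "sessions", id)
    write_session(res$sim$recording, sdir,
                  metadata = session_metadata(
                    fps = 1 / (60 * diff(res$sim$recording$timestamps[1:2])),
                    baseline_window = config$f0_window,
                    drug_label = config$sessions$drug[row], animal_id = id,
                    pre_min = res$sim$truth$params$pre_min,
                    seed = config$sessions$seed[row]),
                  truth = res$sim$truth)
    tabs <- list(
      whole_trace = data.frame(time_min = res$whole_trace$labels,
                               dff_pct = res$whole_trace$values),
      roi_heatmap = heatmap_table(res$roi_traces))
    jsons <- list(rois = roi_set_to_list(res$rois),
                  profile_metrics = unclass(res$metrics))
    figs <- list()
    if (config$write_figures) {
      figs <- list(
        heatmap = function(p) render_heatmap(res$roi_traces, p),
        roi_overlay = function(p) render_roi_overlay(res$rois, p),
        interval_images = function(p)
          render_interval_images(res$interval_images, p))
    }
    manifest_s <- write_results(sdir, tables = tabs, results = jsons,
                                figures = figs)
    manifest_s$file <- file.path("sessions", id, manifest_s$file)
    res$dff <- NULL; res$sim$recording$frames <- NULL  # free the big arrays
    sessions[[id]] <- c(res, list(manifest = manifest_s))
    log_lines <- c(log_lines, sprintf(
      "session %s: %d ROIs, peak %.2f%% at %g min", id,
      length(res$rois$rois), res$metrics$peak_value, res$metrics$peak_label))
  }

  groups <- list()
  for (drug in unique(config$sessions$drug)) {
    ids <- config$sessions$animal_id[config$sessions$drug == drug]
    if (length(ids) < 2) next
    table <- build_group_table(
      lapply(stats::setNames(ids, ids), function(i)
        sessions[[i]]$whole_trace))
    fit <- rm_anova(table, p_adjust = config$p_adjust)
    report <- significance_report(fit)
    gdir <- file.path(config$out_dir, "groups", drug)
    figs <- if (config$write_figures) {
      list(group_bars = function(p)
        render_group_bars(report, p, main = drug))
    } else list()
    manifest_g <- write_results(
      gdir,
      tables = list(group_table = group_table_df(table),
                    significance = report),
      results = list(anova = list(
        f_stat = fit$f_stat, df_time = fit$df_time, df_error = fit$df_error,
        p_omnibus = fit$p_omnibus, degenerate = fit$degenerate,
        posthoc = fit$posthoc)),
      figures = figs)
    manifest_g$file <- file.path("groups", drug, manifest_g$file)
    groups[[drug]] <- list(table = table, fit = fit, report = report,
                           manifest = manifest_g)
    log_lines <- c(log_lines, sprintf(
      "group %s (n=%d): F(%d,%d)=%.2f, p=%.3g", drug, length(ids),
      fit$df_time, fit$df_error, fit$f_stat, fit$p_omnibus))
  }

  manifest <- do.call(rbind, c(lapply(sessions, `[[`, "manifest"),
                               lapply(groups, `[[`, "manifest")))
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines, sprintf("done in %.1f s",
                                    as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(sessions = sessions, groups = groups, manifest = manifest,
                 config_hash = config_hash))
}

md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}

heatmap_table <- function(traces) {
  df <- as.data.frame(traces$values)
  names(df) <- paste0("t", traces$labels)
  cbind(data.frame(roi_id = rownames(traces$values)), df)
}

group_table_df <- function(table) {
  df <- as.data.frame(table$values)
  cbind(data.frame(animal_id = table$animals), df)
}

#' Compare two drug groups side by side
#'
#' Joins the group-mean whole-image interval traces of two completed
#' pipeline runs (or two groups of one run) and reports the profile
#' metrics of each group mean: peak label, time to half rise, baseline
#' crossing and undershoot minimum.
#'
#' @param group_a,group_b Elements of `run_pipeline()$groups` (lists with a
#'   `table` component).
#' @param names Length-2 character vector naming the two groups.
#' @return A list with `traces` (data frame: time_min and one mean column
#'   per group) and `metrics` (data frame, one row per group).
#' @export
compare_drugs <- function(group_a, group_b, names = c("A", "B")) {
  ta <- group_a$table; tb <- group_b$table
  stopifnot(inherits(ta, "group_time_series"),
            inherits(tb, "group_time_series"))
  if (!isTRUE(all.equal(ta$labels, tb$labels))) {
    stop("groups were binned at different interval widths or spans",
         call. = FALSE)
  }
  mean_a <- colMeans(ta$values); mean_b <- colMeans(tb$values)
  metrics <- rbind(
    metrics_row(mean_a, ta$labels, names[1]),
    metrics_row(mean_b, tb$labels, names[2]))
  traces <- data.frame(time_min = ta$labels, a = mean_a, b = mean_b,
                       row.names = NULL)
  names(traces)[2:3] <- names
  list(traces = traces, metrics = metrics)
}

metrics_row <- function(values, labels, name) {
  m <- profile_metrics(values, labels)
  data.frame(group = name, peak_label = m$peak_label,
             peak_value = m$peak_value,
             time_to_half_rise = m$time_to_half_rise,
             baseline_crossing = m$baseline_crossing,
             undershoot_min = m$undershoot_min, stringsAsFactors = FALSE)
}
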