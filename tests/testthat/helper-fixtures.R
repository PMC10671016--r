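# Small in-code fixtures shared across tests.

# Build a session_recording from a frames x rows x cols array with uniform
# frame-centre timestamps at `fpm` frames per minute starting pre_min before
# the injection.
make_recording <- function(frames, pre_min = 5, fpm = 1,
                           geometry = sensor_geometry(dim(frames)[2],
                                                      dim(frames)[3])) {
  n <- dim(frames)[1]
  ts <- -pre_min + (seq_len(n) - 0.5) / fpm
  session_recording(frames, ts, geometry)
}

# Constant-intensity recording.
constant_recording <- function(value = 100, n_frames = 10, n_rows = 4,
                               n_cols = 5, pre_min = 5, fpm = 1) {
  make_recording(array(value, dim = c(n_frames, n_rows, n_cols)),
                 pre_min = pre_min, fpm = fpm)
}

# Assemble a dff_stack directly (bypassing compute_dff) for unit tests of
# downstream operations.
make_dff <- function(values, timestamps, valid = NULL) {
  stopifnot(length(dim(values)) == 3, dim(values)[1] == length(timestamps))
  if (is.null(valid)) valid <- matrix(TRUE, dim(values)[2], dim(values)[3])
  structure(list(values = values, timestamps = timestamps, valid = valid,
                 geometry = sensor_geometry(dim(values)[2], dim(values)[3])),
            class = "dff_stack")
}

# Short default-noise synthetic session plus its dff stack.
quick_session <- function(drug = "morphine_like", seed = 1, post_min = 60,
                          sim_fps = 0.1, geometry = sensor_geometry(), ...) {
  sim <- simulate_session(simulation_params(
    geometry = geometry, kinetics = kinetic_profile(drug), seed = seed,
    post_min = post_min, sim_fps = sim_fps, ...))
  dff <- compute_dff(sim$recording, compute_f0(sim$recording))
  list(sim = sim, dff = dff)
}

# Group table from a bare animals x labels matrix (first column = pre).
make_table_acc <- function(x) {
  labels <- c(0, seq_len(ncol(x) - 1) * 15)
  traces <- lapply(seq_len(nrow(x)), function(i)
    list(labels = labels, values = x[i, ]))
  names(traces) <- paste0("a", seq_len(nrow(x)))
  build_group_table(traces)
}

# Interval trace of one desk-scale session (used by the group-stats tests).
session_trace <- function(drug = "saline", seed = 1, geometry = sensor_geometry(10, 12),
                          post_min = 90, sim_fps = 1/30, width = 15, ...) {
  sim <- simulate_session(simulation_params(
    geometry = geometry, kinetics = kinetic_profile(drug, ...), seed = seed,
    post_min = post_min, sim_fps = sim_fps))
  dff <- compute_dff(sim$recording, compute_f0(sim$recording))
  average_intervals(dff, width, mode = "trace")
}
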