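#' Session recording container
#'
#' Holds a raw multi-frame intensity stack together with its timing and
#' geometry. Frames are stored as an `n_frames x n_rows x n_cols` array of
#' non-negative counts; timestamps are minutes relative to the injection
#' (negative = pre-injection) and must be strictly increasing and uniformly
#' spaced.
#'
#' @param frames Numeric array `n_frames x n_rows x n_cols`, finite and >= 0.
#' @param timestamps Numeric vector of frame-centre times in minutes.
#' @param geometry A [sensor_geometry()].
#' @param injection_time Injection time in minutes (0 by convention).
#' @param label Free-text label (e.g. drug and animal id).
#'
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(frames, timestamps, geometry,
                              injection_time = 0, label = "") {
  stopifnot(inherits(geometry, "sensor_geometry"))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-d array (frame, row, col)", call. = FALSE)
  }
  d <- dim(frames)
  if (d[2] != geometry$n_rows || d[3] != geometry$n_cols) {
    stop(sprintf("frame dimensions %d x %d do not match geometry %d x %d",
                 d[2], d[3], geometry$n_rows, geometry$n_cols), call. = FALSE)
  }
  if (length(timestamps) != d[1]) {
    stop("`timestamps` length must equal the number of frames", call. = FALSE)
  }
  if (d[1] > 1) {
    dt <- diff(timestamps)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing",
                           call. = FALSE)
    if (max(dt) - min(dt) > 1e-9 * max(dt)) {
      stop("timestamps must be uniformly spaced", call. = FALSE)
    }
  }
  if (any(!is.finite(frames)) || any(frames < 0)) {
    stop("frames must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         injection_time = injection_time, geometry = geometry, label = label),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<session_recording> '%s': %d frames of %d x %d px, t = [%.2f, %.2f] min\n",
              x$label, d[1], d[2], d[3], min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Parameters of the synthetic session generator
#'
#' Collects everything [simulate_session()] needs: sensor geometry, the drug
#' kinetic profile, the spatial release-site model, baseline illumination,
#' noise, and the recording window. Defaults give a desk-scale session: 15
#' minutes pre-injection and 225 minutes post-injection sampled at one frame
#' per five seconds (`sim_fps = 0.2`), on the full 40 x 90 sensor.
#'
#' Release sites stand in for localized dopamine release hotspots: each is a
#' Gaussian spatial footprint of width `sigma` (drawn uniformly from
#' `site_sigma_range`) and a gain multiplier on the session kinetic amplitude
#' (drawn uniformly from `site_gain_range`), placed uniformly at random in
#' the frame. All pixels additionally see the kinetic transient scaled by
#' `background_coupling`, emulating diffuse neuropil fluorescence.
#'
#' @param geometry A [sensor_geometry()].
#' @param kinetics A [kinetic_profile()].
#' @param n_sites Number of release sites.
#' @param site_sigma_range Length-2 range of site footprint widths, pixels.
#' @param site_gain_range Length-2 range of site gain multipliers.
#' @param baseline_mean Mean baseline intensity, counts.
#' @param illumination_gradient Fractional linear drop of the baseline across
#'   rows (top of frame brighter by half the gradient, bottom dimmer).
#' @param bleaching_tau Photobleaching time constant in minutes, or `NULL`
#'   for no bleaching (default).
#' @param read_noise_sd Gaussian read-noise standard deviation, counts.
#' @param shot_noise_gain Variance of the signal-proportional noise per unit
#'   intensity; its standard deviation is `sqrt(shot_noise_gain * signal)`.
#' @param background_coupling Fraction of the kinetic transient seen by all
#'   pixels, on top of the site footprints.
#' @param pre_min Minutes recorded before the injection.
#' @param post_min Minutes recorded after the injection.
#' @param sim_fps Simulated frame rate, frames per second; must not exceed
#'   `geometry$fps`.
#' @param seed Integer seed; identical parameters give bit-identical output.
#'
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(geometry = sensor_geometry(),
                              kinetics = kinetic_profile("morphine_like"),
                              n_sites = 6,
                              site_sigma_range = c(1.5, 3),
                              site_gain_range = c(0.75, 1.25),
                              baseline_mean = 1000,
                              illumination_gradient = 0.10,
                              bleaching_tau = NULL,
                              read_noise_sd = 5,
                              shot_noise_gain = 0.1,
                              background_coupling = 0.3,
                              pre_min = 15, post_min = 225,
                              sim_fps = 0.2, seed = 1L) {
  stopifnot(inherits(geometry, "sensor_geometry"),
            inherits(kinetics, "kinetic_profile"))
  if (pre_min <= 0 || post_min <= 0) {
    stop("`pre_min` and `post_min` must be > 0", call. = FALSE)
  }
  if (sim_fps <= 0 || sim_fps > geometry$fps) {
    stop("`sim_fps` must be in (0, geometry$fps]", call. = FALSE)
  }
  if (read_noise_sd < 0 || shot_noise_gain < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (baseline_mean <= 0) stop("`baseline_mean` must be > 0", call. = FALSE)
  if (n_sites < 0 || n_sites != round(n_sites)) {
    stop("`n_sites` must be a non-negative integer", call. = FALSE)
  }
  if (length(site_sigma_range) != 2L || any(site_sigma_range <= 0) ||
      site_sigma_range[1] > site_sigma_range[2]) {
    stop("`site_sigma_range` must be an increasing positive range",
         call. = FALSE)
  }
  if (length(site_gain_range) != 2L || any(site_gain_range <= 0) ||
      site_gain_range[1] > site_gain_range[2]) {
    stop("`site_gain_range` must be an increasing positive range",
         call. = FALSE)
  }
  if (!is.null(bleaching_tau) && bleaching_tau <= 0) {
    stop("`bleaching_tau` must be > 0 or NULL", call. = FALSE)
  }
  if (background_coupling < 0) {
    stop("`background_coupling` must be >= 0", call. = FALSE)
  }
  structure(
    list(geometry = geometry, kinetics = kinetics, n_sites = as.integer(n_sites),
         site_sigma_range = site_sigma_range, site_gain_range = site_gain_range,
         baseline_mean = baseline_mean,
         illumination_gradient = illumination_gradient,
         bleaching_tau = bleaching_tau, read_noise_sd = read_noise_sd,
         shot_noise_gain = shot_noise_gain,
         background_coupling = background_coupling,
         pre_min = pre_min, post_min = post_min, sim_fps = sim_fps,
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

# Frame-centre timestamps in minutes for a pre/post window at rate fps (Hz).
# floor(D * 60 * fps) frames over duration D minutes, centres at
# -pre_min + (k + 0.5) / (60 * fps).
session_timestamps <- function(pre_min, post_min, fps) {
  n <- floor((pre_min + post_min) * 60 * fps)
  -pre_min + (seq_len(n) - 0.5) / (60 * fps)
}

# Baseline illumination image: linear gradient along rows, mean baseline_mean.
baseline_image <- function(geometry, baseline_mean, illumination_gradient) {
  nr <- geometry$n_rows
  rowfac <- if (nr == 1) 1 else
    1 + illumination_gradient * (0.5 - (seq_len(nr) - 1) / (nr - 1))
  matrix(baseline_mean * rowfac, nr, geometry$n_cols)
}

# Per-pixel coupling map: sum of Gaussian site footprints plus the diffuse
# background coupling.
coupling_map <- function(geometry, sites, background_coupling) {
  nr <- geometry$n_rows; nc <- geometry$n_cols
  cmap <- matrix(background_coupling, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (s in sites) {
    d2 <- (rows - s$center_row)^2 + (cols - s$center_col)^2
    cmap <- cmap + s$gain * exp(-d2 / (2 * s$sigma^2))
  }
  cmap
}

#' Simulate a recording session with ground truth
#'
#' Generates a [session_recording()] whose pixel intensities follow
#' `baseline(r, c) * bleach(t) * (1 + coupling(r, c) * kinetic(t)) + noise`,
#' where the coupling map is the sum of Gaussian release-site footprints plus
#' a diffuse background term, the kinetic transient comes from
#' [kinetic_value()], and noise is Gaussian read noise plus a
#' variance-proportional shot-noise-like term. Negative noisy counts are
#' clipped at zero. The same `simulation_params` (including the seed) always
#' produce a bit-identical stack; the RNG state of the caller is left
#' untouched.
#'
#' @param params A [simulation_params()] object.
#' @return A list with components:
#' \describe{
#'   \item{recording}{the [session_recording()];}
#'   \item{truth}{a `simulation_truth` list carrying the planted `sites`
#'     (centre, sigma, gain), the noiseless `kinetic_curve` (fraction, one
#'     value per frame), the coupling map, the baseline image and a copy of
#'     the parameters.}
#' }
#' @export
#' @examples
#' sim <- simulate_session(simulation_params(
#'   geometry = sensor_geometry(8, 12), pre_min = 5, post_min = 10,
#'   sim_fps = 0.1, seed = 42))
#' sim$recording
simulate_session <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  geom <- params$geometry
  ts <- session_timestamps(params$pre_min, params$post_min, params$sim_fps)
  n_frames <- length(ts)
  if (n_frames < 1) stop("recording window contains no frames", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  sites <- replicate(params$n_sites, simplify = FALSE, {
    list(center_row = runif(1, 1, geom$n_rows),
         center_col = runif(1, 1, geom$n_cols),
         sigma = runif(1, params$site_sigma_range[1],
                       params$site_sigma_range[2]),
         gain = runif(1, params$site_gain_range[1], params$site_gain_range[2]))
  })

  base <- baseline_image(geom, params$baseline_mean,
                         params$illumination_gradient)
  cmap <- coupling_map(geom, sites, params$background_coupling)
  kin <- kinetic_value(params$kinetics, ts)
  bleach <- if (is.null(params$bleaching_tau)) rep(1, n_frames) else
    exp(-(ts - ts[1]) / params$bleaching_tau)

  # frames x pixels matrix, pixels in column-major (row fastest) order
  clean <- outer(bleach, as.vector(base)) *
    (1 + outer(kin, as.vector(cmap)))
  # read noise and signal-proportional noise are independent Gaussians, so
  # one draw at the combined standard deviation is equivalent
  noisy <- clean
  if (params$read_noise_sd > 0 || params$shot_noise_gain > 0) {
    noisy <- noisy + stats::rnorm(length(clean)) *
      sqrt(params$read_noise_sd^2 +
             params$shot_noise_gain * pmax(clean, 0))
    noisy[noisy < 0] <- 0
  }

  rec <- session_recording(
    frames = array(noisy, dim = c(n_frames, geom$n_rows, geom$n_cols)),
    timestamps = ts, geometry = geom, injection_time = 0,
    label = params$kinetics$drug_class)
  truth <- structure(
    list(sites = sites, kinetic_curve = kin, timestamps = ts,
         coupling = cmap, baseline = base, params = params),
    class = "simulation_truth")
  list(recording = rec, truth = truth)
}
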