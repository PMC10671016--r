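#' Drug kinetic profile for the session generator
#'
#' Parametrises the noiseless whole-field dopamine transient used by
#' [simulate_session()]. The post-injection time course is a normalized
#' Bateman (difference-of-exponentials) absorption--elimination transient of
#' peak fractional amplitude `amplitude`, minus a logistic late undershoot
#' that models the sub-baseline drift seen after the drug effect wanes.
#' A rectangular negative offset of depth `artifact_depth` over the first
#' `artifact_duration` minutes after the injection models the handling dip
#' seen in the first post-injection 5-min interval image. Keeping the dip
#' strictly post-injection leaves the pre-injection baseline clean, so F0
#' computed from the default window is unbiased.
#'
#' Defaults by drug class:
#' * `morphine_like`: slow GABA-disinhibition-style transient, amplitude 0.10,
#'   rise 18 min, decay 90 min, undershoot 0.015 setting in around 150 min.
#' * `cocaine_like`: fast reuptake-block-style transient, amplitude 0.12,
#'   rise 8 min, decay 50 min, with a sharper and deeper undershoot (0.04)
#'   around 130 min.
#' * `saline`: amplitude and undershoot 0; only the injection artifact remains.
#'
#' @param drug_class One of `"morphine_like"`, `"cocaine_like"`, `"saline"`.
#' @param amplitude Peak dF/F0 as a dimensionless fraction (0.10 = 10%).
#' @param tau_rise,tau_decay Bateman time constants in minutes; must satisfy
#'   `tau_rise < tau_decay`.
#' @param undershoot_depth Depth of the late sub-baseline plateau (fraction,
#'   >= 0).
#' @param undershoot_onset Centre of the logistic undershoot step, minutes
#'   post-injection.
#' @param undershoot_sharpness Logistic time scale of the undershoot, minutes.
#' @param artifact_depth Depth of the injection-handling dip (fraction >= 0).
#' @param artifact_duration Duration of the handling dip, minutes; the dip
#'   spans `[0, artifact_duration)`.
#'
#' @return An object of class `kinetic_profile`.
#' @seealso [kinetic_value()], [simulate_session()]
#' @export
#' @examples
#' kp <- kinetic_profile("morphine_like")
#' kinetic_value(kp, c(-10, 10, 36.2, 200))
kinetic_profile <- function(drug_class = c("morphine_like", "cocaine_like",
                                           "saline"),
                            amplitude = NULL, tau_rise = NULL, tau_decay = NULL,
                            undershoot_depth = NULL, undershoot_onset = NULL,
                            undershoot_sharpness = NULL,
                            artifact_depth = 0.02, artifact_duration = 5) {
  drug_class <- match.arg(drug_class)
  def <- switch(drug_class,
    morphine_like = list(amplitude = 0.10, tau_rise = 18, tau_decay = 90,
                         undershoot_depth = 0.015, undershoot_onset = 150,
                         undershoot_sharpness = 20),
    cocaine_like = list(amplitude = 0.12, tau_rise = 8, tau_decay = 50,
                        undershoot_depth = 0.04, undershoot_onset = 130,
                        undershoot_sharpness = 8),
    saline = list(amplitude = 0, tau_rise = 18, tau_decay = 90,
                  undershoot_depth = 0, undershoot_onset = 150,
                  undershoot_sharpness = 20)
  )
  p <- list(
    drug_class = drug_class,
    amplitude = amplitude %||% def$amplitude,
    tau_rise = tau_rise %||% def$tau_rise,
    tau_decay = tau_decay %||% def$tau_decay,
    undershoot_depth = undershoot_depth %||% def$undershoot_depth,
    undershoot_onset = undershoot_onset %||% def$undershoot_onset,
    undershoot_sharpness = undershoot_sharpness %||% def$undershoot_sharpness,
    artifact_depth = artifact_depth,
    artifact_duration = artifact_duration
  )
  validate_kinetic_profile(p)
  structure(p, class = "kinetic_profile")
}

validate_kinetic_profile <- function(p) {
  if (p$tau_rise >= p$tau_decay) {
    stop("invalid kinetic profile: `tau_rise` must be < `tau_decay`",
         call. = FALSE)
  }
  if (p$tau_rise <= 0 || p$tau_decay <= 0 || p$undershoot_onset <= 0 ||
      p$undershoot_sharpness <= 0) {
    stop("invalid kinetic profile: time constants must be > 0", call. = FALSE)
  }
  if (p$undershoot_depth < 0 || p$artifact_depth < 0 ||
      p$artifact_duration < 0) {
    stop("invalid kinetic profile: depths and durations must be >= 0",
         call. = FALSE)
  }
  if (p$drug_class == "saline" &&
      (p$amplitude != 0 || p$undershoot_depth != 0)) {
    stop("saline profile requires amplitude = 0 and undershoot_depth = 0",
         call. = FALSE)
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time of the Bateman peak
#'
#' Closed-form argmax of `exp(-t/tau_decay) - exp(-t/tau_rise)`:
#' `tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)`.
#'
#' @param tau_rise,tau_decay Time constants in minutes, `tau_rise < tau_decay`.
#' @return Peak time in minutes post-injection.
#' @export
bateman_peak_time <- function(tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Evaluate the noiseless kinetic transient
#'
#' For `t <= 0` the transient is zero; for `t > 0` it is
#' `amplitude * B(t) - undershoot_depth * S(t)`, where `B(t)` is the
#' Bateman difference of exponentials normalized to unit maximum and `S(t)`
#' is a logistic step centred at `undershoot_onset`. The handling dip
#' subtracts `artifact_depth` for `0 <= t < artifact_duration`. The
#' function is vectorised over `t`.
#'
#' @param profile A [kinetic_profile()].
#' @param t Time(s) in minutes relative to injection (negative = before).
#' @return dF/F0 as a dimensionless fraction, same length as `t`.
#' @export
kinetic_value <- function(profile, t) {
  stopifnot(inherits(profile, "kinetic_profile"), is.numeric(t))
  validate_kinetic_profile(profile)
  out <- numeric(length(t))
  post <- t > 0
  if (any(post)) {
    tp <- t[post]
    bmax_t <- bateman_peak_time(profile$tau_rise, profile$tau_decay)
    bmax <- exp(-bmax_t / profile$tau_decay) - exp(-bmax_t / profile$tau_rise)
    b <- (exp(-tp / profile$tau_decay) - exp(-tp / profile$tau_rise)) / bmax
    s <- 1 / (1 + exp(-(tp - profile$undershoot_onset) /
                        profile$undershoot_sharpness))
    out[post] <- profile$amplitude * b - profile$undershoot_depth * s
  }
  dip <- t >= 0 & t < profile$artifact_duration
  out[dip] <- out[dip] - profile$artifact_depth
  out
}

#' @export
print.kinetic_profile <- function(x, ...) {
  cat(sprintf(
    "<kinetic_profile> %s: A=%g, tau_rise=%g min, tau_decay=%g min,\n  undershoot %g @ %g min (scale %g), artifact %g for %g min\n",
    x$drug_class, x$amplitude, x$tau_rise, x$tau_decay, x$undershoot_depth,
    x$undershoot_onset, x$undershoot_sharpness, x$artifact_depth,
    x$artifact_duration))
  invisible(x)
}
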