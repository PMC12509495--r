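#' Synthetic-session generator configuration
#'
#' Builds the configuration object consumed by [simulate_trajectory()],
#' [simulate_ethogram()], [simulate_ground_truth()] and
#' [render_photometry()].  Defaults describe a 15 min object-location-memory
#' (ObLoM) session in a 40 x 40 cm arena, recorded at 610 Hz (photometry)
#' and 30 fps (video), with the latent cholinergic signal composed of a
#' log2-speed term, behavioral-state terms (grooming suppression, rearing
#' elevation), phasic novelty transients during object-exploration bouts,
#' an exponentially decaying session-start recency term, and
#' fast Ornstein-Uhlenbeck intrinsic noise and a slow speed-independent
#' drift in cholinergic tone.
#'
#' @param seed integer; master seed for the session.  All generator stages
#'   derive their own sub-seed from it, so a given seed fully determines the
#'   session.
#' @param phase `"sample"` or `"test"`.  In the test phase the nonstationary
#'   object sits at a novel location and early exploration is biased toward
#'   it (see `test_preference`).
#' @param session_duration seconds (>= 60); default 900.
#' @param photometry_rate Hz; default 610.
#' @param video_rate frames per second; default 30.
#' @param arena_size cm (square arena); default 40.
#' @param object_centers named list with `sample` and `test` elements, each a
#'   list with `stat` and `nonstat` (x, y) centers in cm.  The stationary
#'   object keeps its place across phases.
#' @param beta_speed z-units per log2(cm/s); default 0.25.
#' @param beta_groom z-units (negative); default -0.75.
#' @param beta_rear z-units (positive); default 0.15.
#' @param novelty_amp z-units added during novelty-carrying object bouts;
#'   default 0.5.
#' @param novelty_assignment `"phase_dependent"` (both objects carry
#'   transients in the sample phase, only the nonstationary object in the
#'   test phase), `"symmetric"` (both objects in both phases) or `"none"`.
#' @param recency_amp amplitude A (z-units) of the session-start recency
#'   term `A * exp(-t / recency_tau)`; default 2.
#' @param recency_tau time constant (seconds) of the recency term; default 28.
#' @param noise_sd stationary standard deviation (z-units) of the
#'   Ornstein-Uhlenbeck intrinsic noise; default 0.5.
#' @param ou_timescale relaxation time (seconds) of the intrinsic noise;
#'   default 2.
#' @param drift_sd stationary standard deviation (z-units) of a slow
#'   speed-independent drift in cholinergic tone (state changes, slow
#'   physiological and instrumental variation); default 0.6.
#' @param drift_timescale relaxation time (seconds) of the slow drift;
#'   default 150.
#' @param speed_floor cm/s floor applied before the log2 transform when the
#'   generator builds the latent speed term; default 1.
#' @param activity_lead seconds by which the structured (non-noise) part of
#'   the latent activity leads behavior; default 0.  Positive values shift
#'   activity earlier in time, emulating anticipatory cholinergic transients
#'   before movement onsets.
#' @param dwell named numeric vector of mean dwell times (seconds, > 2) per
#'   behavioral state (`locomotion`, `grooming`, `rearing`, `quiet`,
#'   `explore`).
#' @param state_probs named numeric vector of stationary transition
#'   probabilities over the same states; renormalized internally.
#' @param test_preference multiplier (> 0) on the probability that an
#'   exploration episode targets the nonstationary object during the first
#'   3 min of the test phase; default 3 (symmetric when 1).
#' @param explore_drive_amp,explore_drive_tau amplitude and time constant of
#'   the decaying exploratory-drive multiplier on target speed, producing
#'   elevated movement speed at session start (defaults 0.8 and 45 s).
#' @param re_sd named numeric vector of between-session random-effect
#'   standard deviations applied to the generating coefficients
#'   (`intercept`, `speed`, `grooming`, `rearing`, `objects`).  Set to zeros
#'   for sessions with identical coefficients.
#' @param bleach list describing the shared multiplicative photobleaching
#'   trend `B(t) = base * (b_inf + a1 exp(-t/tau1) + a2 exp(-t/tau2))`.
#' @param gain fractional fluorescence change per z-unit of latent activity
#'   in the 465 nm channel; default 0.04.
#' @param iso_scale brightness of the isosbestic channel relative to the
#'   bleaching trend (c0); default 0.7.
#' @param motion_amp amplitude (a.u.) of shared additive motion transients;
#'   default 3.
#' @param motion_rate Poisson rate (events/s) of motion transients;
#'   default 0.05.
#' @param photon_noise_sd additive measurement noise s.d. (a.u.) per
#'   channel; default 0.3.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(seed = 1, phase = "sample")
#' cfg$recency_tau
generator_config <- function(seed,
                             phase = c("sample", "test"),
                             session_duration = 900,
                             photometry_rate = 610,
                             video_rate = 30,
                             arena_size = 40,
                             object_centers = NULL,
                             beta_speed = 0.25,
                             beta_groom = -0.75,
                             beta_rear = 0.15,
                             novelty_amp = 0.5,
                             novelty_assignment = c("phase_dependent", "symmetric", "none"),
                             recency_amp = 2,
                             recency_tau = 28,
                             noise_sd = 0.5,
                             ou_timescale = 2,
                             drift_sd = 0.6,
                             drift_timescale = 150,
                             speed_floor = 1,
                             activity_lead = 0,
                             dwell = c(locomotion = 6, grooming = 8, rearing = 5,
                                       quiet = 5, explore = 6),
                             state_probs = c(locomotion = 0.32, grooming = 0.13,
                                             rearing = 0.15, quiet = 0.20,
                                             explore = 0.20),
                             test_preference = 3,
                             explore_drive_amp = 0.8,
                             explore_drive_tau = 45,
                             re_sd = c(intercept = 0.2, speed = 0.05,
                                       grooming = 0.15, rearing = 0.08,
                                       objects = 0.15),
                             bleach = list(base = 100, b_inf = 0.75,
                                           a1 = 0.05, tau1 = 60,
                                           a2 = 0.20, tau2 = 1000),
                             gain = 0.04,
                             iso_scale = 0.7,
                             motion_amp = 3,
                             motion_rate = 0.05,
                             photon_noise_sd = 0.3) {
  phase <- match.arg(phase)
  novelty_assignment <- match.arg(novelty_assignment)
  stopifnot_scalar(seed, "seed")
  stopifnot_scalar(session_duration, "session_duration", positive = TRUE)
  if (session_duration < 60) stop("session_duration must be >= 60 s", call. = FALSE)
  stopifnot_scalar(photometry_rate, "photometry_rate", positive = TRUE)
  stopifnot_scalar(video_rate, "video_rate", positive = TRUE)
  stopifnot_scalar(arena_size, "arena_size", positive = TRUE)
  stopifnot_scalar(recency_tau, "recency_tau", positive = TRUE)
  stopifnot_scalar(ou_timescale, "ou_timescale", positive = TRUE)
  stopifnot_scalar(test_preference, "test_preference", positive = TRUE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  states <- c("locomotion", "grooming", "rearing", "quiet", "explore")
  if (!all(states %in% names(dwell))) {
    stop("dwell must name all states: ", paste(states, collapse = ", "), call. = FALSE)
  }
  if (any(dwell[states] <= 2)) {
    stop("mean dwell times must exceed 2 s so filtered bouts exist", call. = FALSE)
  }
  if (!all(states %in% names(state_probs)) || any(state_probs[states] < 0)) {
    stop("state_probs must be nonnegative and name all states", call. = FALSE)
  }
  if (is.null(object_centers)) {
    object_centers <- default_object_centers(arena_size)
  }
  for (ph in c("sample", "test")) {
    for (ob in c("stat", "nonstat")) {
      ctr <- object_centers[[ph]][[ob]]
      if (length(ctr) != 2 || any(ctr < 0) || any(ctr > arena_size)) {
        stop("object centers must lie inside the arena", call. = FALSE)
      }
    }
  }
  re_names <- c("intercept", "speed", "grooming", "rearing", "objects")
  re_full <- setNames(numeric(length(re_names)), re_names)
  re_full[names(re_sd)[names(re_sd) %in% re_names]] <-
    re_sd[names(re_sd) %in% re_names]
  cfg <- list(
    seed = as.integer(seed), phase = phase,
    session_duration = session_duration,
    photometry_rate = photometry_rate, video_rate = video_rate,
    arena_size = arena_size, object_centers = object_centers,
    beta_speed = beta_speed, beta_groom = beta_groom, beta_rear = beta_rear,
    novelty_amp = novelty_amp, novelty_assignment = novelty_assignment,
    recency_amp = recency_amp, recency_tau = recency_tau,
    noise_sd = noise_sd, ou_timescale = ou_timescale,
    drift_sd = drift_sd, drift_timescale = drift_timescale,
    speed_floor = speed_floor, activity_lead = activity_lead,
    dwell = dwell[states], state_probs = state_probs[states] / sum(state_probs[states]),
    test_preference = test_preference,
    explore_drive_amp = explore_drive_amp, explore_drive_tau = explore_drive_tau,
    re_sd = re_full,
    bleach = bleach, gain = gain, iso_scale = iso_scale,
    motion_amp = motion_amp, motion_rate = motion_rate,
    photon_noise_sd = photon_noise_sd
  )
  class(cfg) <- "generator_config"
  cfg
}

default_object_centers <- function(arena_size) {
  lo <- 0.3 * arena_size
  hi <- 0.7 * arena_size
  list(
    sample = list(stat = c(lo, lo), nonstat = c(hi, lo)),
    test   = list(stat = c(lo, lo), nonstat = c(hi, hi))
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> seed=%d phase=%s duration=%gs rates=%g/%g Hz\n",
    x$seed, x$phase, x$session_duration, x$photometry_rate, x$video_rate))
  cat(sprintf(
    "  betas: speed=%g groom=%g rear=%g novelty=%g (%s)\n",
    x$beta_speed, x$beta_groom, x$beta_rear, x$novelty_amp,
    x$novelty_assignment))
  cat(sprintf("  recency: A=%g tau=%gs; noise: sd=%g ou=%gs\n",
              x$recency_amp, x$recency_tau, x$noise_sd, x$ou_timescale))
  invisible(x)
}

#' Objects for a configured session's phase
#'
#' @param cfg a [generator_config()].
#' @return list with `stat` and `nonstat` (x, y) centers (cm) for `cfg$phase`.
#' @export
session_objects <- function(cfg) {
  cfg$object_centers[[cfg$phase]]
}
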