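#' Latent cholinergic ground truth for a synthetic session
#'
#' Composes the latent activity (z-units, video clock) as
#' `z(t) = b0 + beta_speed * log2(max(speed, floor)) + beta_groom * I_groom +
#' beta_rear * I_rear + novelty_amp * I_novel + A * exp(-t / tau) +
#' OU noise + slow drift`,
#' where `I_novel` marks object-exploration frames that carry a novelty
#' transient under the configured assignment (both objects in the sample
#' phase, the nonstationary object only in the test phase).  Per-session
#' random deviations of the coefficients (`cfg$re_sd`) emulate
#' between-session variability in expression level and responsiveness.
#' A positive `cfg$activity_lead` shifts the structured components earlier
#' in time (anticipatory activity).
#'
#' @param cfg a [generator_config()].
#' @param traj trajectory from [simulate_trajectory()].
#' @param etho ethogram from [simulate_ethogram()].
#' @return list of class `ground_truth` with `z_true`, `t`, `rate`,
#'   `components` (named list of per-term series summing to `z_true`) and
#'   `coef` (the session's realized generating coefficients).
#' @export
simulate_ground_truth <- function(cfg, traj, etho) {
  with_seed(derive_seed(cfg$seed, 3L), {
    n <- nrow(traj)
    rate <- cfg$video_rate
    tt <- traj$t
    re <- cfg$re_sd
    coefs <- list(
      intercept = rnorm(1, 0, re[["intercept"]]),
      speed = cfg$beta_speed + rnorm(1, 0, re[["speed"]]),
      grooming = cfg$beta_groom + rnorm(1, 0, re[["grooming"]]),
      rearing = cfg$beta_rear + rnorm(1, 0, re[["rearing"]]),
      nov_stat = cfg$novelty_amp + rnorm(1, 0, re[["objects"]]),
      nov_nonstat = cfg$novelty_amp + rnorm(1, 0, re[["objects"]])
    )
    novel_flag <- switch(cfg$novelty_assignment,
      none = numeric(n),
      symmetric = coefs$nov_stat * etho$explore_stat +
                  coefs$nov_nonstat * etho$explore_nonstat,
      phase_dependent = if (cfg$phase == "sample") {
        coefs$nov_stat * etho$explore_stat +
          coefs$nov_nonstat * etho$explore_nonstat
      } else {
        coefs$nov_nonstat * etho$explore_nonstat
      })
    comp <- list(
      intercept = rep(coefs$intercept, n),
      speed = coefs$speed * log2(pmax(traj$speed, cfg$speed_floor)),
      grooming = coefs$grooming * etho$grooming,
      rearing = coefs$rearing * etho$rearing,
      novelty = novel_flag,
      recency = cfg$recency_amp * exp(-tt / cfg$recency_tau)
    )
    if (cfg$activity_lead > 0) {
      k <- round(cfg$activity_lead * rate)
      shift <- function(x) c(x[(k + 1):n], rep(x[n], k))
      comp <- lapply(comp, shift)
    }
    # Ornstein-Uhlenbeck intrinsic noise with stationary sd = noise_sd,
    # plus a slow speed-independent drift in cholinergic tone
    ou <- function(sd, theta) {
      if (sd <= 0) return(numeric(n))
      rho <- exp(-1 / (rate * theta))
      eps <- rnorm(n, 0, sd * sqrt(1 - rho^2))
      eps[1] <- rnorm(1, 0, sd)
      as.numeric(stats::filter(eps, rho, method = "recursive"))
    }
    comp$noise <- ou(cfg$noise_sd, cfg$ou_timescale)
    comp$drift <- ou(cfg$drift_sd, cfg$drift_timescale)
    z <- Reduce(`+`, comp)
    structure(list(z_true = z, t = tt, rate = rate,
                   components = comp, coef = coefs),
              class = "ground_truth")
  })
}

#' Render raw two-channel photometry from latent activity
#'
#' Forward model on the photometry clock:
#' `F465(t) = B(t) * (1 + g * z(t)) + M(t) + e1(t)` and
#' `F405(t) = c0 * B(t) + M(t) + e2(t)`, with `B(t)` a slow double-exponential
#' photobleaching trend shared (up to the scale `c0`) across channels, `M(t)`
#' shared additive motion transients (Poisson-timed biexponential pulses) and
#' `e` i.i.d. measurement noise.  The latent activity is linearly
#' interpolated from the video clock to the photometry clock.
#'
#' @param cfg a [generator_config()].
#' @param truth a [simulate_ground_truth()] result.
#' @return list of class `photometry_session` with `f465`, `f405`, `t`,
#'   `rate` and `meta`.
#' @export
render_photometry <- function(cfg, truth) {
  with_seed(derive_seed(cfg$seed, 4L), {
    rate <- cfg$photometry_rate
    np <- round(cfg$session_duration * rate)
    tp <- (seq_len(np) - 1) / rate
    z <- approx(truth$t, truth$z_true, xout = tp, rule = 2)$y
    bl <- cfg$bleach
    B <- bl$base * (bl$b_inf + bl$a1 * exp(-tp / bl$tau1) + bl$a2 * exp(-tp / bl$tau2))
    M <- numeric(np)
    if (cfg$motion_amp > 0 && cfg$motion_rate > 0) {
      n_ev <- rpois(1, cfg$motion_rate * cfg$session_duration)
      if (n_ev > 0) {
        ev_t <- runif(n_ev, 0, cfg$session_duration)
        ev_a <- -cfg$motion_amp * runif(n_ev, 0.5, 1.5)
        for (k in seq_len(n_ev)) {
          i0 <- floor(ev_t[k] * rate) + 1L
          i1 <- min(np, i0 + round(3 * rate))
          u <- tp[i0:i1] - ev_t[k]
          M[i0:i1] <- M[i0:i1] + ev_a[k] * (exp(-u / 0.5) - exp(-u / 0.05))
        }
      }
    }
    act <- 1 + cfg$gain * z
    if (any(act <= 0)) {
      stop("gain too large: modulated 465 nm signal would be nonpositive",
           call. = FALSE)
    }
    f465 <- B * act + M + rnorm(np, 0, cfg$photon_noise_sd)
    f405 <- cfg$iso_scale * B + M + rnorm(np, 0, cfg$photon_noise_sd)
    structure(list(f465 = f465, f405 = f405, t = tp, rate = rate,
                   meta = list(phase = cfg$phase)),
              class = "photometry_session")
  })
}

#' Generate a complete synthetic session
#'
#' Runs trajectory, ethogram, ground-truth and photometry generation for one
#' configured session.
#'
#' @param cfg a [generator_config()].
#' @param mouse_id,oblom_id,session_id identifiers stored in the session
#'   metadata.
#' @param render if `FALSE`, skip the raw photometry render (video-clock
#'   studies of downstream stages do not need it).
#' @return list of class `synth_session` with elements `config`,
#'   `trajectory`, `ethogram`, `truth`, `objects`, `meta` and (when rendered)
#'   `photometry`.
#' @export
simulate_session <- function(cfg, mouse_id = "m1", oblom_id = 1L,
                             session_id = NULL, render = TRUE) {
  traj <- simulate_trajectory(cfg)
  etho <- simulate_ethogram(cfg, traj)
  truth <- simulate_ground_truth(cfg, traj, etho)
  session_id <- session_id %||% sprintf("%s_%s_r%d_s%d", mouse_id, cfg$phase,
                                        oblom_id, cfg$seed)
  meta <- list(mouse_id = mouse_id, phase = cfg$phase,
               oblom_id = oblom_id, session_id = session_id,
               video_rate = cfg$video_rate,
               photometry_rate = cfg$photometry_rate,
               session_duration = cfg$session_duration)
  out <- list(config = cfg, trajectory = traj, ethogram = etho,
              truth = truth, objects = session_objects(cfg), meta = meta)
  if (render) {
    out$photometry <- render_photometry(cfg, truth)
    out$photometry$meta <- meta
  }
  class(out) <- "synth_session"
  out
}
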