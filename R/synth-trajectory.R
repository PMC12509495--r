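# Behavioral state sequence: semi-Markov chain with (shifted) exponential
# dwell times per state, plus a per-episode target object for exploration.
# The object choice is biased toward the nonstationary object during the
# first 3 min of the test phase (test_preference).
simulate_states <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    dt <- 1 / cfg$video_rate
    n <- round(cfg$session_duration * cfg$video_rate)
    states <- names(cfg$dwell)
    probs <- cfg$state_probs
    ep_state <- character(0)
    ep_obj <- character(0)
    ep_start <- numeric(0)
    ep_dur <- numeric(0)
    t_cur <- 0
    cur <- "locomotion"  # the animal is moving right after placement
    while (t_cur < cfg$session_duration) {
      dw <- 1 + rexp(1, rate = 1 / max(cfg$dwell[[cur]] - 1, 0.5))
      obj <- NA_character_
      if (cur == "explore") {
        p_non <- 0.5
        if (cfg$phase == "test" && t_cur < 180) {
          p_non <- cfg$test_preference / (cfg$test_preference + 1)
        }
        obj <- if (runif(1) < p_non) "nonstat" else "stat"
      }
      ep_state <- c(ep_state, cur)
      ep_obj <- c(ep_obj, obj)
      ep_start <- c(ep_start, t_cur)
      ep_dur <- c(ep_dur, dw)
      t_cur <- t_cur + dw
      p <- probs
      # decaying exploratory drive: locomotion is favored early in the
      # session, giving movement speed its slow session-start decay
      p["locomotion"] <- p["locomotion"] *
        (1 + cfg$explore_drive_amp * exp(-t_cur / cfg$explore_drive_tau))
      p[cur] <- 0
      if (sum(p) == 0) break
      cur <- sample(states, 1, prob = p / sum(p))
    }
    ep <- data.frame(state = ep_state, object = ep_obj,
                     start = ep_start, dur = ep_dur,
                     stringsAsFactors = FALSE)
    ep$i0 <- pmin(n, floor(ep$start / dt) + 1L)
    ep$i1 <- pmin(n, floor((ep$start + ep$dur) / dt))
    ep <- ep[ep$i1 >= ep$i0, , drop = FALSE]
    frame_state <- character(n)
    frame_obj <- rep(NA_character_, n)
    for (k in seq_len(nrow(ep))) {
      idx <- ep$i0[k]:ep$i1[k]
      frame_state[idx] <- ep$state[k]
      frame_obj[idx] <- ep$object[k]
    }
    # guard against any unassigned tail frames
    frame_state[frame_state == ""] <- "quiet"
    list(episodes = ep, frame_state = frame_state, frame_obj = frame_obj, n = n)
  })
}

#' Simulate a pose trajectory for a synthetic session
#'
#' Integrates neck/nose positions on the video clock.  Movement follows an
#' Ornstein-Uhlenbeck relaxation (about 1 s) toward a state-conditioned
#' log-normal target speed, with waypoint steering: random waypoints during
#' locomotion, the configured object center during exploration episodes, and
#' near-zero target speed during grooming, rearing and quiet states.  Target
#' speed is modulated by a decaying exploratory drive
#' `1 + explore_drive_amp * exp(-t / explore_drive_tau)` so that movement
#' speed is elevated at session start.
#'
#' @param cfg a [generator_config()].
#' @return A `trajectory` data.frame with columns `frame`, `t`, `neck_x`,
#'   `neck_y`, `nose_x`, `nose_y`, `speed` (cm/s, neck displacement times
#'   frame rate), carrying the hidden behavioral state sequence in
#'   attributes `state`, `object` and `episodes`.
#' @export
simulate_trajectory <- function(cfg) {
  st <- simulate_states(cfg)
  with_seed(derive_seed(cfg$seed, 2L), {
    n <- st$n
    dt <- 1 / cfg$video_rate
    tt <- (seq_len(n) - 1) * dt
    a <- cfg$arena_size
    objs <- session_objects(cfg)
    ep <- st$episodes
    # per-episode baseline target speed (cm/s)
    base_speed <- numeric(nrow(ep))
    for (k in seq_len(nrow(ep))) {
      base_speed[k] <- switch(ep$state[k],
        locomotion = rlnorm(1, meanlog = log(12), sdlog = 0.35),
        explore    = 1.5,
        grooming   = 0.2,
        rearing    = 0.3,
        quiet      = 0.4)
    }
    frame_ep <- integer(n)
    for (k in seq_len(nrow(ep))) frame_ep[ep$i0[k]:ep$i1[k]] <- k

    drive <- 1 + cfg$explore_drive_amp * exp(-tt / cfg$explore_drive_tau)
    nx <- ny <- numeric(n)
    nosex <- nosey <- numeric(n)
    v <- numeric(n)
    px <- runif(1, 0.25 * a, 0.75 * a)
    py <- runif(1, 0.25 * a, 0.75 * a)
    vel <- 2
    wpx <- runif(1, 0.1 * a, 0.9 * a)
    wpy <- runif(1, 0.1 * a, 0.9 * a)
    hdx <- 1; hdy <- 0
    jit <- 0.01
    noise_v <- rnorm(n, 0, 0.5) * sqrt(dt)
    jx <- rnorm(n, 0, jit)
    jy <- rnorm(n, 0, jit)
    # per-frame episode attributes hoisted out of the loop (scalar hot loop)
    st_code <- c(locomotion = 1L, grooming = 0L, rearing = 0L, quiet = 0L,
                 explore = 2L)[ep$state]
    obx <- oby <- numeric(nrow(ep))
    isx <- ep$state == "explore"
    obx[isx] <- vapply(ep$object[isx], function(o) objs[[o]][1], numeric(1))
    oby[isx] <- vapply(ep$object[isx], function(o) objs[[o]][2], numeric(1))
    code_f <- st_code[frame_ep]
    base_f <- base_speed[frame_ep]
    obx_f <- obx[frame_ep]
    oby_f <- oby[frame_ep]
    lo <- 0.5; hi <- a - 0.5
    for (i in seq_len(n)) {
      code <- code_f[i]
      if (code == 2L) {            # explore: steer to the episode's object
        wpx <- obx_f[i]; wpy <- oby_f[i]
        d2 <- (wpx - px)^2 + (wpy - py)^2
        target <- if (d2 > 36) 10 * drive[i] else base_f[i]
      } else if (code == 1L) {     # locomotion: random waypoints
        target <- base_f[i] * drive[i]
        if ((wpx - px)^2 + (wpy - py)^2 < 4) {
          wpx <- runif(1, 0.1 * a, 0.9 * a)
          wpy <- runif(1, 0.1 * a, 0.9 * a)
        }
      } else {                     # grooming / rearing / quiet: stay
        target <- base_f[i]
        wpx <- px; wpy <- py
      }
      vel <- vel + dt * (target - vel) + noise_v[i]
      if (vel < 0) vel <- 0
      dx <- wpx - px; dy <- wpy - py
      nrm <- sqrt(dx * dx + dy * dy)
      if (nrm > 1e-6) { hdx <- dx / nrm; hdy <- dy / nrm }
      px <- px + vel * dt * hdx + jx[i]
      py <- py + vel * dt * hdy + jy[i]
      if (px < lo) px <- lo else if (px > hi) px <- hi
      if (py < lo) py <- lo else if (py > hi) py <- hi
      nx[i] <- px; ny[i] <- py
      if (code == 2L) {
        dx <- obx_f[i] - px; dy <- oby_f[i] - py
        nn <- sqrt(dx * dx + dy * dy)
        if (nn > 1e-6) { ux <- dx / nn; uy <- dy / nn } else { ux <- hdx; uy <- hdy }
      } else {
        ux <- hdx; uy <- hdy
      }
      nosex[i] <- px + 3 * ux
      nosey[i] <- py + 3 * uy
      v[i] <- vel
    }
    traj <- data.frame(frame = seq_len(n) - 1L, t = tt,
                       neck_x = nx, neck_y = ny,
                       nose_x = nosex, nose_y = nosey)
    traj$speed <- compute_speed(traj, cfg$video_rate)
    attr(traj, "state") <- st$frame_state
    attr(traj, "object") <- st$frame_obj
    attr(traj, "episodes") <- ep
    class(traj) <- c("trajectory", "data.frame")
    traj
  })
}
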