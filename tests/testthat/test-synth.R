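test_that("generator config validates its invariants", {
  expect_error(generator_config(seed = 1, session_duration = 30), "60")
  expect_error(generator_config(seed = 1, recency_tau = -1), "recency_tau")
  expect_error(generator_config(seed = 1, dwell = c(locomotion = 1, grooming = 8,
                                                    rearing = 5, quiet = 5,
                                                    explore = 6)), "dwell")
  expect_error(generator_config(
    seed = 1,
    object_centers = list(sample = list(stat = c(-5, 10), nonstat = c(30, 10)),
                          test = list(stat = c(10, 10), nonstat = c(30, 30)))),
    "arena")
})

test_that("trajectories are deterministic under a fixed seed and stay in the arena", {
  cfg <- generator_config(seed = 5, session_duration = 120)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_identical(t1$neck_x, t2$neck_x)
  expect_identical(t1$speed, t2$speed)
  expect_true(all(t1$neck_x >= 0 & t1$neck_x <= cfg$arena_size))
  expect_true(all(t1$neck_y >= 0 & t1$neck_y <= cfg$arena_size))
  expect_true(all(t1$speed >= 0))
})

test_that("locomotion frames are faster than non-locomotion frames", {
  ses <- fixture("s11", function() short_session(11))
  st <- attr(ses$trajectory, "state")
  sp <- ses$trajectory$speed
  expect_gt(mean(sp[st == "locomotion"]), mean(sp[st != "locomotion"]))
})

test_that("suppressing locomotion and exploration yields a near-stationary animal", {
  cfg <- generator_config(seed = 3, session_duration = 120,
                          state_probs = c(locomotion = 0, grooming = 0.3,
                                          rearing = 0.3, quiet = 0.4,
                                          explore = 0))
  traj <- simulate_trajectory(cfg)
  # only the initial placement episode moves; the bulk of the session is still
  expect_lt(median(traj$speed), 1.5)
})

test_that("exploratory drive elevates early-session speed (Monte Carlo)", {
  rate <- 30
  early_minus_late <- vapply(1:20, function(s) {
    traj <- simulate_trajectory(generator_config(seed = 200 + s,
                                                 session_duration = 300))
    mean(traj$speed[1:(60 * rate)]) - mean(tail(traj$speed, 60 * rate))
  }, numeric(1))
  expect_gt(mean(early_minus_late), 0)
  expect_gt(mean(early_minus_late > 0), 0.6)
})

test_that("ethogram flags respect exclusivity and position gating", {
  ses <- fixture("s11", function() short_session(11))
  e <- ses$ethogram
  expect_true(all(e$grooming + e$locomotion <= 1))
  expect_true(all(e$grooming + e$rearing <= 1))
  expect_true(all(e$rearing + e$locomotion <= 1))
  expect_true(all(e$explore_stat + e$explore_nonstat <= 1))
  # grooming never co-occurs with object exploration
  expect_true(all(e$grooming + e$explore_stat + e$explore_nonstat <= 1))
  others <- e$locomotion + e$grooming + e$rearing + e$explore_stat + e$explore_nonstat
  expect_identical(e$background, as.integer(others == 0))
  expect_gt(sum(e$grooming), 0)
  # exploration frames have the nose within 10 cm of the labeled object
  obj <- ses$objects
  for (ob in c("stat", "nonstat")) {
    col <- paste0("explore_", ob)
    idx <- which(e[[col]] == 1)
    d <- sqrt((ses$trajectory$nose_x[idx] - obj[[ob]][1])^2 +
              (ses$trajectory$nose_y[idx] - obj[[ob]][2])^2)
    expect_true(all(d <= 10 + 1e-9))
  }
})

test_that("every behavior yields long bouts in a full-length session (Monte Carlo)", {
  ok <- vapply(1:20, function(s) {
    ses <- short_session(400 + s, duration = 900,
                         dwell = c(locomotion = 10, grooming = 10, rearing = 10,
                                   quiet = 10, explore = 10))
    all(vapply(c("locomotion", "grooming", "rearing",
                 "explore_stat", "explore_nonstat"), function(b) {
      flags <- ses$ethogram[[b]]
      r <- rle(flags)
      any(r$values == 1 & r$lengths >= 2 * 30)
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("symmetric allocation gives near-zero mean discrimination index", {
  dis <- vapply(1:50, function(s) {
    ses <- short_session(600 + s, phase = "test", duration = 240,
                         test_preference = 1)
    e <- ses$ethogram
    n <- 180 * 30
    tn <- sum(e$explore_nonstat[1:n])
    ts <- sum(e$explore_stat[1:n])
    if (tn + ts == 0) return(NA_real_)
    (tn - ts) / (tn + ts)
  }, numeric(1))
  expect_lt(abs(mean(dis, na.rm = TRUE)), 0.1)
})

test_that("ground truth composes exactly from its components", {
  ses <- fixture("s11", function() short_session(11))
  z <- Reduce(`+`, ses$truth$components)
  expect_equal(ses$truth$z_true, z, tolerance = 1e-14)
})

test_that("null generator produces an identically zero latent signal", {
  cfg <- generator_config(seed = 2, session_duration = 120,
                          beta_speed = 0, beta_groom = 0, beta_rear = 0,
                          novelty_amp = 0, recency_amp = 0, noise_sd = 0,
                          drift_sd = 0,
                          re_sd = c(intercept = 0, speed = 0, grooming = 0,
                                    rearing = 0, objects = 0))
  traj <- simulate_trajectory(cfg)
  etho <- simulate_ethogram(cfg, traj)
  truth <- simulate_ground_truth(cfg, traj, etho)
  expect_equal(max(abs(truth$z_true)), 0)
})

test_that("a pure recency term satisfies the exponential identity z(tau)/z(0) = 1/e", {
  cfg <- generator_config(seed = 2, session_duration = 120,
                          beta_speed = 0, beta_groom = 0, beta_rear = 0,
                          novelty_amp = 0, recency_amp = 2, recency_tau = 28,
                          noise_sd = 0, drift_sd = 0,
                          re_sd = c(intercept = 0, speed = 0, grooming = 0,
                                    rearing = 0, objects = 0))
  traj <- simulate_trajectory(cfg)
  etho <- simulate_ethogram(cfg, traj)
  truth <- simulate_ground_truth(cfg, traj, etho)
  i_tau <- which.min(abs(truth$t - 28))
  expect_equal(truth$z_true[i_tau] / truth$z_true[1], exp(-1), tolerance = 1e-3)
})

test_that("the speed component dominates outside bouts once recency has decayed", {
  cfg <- generator_config(seed = 9, session_duration = 600, noise_sd = 0,
                          drift_sd = 0)
  traj <- simulate_trajectory(cfg)
  etho <- simulate_ethogram(cfg, traj)
  truth <- simulate_ground_truth(cfg, traj, etho)
  sel <- truth$t > 120 & etho$grooming == 0 & etho$rearing == 0 &
    etho$explore_stat == 0 & etho$explore_nonstat == 0
  r <- cor(truth$z_true[sel], log2(pmax(traj$speed[sel], 1)))
  expect_gt(r, 0.95)
})

test_that("rendered photometry is deterministic, positive, and proportional when artifact-only", {
  cfg <- generator_config(seed = 12, session_duration = 90,
                          beta_speed = 0, beta_groom = 0, beta_rear = 0,
                          novelty_amp = 0, recency_amp = 0, noise_sd = 0,
                          drift_sd = 0,
                          re_sd = c(intercept = 0, speed = 0, grooming = 0,
                                    rearing = 0, objects = 0),
                          motion_amp = 0, photon_noise_sd = 0)
  traj <- simulate_trajectory(cfg)
  etho <- simulate_ethogram(cfg, traj)
  truth <- simulate_ground_truth(cfg, traj, etho)
  ph1 <- render_photometry(cfg, truth)
  ph2 <- render_photometry(cfg, truth)
  expect_identical(ph1$f465, ph2$f465)
  expect_true(all(ph1$f465 > 0) && all(ph1$f405 > 0))
  ratio <- ph1$f465 / ph1$f405
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
})

test_that("an excessive gain raises an error instead of negative fluorescence", {
  ses <- fixture("s11", function() short_session(11))
  cfg <- ses$config
  cfg$gain <- 10
  expect_error(render_photometry(cfg, ses$truth), "gain")
})
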