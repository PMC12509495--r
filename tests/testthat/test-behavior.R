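test_that("speed derives from neck displacement times frame rate", {
  traj <- data.frame(neck_x = rep(5, 10), neck_y = rep(5, 10))
  expect_equal(compute_speed(traj, 30), rep(0, 10))
  traj2 <- data.frame(neck_x = cumsum(rep(5, 10)), neck_y = rep(0, 10))
  expect_equal(compute_speed(traj2, 30), rep(150, 10))
  set.seed(8)
  rw <- data.frame(neck_x = cumsum(rnorm(50)), neck_y = cumsum(rnorm(50)))
  sp <- compute_speed(rw, 30)
  manual <- sqrt(diff(rw$neck_x)^2 + diff(rw$neck_y)^2) * 30
  expect_equal(sp, c(manual[1], manual), tolerance = 1e-12)
  rw$neck_x[3] <- NA
  expect_error(compute_speed(rw, 30), "frames")
})

test_that("object exploration is relabeled by nose distance with tie to stationary", {
  objects <- list(stat = c(10, 10), nonstat = c(30, 10))
  res <- classify_object_exploration(1, matrix(c(10, 10), 1), objects)
  expect_equal(res$explore_stat, 1L)
  res2 <- classify_object_exploration(1, matrix(c(20, 10 + sqrt(10.1^2 - 10^2)), 1),
                                      objects)
  expect_equal(res2$explore_stat + res2$explore_nonstat, 0L)
  # exact equidistance within both radii: stationary wins
  res3 <- classify_object_exploration(1, matrix(c(20, 10), 1), objects, radius = 11)
  expect_equal(res3$explore_stat, 1L)
  expect_equal(res3$explore_nonstat, 0L)
})

test_that("grid classification matches a brute-force distance oracle", {
  objects <- list(stat = c(12, 12), nonstat = c(28, 28))
  g <- expand.grid(x = seq(0, 40, by = 2.5), y = seq(0, 40, by = 2.5))
  nose <- as.matrix(g)
  res <- classify_object_exploration(rep(1, nrow(nose)), nose, objects)
  for (i in seq_len(nrow(nose))) {
    ds <- sqrt(sum((nose[i, ] - objects$stat)^2))
    dn <- sqrt(sum((nose[i, ] - objects$nonstat)^2))
    expected <- if (ds <= 10 && (dn > 10 || ds <= dn)) "stat"
      else if (dn <= 10) "nonstat" else "none"
    got <- if (res$explore_stat[i] == 1) "stat"
      else if (res$explore_nonstat[i] == 1) "nonstat" else "none"
    expect_identical(got, expected)
  }
})

test_that("discrimination index arithmetic and antisymmetry", {
  expect_equal(discrimination_index(3, 1)$di, 0.5)
  expect_equal(discrimination_index(4.2, 4.2)$di, 0)
  expect_equal(discrimination_index(7.2, 0)$di, 1)
  expect_equal(discrimination_index(2, 5)$di, -discrimination_index(5, 2)$di)
  expect_error(discrimination_index(0, 0), "undefined")
})

test_that("sliding DI handles uniform, one-sided and empty windows", {
  rate <- 30
  n <- 600 * rate
  etho <- data.frame(explore_stat = integer(n), explore_nonstat = integer(n))
  # uniform exploration of both objects
  etho$explore_stat[seq(1, n, by = 10)] <- 1L
  etho$explore_nonstat[seq(2, n, by = 10)] <- 1L
  di <- sliding_di(etho, rate)
  expect_true(all(abs(di$di) < 0.01))
  # only nonstationary exploration in the first window
  e2 <- data.frame(explore_stat = integer(n), explore_nonstat = integer(n))
  e2$explore_nonstat[1:(30 * rate)] <- 1L
  di2 <- sliding_di(e2, rate)
  expect_equal(di2$di[1], 1)
  expect_true(is.na(di2$di[nrow(di2)]))
  # full-session window equals the whole-session DI
  e3 <- data.frame(explore_stat = integer(n), explore_nonstat = integer(n))
  set.seed(4)
  e3$explore_stat[sample(n, 500)] <- 1L
  e3$explore_nonstat[sample(n, 800)] <- 1L
  di3 <- sliding_di(e3, rate, window = 600, step = 600)
  whole <- discrimination_index(sum(e3$explore_nonstat) / rate,
                                sum(e3$explore_stat) / rate)
  expect_equal(di3$di[1], whole$di)
})

test_that("early test-phase novelty preference appears in the first DI window", {
  first_last <- t(vapply(1:20, function(s) {
    ses <- short_session(800 + s, phase = "test", duration = 600)
    di <- sliding_di(ses$ethogram, 30)
    c(di$di[1], di$di[nrow(di)])
  }, numeric(2)))
  expect_gt(mean(first_last[, 1], na.rm = TRUE),
            mean(first_last[, 2], na.rm = TRUE))
})

test_that("bout extraction filters short and poorly isolated bouts", {
  rate <- 30
  t <- (0:(60 * rate - 1)) / rate
  expect_equal(nrow(extract_bouts(integer(60 * rate), t)), 0)
  # a single 1.5 s run is below the minimum duration
  f <- integer(60 * rate)
  f[301:(300 + 1.5 * rate)] <- 1L
  expect_equal(nrow(extract_bouts(f, t)), 0)
  # 5 s on / 3 s off / 5 s on: both runs violate the 4 s isolation rule
  f2 <- integer(60 * rate)
  f2[1:(5 * rate)] <- 1L
  f2[(8 * rate + 1):(13 * rate)] <- 1L
  expect_equal(nrow(extract_bouts(f2, t)), 0)
  # a well-isolated 5 s bout survives with half-open boundaries
  f3 <- integer(60 * rate)
  f3[(10 * rate + 1):(15 * rate)] <- 1L
  b <- extract_bouts(f3, t)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_t, 10)
  expect_equal(b$offset_t, 15)
  expect_equal(b$duration, 5)
})

test_that("bout extraction matches the brute-force scan oracle on random strings", {
  set.seed(99)
  rate <- 10
  for (k in 1:1000) {
    n <- 120
    f <- as.integer(runif(n) < 0.35)
    t <- (0:(n - 1)) / rate
    got <- extract_bouts(f, t, min_dur = 2, isolation = 4)
    want <- oracle_bouts(f, 1 / rate, min_dur = 2, isolation = 4)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$onset_i, vapply(want, `[`, numeric(1), 1))
      expect_equal(got$offset_i, vapply(want, `[`, numeric(1), 2) + 1L)
    }
  }
})

test_that("bout extraction is idempotent on its own output mask", {
  set.seed(7)
  rate <- 10
  n <- 300
  f <- as.integer(runif(n) < 0.3)
  t <- (0:(n - 1)) / rate
  b <- extract_bouts(f, t)
  mask <- integer(n)
  for (k in seq_len(nrow(b))) mask[b$onset_i[k]:(b$offset_i[k] - 1L)] <- 1L
  b2 <- extract_bouts(mask, t)
  expect_equal(b2$onset_i, b$onset_i)
  expect_equal(b2$offset_i, b$offset_i)
})

test_that("behavior proportions sum to 100 and split co-occurrences evenly", {
  rate <- 30
  n <- 120 * rate
  t <- (0:(n - 1)) / rate
  etho <- data.frame(locomotion = integer(n), grooming = integer(n),
                     background = integer(n))
  etho$locomotion[(20 * rate):(40 * rate)] <- 1L
  etho$background <- as.integer(etho$locomotion == 0)
  bouts <- extract_bouts(etho$locomotion, t, behavior = "locomotion")
  bouts <- rbind(bouts, bouts)  # two identical events for averaging
  prop <- proportion_of_total(etho, bouts, rate)
  core <- 151:250
  expect_true(all(abs(rowSums(prop) - 100) < 1e-9))
  expect_true(all(abs(prop[core, "locomotion"] - 100) < 1e-9))
  # co-occurring behaviors share the mass equally
  etho2 <- etho
  etho2$grooming <- etho2$locomotion  # synthetic overlap
  prop2 <- proportion_of_total(etho2, bouts, rate)
  expect_true(all(abs(prop2[core, "locomotion"] - 50) < 1e-9))
  expect_true(all(abs(prop2[core, "grooming"] - 50) < 1e-9))
})
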