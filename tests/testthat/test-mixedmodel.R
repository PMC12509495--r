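toy_table <- function(n = 600, seed = 17, beta = list(int = -0.2, phase = 0.1,
                                                      speed = 0.25,
                                                      groom = -0.75,
                                                      rear = 0.15,
                                                      exps = 0.1, expn = 0.1,
                                                      i_speed = 0, i_groom = 0,
                                                      i_rear = 0, i_exps = 0,
                                                      i_expn = 0),
                      sigma = 0.4, n_sessions = 4) {
  set.seed(seed)
  per <- n / n_sessions
  rows <- lapply(seq_len(n_sessions), function(s) {
    phase <- as.integer(s %% 2 == 0)
    lsp <- rnorm(per, 1.5, 1)
    st <- sample(0:4, per, replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
    groom <- as.integer(st == 1); rear <- as.integer(st == 2)
    exps <- as.integer(st == 3); expn <- as.integer(st == 4)
    mu <- beta$int + beta$phase * phase + beta$speed * lsp +
      beta$groom * groom + beta$rear * rear + beta$exps * exps +
      beta$expn * expn + phase * (beta$i_speed * lsp + beta$i_groom * groom +
                                  beta$i_rear * rear + beta$i_exps * exps +
                                  beta$i_expn * expn)
    data.frame(dff_z = mu + rnorm(per, 0, sigma), phase = phase,
               log2speed = lsp, grooming = groom, rearing = rear,
               exp_stat = exps, exp_nonstat = expn,
               mouse_id = sprintf("m%d", (s + 1) %/% 2),
               oblom_id = sprintf("m%d:1", (s + 1) %/% 2),
               session_id = sprintf("s%d", s),
               t = seq_len(per) / 30)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("frame_table", "data.frame")
  tab
}

test_that("frame tables assemble with correct size, coding and alignment checks", {
  ses <- lapply(1:2, function(k) {
    s <- short_session(40 + k, phase = c("sample", "test")[k], duration = 120)
    list(dff = s$truth$z_true, speed = s$trajectory$speed, etho = s$ethogram,
         meta = s$meta)
  })
  tab <- assemble_frame_table(ses)
  expect_equal(nrow(tab), 2 * 120 * 30)
  expect_setequal(unique(tab$phase), c(0L, 1L))
  expect_true(all(tab$exp_stat + tab$exp_nonstat <= 1))
  ses[[2]]$speed <- ses[[2]]$speed[-1]
  expect_error(assemble_frame_table(ses), "misaligned")
})

test_that("the fixed-effects design matrix matches a hand-built matrix", {
  tab <- toy_table(n = 20, n_sessions = 2)
  X <- model.matrix(as.formula(
    "dff_z ~ phase * (log2speed + exp_nonstat + exp_stat + rearing + grooming)"),
    data = tab)
  H <- cbind(1, tab$phase, tab$log2speed, tab$exp_nonstat, tab$exp_stat,
             tab$rearing, tab$grooming, tab$phase * tab$log2speed,
             tab$phase * tab$exp_nonstat, tab$phase * tab$exp_stat,
             tab$phase * tab$rearing, tab$phase * tab$grooming)
  expect_equal(matrix(X, nrow(X)), matrix(H, nrow(H)), tolerance = 1e-14)
})

test_that("the mixed model recovers the generating fixed effects", {
  tab <- toy_table(n = 8000, seed = 18, n_sessions = 8)
  fit <- fit_lmm(tab, random_spec = "intercepts")
  cf <- fit$coefficients
  truth <- c("(Intercept)" = -0.2, phase = 0.1, log2speed = 0.25,
             grooming = -0.75, rearing = 0.15)
  for (nm in names(truth)) {
    row <- cf[cf$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * row$se)
  }
  expect_true(fit$converged)
  expect_true(fit$random_level %in% c("full", "diag", "intercepts"))
})

test_that("intercept-only data yields the sample mean with near-zero slopes", {
  tab <- toy_table(n = 2000, seed = 19,
                   beta = list(int = 1.3, phase = 0, speed = 0, groom = 0,
                               rear = 0, exps = 0, expn = 0, i_speed = 0,
                               i_groom = 0, i_rear = 0, i_exps = 0, i_expn = 0),
                   sigma = 0.2)
  fit <- fit_lmm(tab, random_spec = "intercepts")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 1.3, tolerance = 0.05)
})

test_that("the novelty contrast equals the difference of the interaction estimates", {
  tab <- toy_table(n = 6000, seed = 20,
                   beta = list(int = 0, phase = 0, speed = 0.25, groom = -0.5,
                               rear = 0.1, exps = 0.3, expn = 0.3, i_speed = 0,
                               i_groom = 0, i_rear = 0, i_exps = -0.2,
                               i_expn = 0.3))
  fit <- fit_lmm(tab, random_spec = "intercepts")
  ct <- novelty_contrast(fit)
  cf <- fit$coefficients
  expect_equal(ct$estimate,
               cf$estimate[cf$term == "phase:exp_nonstat"] -
                 cf$estimate[cf$term == "phase:exp_stat"],
               tolerance = 1e-12)
  expect_gte(ct$F, 0)
  expect_equal(ct$df1, 1)
  # symmetric interactions: small contrast
  tab0 <- toy_table(n = 6000, seed = 21,
                    beta = list(int = 0, phase = 0, speed = 0.25, groom = -0.5,
                                rear = 0.1, exps = 0.3, expn = 0.3, i_speed = 0,
                                i_groom = 0, i_rear = 0, i_exps = 0.2,
                                i_expn = 0.2))
  ct0 <- novelty_contrast(fit_lmm(tab0, random_spec = "intercepts"))
  expect_lt(abs(ct0$estimate), 3 * ct0$se)
})

test_that("a full-session sliding window reproduces the global object coefficients", {
  ses <- lapply(1:4, function(k) {
    s <- short_session(60 + k, phase = c("sample", "test")[(k %% 2) + 1],
                       duration = 240)
    list(dff = s$truth$z_true, speed = s$trajectory$speed, etho = s$ethogram,
         meta = s$meta)
  })
  tab <- assemble_frame_table(ses)
  sl <- sliding_lmm(tab, window = 240, step = 300, min_exploration = 1,
                    random_spec = "intercepts")
  fit <- fit_lmm(tab, random_spec = "intercepts")
  cf <- fit$coefficients
  sample_row <- sl[sl$phase == 0, ]
  expect_equal(sample_row$coef_nonstat,
               cf$estimate[cf$term == "exp_nonstat"], tolerance = 1e-6)
  test_row <- sl[sl$phase == 1, ]
  expect_equal(test_row$coef_nonstat,
               cf$estimate[cf$term == "exp_nonstat"] +
                 cf$estimate[cf$term == "phase:exp_nonstat"], tolerance = 1e-6)
})

test_that("the OLS meta-model matches its closed form and flags degenerate designs", {
  cw <- expand.grid(window_idx = 1:13, phase = 0:1)
  cw$diff <- 0.7
  m <- ols_meta(cw)
  expect_equal(m$coefficients$estimate[1], 0.7, tolerance = 1e-12)
  expect_true(all(abs(m$coefficients$estimate[-1]) < 1e-12))
  set.seed(22)
  cw$diff <- 0.1 + 0.25 * cw$phase + rnorm(nrow(cw), 0, 0.05)
  m2 <- ols_meta(cw)
  X <- cbind(1, cw$phase, cw$window_idx, cw$phase * cw$window_idx)
  beta <- solve(crossprod(X), crossprod(X, cw$diff))
  expect_equal(m2$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  expect_error(ols_meta(cw[cw$phase == 0, ]), "2 phases")
})
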