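#' Assemble the frame-level model table from preprocessed sessions
#'
#' Concatenates sessions into one row-per-frame table on the 30 Hz video
#' clock: z-scored smoothed delta-F/F, smoothed log2 speed, behavioral
#' indicator columns, task phase (treatment-coded, sample = 0) and grouping
#' identifiers.  Smoothing (0.5 s moving average) is applied here to both
#' the activity and the log2-speed series, matching the preprocessing used
#' before model fitting.
#'
#' @param sessions list; each element needs `dff` (numeric series on the
#'   video clock, unsmoothed or already smoothed — see `smooth_window`),
#'   `speed`, `etho` (ethogram data.frame), and `meta` (with `mouse_id`,
#'   `phase`, `oblom_id`, `session_id`).
#' @param video_rate frames per second (default 30).
#' @param smooth_window moving-average window in seconds applied to the
#'   activity and log2-speed series (default 0.5); `NULL` to skip.
#' @param speed_floor cm/s floor before the log2 transform (default 1).
#' @param standardize z-score the activity per session (default TRUE).
#' @param thin keep every `thin`-th frame (default 1 = all frames); frames
#'   are thinned after smoothing, a decorrelation option for desk-scale
#'   recovery studies.
#' @return a `frame_table` data.frame.
#' @export
assemble_frame_table <- function(sessions, video_rate = 30,
                                 smooth_window = 0.5, speed_floor = 1,
                                 standardize = TRUE, thin = 1L) {
  rows <- lapply(sessions, function(s) {
    n <- length(s$dff)
    if (nrow(s$etho) != n || length(s$speed) != n) {
      stop(sprintf("session %s: misaligned clocks (dff %d, speed %d, ethogram %d rows)",
                   s$meta$session_id, n, length(s$speed), nrow(s$etho)),
           call. = FALSE)
    }
    dff <- s$dff
    lsp <- log2_speed(s$speed, speed_floor)
    if (!is.null(smooth_window)) {
      dff <- moving_average(dff, smooth_window, video_rate)
      lsp <- moving_average(lsp, smooth_window, video_rate)
    }
    if (standardize) dff <- zscore(dff)
    idx <- seq(1L, n, by = as.integer(thin))
    data.frame(
      dff_z = dff[idx],
      phase = if (identical(s$meta$phase, "test")) 1L else 0L,
      log2speed = lsp[idx],
      grooming = s$etho$grooming[idx],
      rearing = s$etho$rearing[idx],
      exp_stat = s$etho$explore_stat[idx],
      exp_nonstat = s$etho$explore_nonstat[idx],
      mouse_id = s$meta$mouse_id,
      oblom_id = paste(s$meta$mouse_id, s$meta$oblom_id, sep = ":"),
      session_id = s$meta$session_id,
      t = (idx - 1L) / video_rate,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (anyNA(tab)) stop("frame table contains missing values", call. = FALSE)
  class(tab) <- c("frame_table", "data.frame")
  tab
}

lmm_fixed_formula <- "dff_z ~ phase * (log2speed + exp_nonstat + exp_stat + rearing + grooming)"

lmm_random_terms <- function(level, tab) {
  slopes <- "log2speed + exp_nonstat + exp_stat + rearing + grooming"
  multi_mouse <- length(unique(tab$mouse_id)) > 1
  multi_oblom <- length(unique(tab$oblom_id)) > length(unique(tab$mouse_id))
  switch(level,
    full = {
      re <- sprintf("(1 + phase * (%s) | session_id)", slopes)
      if (multi_mouse) {
        re <- c(sprintf("(1 + phase * (%s) | mouse_id)", slopes), re)
      }
      if (multi_oblom) {
        re <- c(re, sprintf("(1 + phase * (%s) | oblom_id)", slopes))
      }
      re
    },
    diag = {
      re <- sprintf("(1 + %s || session_id)", slopes)
      if (multi_mouse) re <- c("(1 | mouse_id)", re)
      re
    },
    objects = {
      # tailored to the novelty contrast: between-session variation of the
      # object-exploration effects, diagonal covariance
      re <- "(1 + exp_nonstat + exp_stat || session_id)"
      if (multi_mouse) re <- c("(1 | mouse_id)", re)
      re
    },
    intercepts = {
      re <- "(1 | session_id)"
      if (multi_mouse) re <- c("(1 | mouse_id)", re)
      re
    })
}

#' Fit the frame-level linear mixed-effects model
#'
#' Fits z-scored activity on task phase, log2 speed and behavioral
#' indicators with phase interactions, with nested random effects, by
#' restricted maximum likelihood (lme4 backend).  The random-effects
#' structure follows a fallback ladder: full random slopes with free
#' covariance, diagonal-covariance random slopes by session, then random
#' intercepts only; on failure or non-convergence the next level is tried
#' and the level used is recorded.  Inference on fixed effects uses the
#' residual degrees of freedom (observations minus fixed-effect count).
#'
#' @param tab a [assemble_frame_table()] result.
#' @param random_spec starting level of the fallback ladder: `"full"`,
#'   `"diag"` (default), `"objects"` (random object-exploration slopes only)
#'   or `"intercepts"`.
#' @return list of class `lmm_result` with `coefficients` (estimate, se, t,
#'   df, p, ci_lo, ci_hi per fixed effect), `vcov`, `fit_stats` (AIC, BIC,
#'   logLik), `random_level`, `converged`, `n_obs`, and the lme4 `model`.
#' @export
fit_lmm <- function(tab, random_spec = c("diag", "full", "objects", "intercepts")) {
  random_spec <- match.arg(random_spec)
  ladder <- c("full", "diag", "objects", "intercepts")
  ladder <- ladder[seq(match(random_spec, ladder), length(ladder))]
  X <- stats::model.matrix(stats::as.formula(lmm_fixed_formula), data = tab)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qr(X)$rank)]
    stop("rank-deficient fixed design; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  model <- NULL
  used <- NA_character_
  converged <- FALSE
  for (level in ladder) {
    fml <- stats::as.formula(paste(
      lmm_fixed_formula, "+", paste(lmm_random_terms(level, tab), collapse = " + ")))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = tab, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) e)
    if (inherits(fit, "error")) next
    model <- fit
    used <- level
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
    if (converged) break
  }
  if (is.null(model)) stop("mixed model failed at every random-effects level", call. = FALSE)
  est <- lme4::fixef(model)
  V <- as.matrix(vcov(model))
  se <- sqrt(diag(V))
  n_obs <- nrow(tab)
  df <- n_obs - length(est)
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  crit <- qt(0.975, df)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), t = unname(tval), df = df,
                      p = unname(pval),
                      ci_lo = unname(est - crit * se),
                      ci_hi = unname(est + crit * se),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, vcov = V,
                 fit_stats = c(AIC = AIC(model), BIC = BIC(model),
                               logLik = as.numeric(logLik(model))),
                 random_level = used, converged = converged,
                 n_obs = n_obs, model = model),
            class = "lmm_result")
}

#' Novelty interaction contrast
#'
#' Linear contrast between the phase x exploring-nonstationary and
#' phase x exploring-stationary interaction terms: a positive estimate means
#' the test-phase shift in the nonstationary-object effect exceeds the shift
#' in the stationary-object effect (a spatial-novelty signal).  Wald F test
#' with 1 numerator and residual denominator degrees of freedom.
#'
#' @param result an [fit_lmm()] result.
#' @return list of class `contrast_result` with `estimate`, `se`, `F`,
#'   `df1`, `df2`, `p`.
#' @export
novelty_contrast <- function(result) {
  terms <- result$coefficients$term
  i_non <- which(terms == "phase:exp_nonstat")
  i_stat <- which(terms == "phase:exp_stat")
  if (!length(i_non) || !length(i_stat)) {
    stop("interaction terms missing from the fitted model", call. = FALSE)
  }
  cvec <- numeric(length(terms))
  cvec[i_non] <- 1
  cvec[i_stat] <- -1
  est <- sum(cvec * result$coefficients$estimate)
  vc <- as.numeric(t(cvec) %*% result$vcov %*% cvec)
  Fstat <- est^2 / vc
  df2 <- result$n_obs - length(terms)
  structure(list(estimate = est, se = sqrt(vc), F = Fstat,
                 df1 = 1, df2 = df2, p = pf(Fstat, 1, df2, lower.tail = FALSE)),
            class = "contrast_result")
}

#' Sliding-window LMM coefficients for the object-exploration terms
#'
#' Refits the frame-level model on consecutive time windows (per-session
#' time), keeping windows with at least `min_exploration` seconds of
#' exploration of each object in each phase present in the window, and
#' extracts the per-phase object-exploration effects: sample-phase effect =
#' main term, test-phase effect = main term + phase interaction.
#'
#' @param tab a `frame_table`.
#' @param window window length in seconds (default 180).
#' @param step step in seconds (default 60).
#' @param min_exploration minimum exploration seconds per object term
#'   (default 1).
#' @param video_rate frames per second (default 30).
#' @param random_spec random-effects level for the per-window fits
#'   (default `"intercepts"`; window fits are small).
#' @return data.frame with one row per (window, phase): `window_idx`,
#'   `start`, `phase`, `coef_nonstat`, `se_nonstat`, `coef_stat`, `se_stat`,
#'   `diff` and `se_diff`.
#' @export
sliding_lmm <- function(tab, window = 180, step = 60, min_exploration = 1,
                        video_rate = 30, random_spec = "intercepts") {
  dur <- max(tab$t)
  starts <- seq(0, max(0, dur - window + 1e-9), by = step)
  out <- list()
  for (wi in seq_along(starts)) {
    s0 <- starts[wi]
    sub <- tab[tab$t >= s0 & tab$t < s0 + window, , drop = FALSE]
    enough <- all(vapply(split(sub, sub$phase), function(ph) {
      sum(ph$exp_stat) / video_rate >= min_exploration &&
        sum(ph$exp_nonstat) / video_rate >= min_exploration
    }, logical(1)))
    if (!enough) next
    fit <- tryCatch(fit_lmm(sub, random_spec = random_spec),
                    error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    V <- fit$vcov
    get <- function(term) {
      i <- match(term, cf$term)
      c(est = cf$estimate[i], i = i)
    }
    for (ph in c(0L, 1L)) {
      terms_non <- c("exp_nonstat", if (ph == 1L) "phase:exp_nonstat")
      terms_stat <- c("exp_stat", if (ph == 1L) "phase:exp_stat")
      idx_n <- match(terms_non, cf$term)
      idx_s <- match(terms_stat, cf$term)
      cn <- numeric(nrow(cf)); cn[idx_n] <- 1
      cs <- numeric(nrow(cf)); cs[idx_s] <- 1
      cd <- cn - cs
      out[[length(out) + 1L]] <- data.frame(
        window_idx = wi, start = s0, phase = ph,
        coef_nonstat = sum(cn * cf$estimate),
        se_nonstat = sqrt(as.numeric(t(cn) %*% V %*% cn)),
        coef_stat = sum(cs * cf$estimate),
        se_stat = sqrt(as.numeric(t(cs) %*% V %*% cs)),
        diff = sum(cd * cf$estimate),
        se_diff = sqrt(as.numeric(t(cd) %*% V %*% cd)))
    }
  }
  do.call(rbind, out)
}

#' OLS meta-model on sliding-window coefficient differences
#'
#' Ordinary least squares of the per-window difference between the
#' nonstationary- and stationary-object effects on task phase, window index
#' and their interaction:
#' `(exp_nonstat - exp_stat) ~ phase * window_idx`.
#'
#' @param coef_windows a [sliding_lmm()] result.
#' @return list of class `ols_meta_result` with a `coefficients` table
#'   (estimate, se, t, p, ci), `r_squared`, `adj_r_squared`, `f_stat`,
#'   `f_p`, `n_obs` and the `lm` fit.
#' @export
ols_meta <- function(coef_windows) {
  if (length(unique(coef_windows$phase)) < 2 ||
      length(unique(coef_windows$window_idx)) < 2) {
    stop("need at least 2 phases and 2 windows of coefficients", call. = FALSE)
  }
  fit <- lm(diff ~ phase * window_idx, data = coef_windows)
  sm <- summary(fit)
  if (any(is.na(coef(fit)))) stop("collinear meta-model design", call. = FALSE)
  cf <- sm$coefficients
  crit <- qt(0.975, fit$df.residual)
  fs <- sm$fstatistic
  structure(list(
    coefficients = data.frame(
      term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
      t = cf[, 3], p = cf[, 4],
      ci_lo = cf[, 1] - crit * cf[, 2], ci_hi = cf[, 1] + crit * cf[, 2],
      row.names = NULL, stringsAsFactors = FALSE),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_stat = unname(fs[1]),
    f_p = pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
    n_obs = nrow(coef_windows), model = fit),
    class = "ols_meta_result")
}
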