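#' Experiment configuration
#'
#' Describes a multi-session synthetic experiment mirroring the ObLoM study
#' design: each mouse contributes one sample and one test session per task
#' repetition.  The default structure (4 mice with 2 repetitions, 2 mice
#' with 1) yields 10 sample and 10 test sessions from 6 mice.
#'
#' @param seed master seed; every session derives its own seed from it.
#' @param oblom_structure integer vector, one entry per mouse, giving the
#'   number of task repetitions for that mouse.
#' @param session_duration seconds per session (default 900).
#' @param render render raw two-channel photometry and run the delta-F/F
#'   correction (default TRUE); when FALSE the latent activity plus noise is
#'   observed directly on the video clock (used by desk-scale studies of
#'   stages downstream of the correction).
#' @param generator named list of [generator_config()] overrides applied to
#'   every session.
#' @param target_rate,smooth_window,speed_floor preprocessing parameters.
#' @param standardize z-score the activity per session (default TRUE);
#'   recovery studies that compare estimates with generating coefficients
#'   use FALSE so effects stay in generator units.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(seed, oblom_structure = c(2, 2, 2, 2, 1, 1),
                              session_duration = 900, render = TRUE,
                              generator = list(), target_rate = 30,
                              smooth_window = 0.5, speed_floor = 1,
                              standardize = TRUE) {
  structure(list(seed = as.integer(seed), oblom_structure = oblom_structure,
                 session_duration = session_duration, render = render,
                 generator = generator, target_rate = target_rate,
                 smooth_window = smooth_window, speed_floor = speed_floor,
                 standardize = standardize),
            class = "experiment_config")
}

#' Generate and preprocess a synthetic experiment
#'
#' Simulates every configured session and computes its analysis-ready
#' series: smoothed z-scored delta-F/F on the video clock (through the full
#' correction pipeline when rendering, directly from the latent activity
#' otherwise), smoothed log2 speed, the per-session speed model (predicted
#' and speed-adjusted activity) and the ethogram.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, sessions are written via
#'   [write_session()] and the configuration serialized as `config.yaml`.
#' @return list of class `experiment_run` with `config` and `sessions`;
#'   each session carries `meta`, `dff` (values), `speed`, `log2speed`
#'   (smoothed), `etho`, `t`, `speed_model` and the generating
#'   `truth`/`config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sessions <- list()
  k <- 0L
  for (m in seq_along(config$oblom_structure)) {
    for (r in seq_len(config$oblom_structure[m])) {
      for (phase in c("sample", "test")) {
        k <- k + 1L
        args <- c(list(seed = derive_seed(config$seed, 100L + k),
                       phase = phase,
                       session_duration = config$session_duration),
                  config$generator)
        cfg <- do.call(generator_config, args)
        ses <- simulate_session(cfg, mouse_id = sprintf("m%02d", m),
                                oblom_id = r, render = config$render)
        sessions[[k]] <- prepare_session(ses, config)
        if (!is.null(out_dir)) {
          write_session(ses, file.path(out_dir, ses$meta$session_id))
        }
      }
    }
  }
  if (!is.null(out_dir)) {
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  structure(list(config = config, sessions = sessions),
            class = "experiment_run")
}

# analysis-ready series for one simulated session
prepare_session <- function(ses, config) {
  rate <- config$target_rate
  cfg <- ses$config
  if (config$render) {
    dffs <- preprocess_session(ses$photometry, target_rate = rate,
                               window = config$smooth_window,
                               standardize = config$standardize)
    dff <- dffs$values
  } else {
    dff <- moving_average(ses$truth$z_true, config$smooth_window, rate)
    if (config$standardize) dff <- zscore(dff)
  }
  n <- length(dff)
  speed <- ses$trajectory$speed[seq_len(n)]
  lsp <- moving_average(log2_speed(speed, config$speed_floor),
                        config$smooth_window, rate)
  model <- fit_speed_model(dff, lsp)
  list(meta = ses$meta, t = (seq_len(n) - 1) / rate, rate = rate,
       dff = dff, speed = speed, log2speed = lsp,
       etho = ses$ethogram[seq_len(n), ], speed_model = model,
       truth = ses$truth, generator = cfg)
}

#' Per-session speed-coding summary
#'
#' For every session: Pearson correlation of activity with raw speed and
#' with log2 speed (both smoothed), the regression slope, and the best
#' smoothing timescale.
#'
#' @param run an [run_experiment()] result.
#' @param windows timescale grid passed to [timescale_correlation()].
#' @return list with `table` (one row per session) and `paired_test`
#'   (paired t test of r_log2speed vs r_speed across sessions).
#' @export
analyze_speed <- function(run, windows = 2^seq(-2, 8, by = 0.5)) {
  rows <- lapply(run$sessions, function(s) {
    sp_s <- moving_average(s$speed, run$config$smooth_window, s$rate)
    curve <- timescale_correlation(s$dff, s$log2speed, s$rate, windows)
    data.frame(session_id = s$meta$session_id, phase = s$meta$phase,
               r_speed = cor(s$dff, sp_s),
               r_log2speed = s$speed_model$r,
               slope = s$speed_model$slope,
               best_window = curve$best_window,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tt <- stats::t.test(tab$r_log2speed, tab$r_speed, paired = TRUE)
  list(table = tab, paired_test = list(t = unname(tt$statistic),
                                       df = unname(tt$parameter),
                                       p = tt$p.value))
}

#' Discrimination-index summary
#'
#' Sliding-window DI per session plus the headline windows: test-phase DI
#' over the first 3 min, sample-phase DI over the first 12 min.
#'
#' @param run an `experiment_run`.
#' @param window,step sliding window and step in seconds.
#' @return list with `sliding` (per session x window) and `headline`
#'   (per session).
#' @export
analyze_di <- function(run, window = 180, step = 30) {
  sliding <- list()
  headline <- list()
  for (s in run$sessions) {
    sl <- sliding_di(s$etho, s$rate, window, step)
    sl$session_id <- s$meta$session_id
    sl$phase <- s$meta$phase
    sliding[[length(sliding) + 1L]] <- sl
    win <- if (s$meta$phase == "test") 180 else 720
    n <- min(nrow(s$etho), round(win * s$rate))
    tn <- sum(s$etho$explore_nonstat[seq_len(n)]) / s$rate
    ts <- sum(s$etho$explore_stat[seq_len(n)]) / s$rate
    headline[[length(headline) + 1L]] <- data.frame(
      session_id = s$meta$session_id, phase = s$meta$phase, window_s = win,
      t_nonstat = tn, t_stat = ts,
      di = if (tn + ts > 0) (tn - ts) / (tn + ts) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(sliding = do.call(rbind, sliding), headline = do.call(rbind, headline))
}

#' Session-start recency analysis across an experiment
#'
#' Fits exponential decays to the across-session average of the observed
#' activity, the speed-predicted activity, the speed-adjusted residual and
#' the movement speed, and runs the observed-vs-predicted cluster-based
#' permutation test over the first `fit_window` seconds (sessions as paired
#' events).
#'
#' @param run an `experiment_run`.
#' @param fit_window seconds from session start (default 180).
#' @param n_perm permutations for the cluster test (default 500).
#' @param seed seed for the permutation null.
#' @return list with `tau` (named: observed, predicted, residual, speed),
#'   `fits` (the decay_fit objects), `cluster` (cluster_result) and
#'   `per_session` (per-session residual decay fits).
#' @export
analyze_recency <- function(run, fit_window = 180, n_perm = 500, seed = 1) {
  rate <- run$sessions[[1]]$rate
  nwin <- round(fit_window * rate)
  obs <- t(vapply(run$sessions, function(s) s$dff[seq_len(nwin)], numeric(nwin)))
  pred <- t(vapply(run$sessions, function(s) s$speed_model$predicted[seq_len(nwin)],
                   numeric(nwin)))
  spd <- t(vapply(run$sessions, function(s) {
    moving_average(s$speed, run$config$smooth_window, rate)[seq_len(nwin)]
  }, numeric(nwin)))
  tt <- (seq_len(nwin) - 1) / rate
  fits <- list(observed = fit_exponential_decay(colMeans(obs), tt, fit_window),
               predicted = fit_exponential_decay(colMeans(pred), tt, fit_window),
               residual = fit_exponential_decay(colMeans(obs - pred), tt, fit_window),
               speed = fit_exponential_decay(colMeans(spd), tt, fit_window))
  per_session <- vapply(run$sessions, function(s) {
    fit_exponential_decay(s$speed_model$residual, s$t, fit_window)$tau
  }, numeric(1))
  cluster <- cluster_permutation_test(obs, pred, dt = 1 / rate,
                                      n_perm = n_perm, seed = seed)
  list(tau = vapply(fits, function(f) f$tau, numeric(1)), fits = fits,
       cluster = cluster, per_session_residual_tau = per_session)
}

#' Event-triggered cluster tests per behavior
#'
#' Pools filtered bouts of each behavior across sessions, builds warped
#' profiles of the observed and speed-predicted activity on identical bouts,
#' and tests their difference over the warped bout core with the
#' cluster-based permutation test.  Exploration behaviors are additionally
#' split by task phase.
#'
#' @param run an `experiment_run`.
#' @param behaviors ethogram columns to analyze.
#' @param n_perm permutations (default 1000).
#' @param seed base seed; each comparison derives its own.
#' @param min_dur,isolation bout filter parameters (seconds).
#' @param n_core warped core grid length (default 100).
#' @return named list per comparison with `n_bouts`, `cluster`
#'   (cluster_result over the core), `profile_obs`, `profile_pred`,
#'   `median_duration`.
#' @export
analyze_bout_clusters <- function(run,
                                  behaviors = c("locomotion", "grooming",
                                                "rearing", "explore_stat",
                                                "explore_nonstat"),
                                  n_perm = 1000, seed = 1,
                                  min_dur = 2, isolation = 4, n_core = 100) {
  comparisons <- list()
  for (b in behaviors) {
    splits <- if (startsWith(b, "explore")) c("sample", "test") else list(NULL)
    for (ph in splits) {
      rows_obs <- list(); rows_pred <- list(); durs <- numeric(0)
      for (s in run$sessions) {
        if (!is.null(ph) && s$meta$phase != ph) next
        bouts <- extract_bouts(s$etho[[b]], s$t, min_dur, isolation,
                               behavior = b, session_id = s$meta$session_id)
        if (!nrow(bouts)) next
        for (k in seq_len(nrow(bouts))) {
          wo <- warp_bout(s$dff, s$t, s$rate, bouts[k, ], n_core = n_core)
          wp <- warp_bout(s$speed_model$predicted, s$t, s$rate, bouts[k, ],
                          n_core = n_core)
          if (is.null(wo) || is.null(wp)) next
          rows_obs[[length(rows_obs) + 1L]] <- wo
          rows_pred[[length(rows_pred) + 1L]] <- wp
          durs <- c(durs, bouts$duration[k])
        }
      }
      nm <- if (is.null(ph)) b else paste(b, ph, sep = "_")
      if (length(rows_obs) < 2) {
        comparisons[[nm]] <- list(n_bouts = length(rows_obs), cluster = NULL)
        next
      }
      obs <- do.call(rbind, rows_obs)
      pred <- do.call(rbind, rows_pred)
      n_pre <- round(5 * run$sessions[[1]]$rate)
      core_cols <- n_pre + seq_len(n_core)
      dt_core <- median(durs) / n_core
      cl <- cluster_permutation_test(obs[, core_cols, drop = FALSE],
                                     pred[, core_cols, drop = FALSE],
                                     dt = dt_core, n_perm = n_perm,
                                     seed = derive_seed(seed, length(comparisons) + 1L))
      comparisons[[nm]] <- list(
        n_bouts = nrow(obs), cluster = cl, median_duration = median(durs),
        mean_obs = colMeans(obs), mean_pred = colMeans(pred))
    }
  }
  comparisons
}

#' Fit the experiment-level mixed model and its derived analyses
#'
#' Assembles the frame table across sessions, fits the LMM, computes the
#' novelty interaction contrast, the sliding-window object coefficients and
#' the OLS meta-model on their differences.
#'
#' @param run an `experiment_run`.
#' @param random_spec random-effects ladder start (default `"diag"`).
#' @param sliding run the sliding-window analysis (default TRUE).
#' @param thin frame thinning passed to [assemble_frame_table()].
#' @return list with `table`, `fit`, `contrast`, `sliding`, `meta`.
#' @export
analyze_lmm <- function(run, random_spec = "diag", sliding = TRUE, thin = 1L) {
  sess <- lapply(run$sessions, function(s) {
    list(dff = s$dff, speed = s$speed, etho = s$etho, meta = s$meta)
  })
  # dff and log2speed in the run are already smoothed once at preparation
  tab <- assemble_frame_table(sess, video_rate = run$sessions[[1]]$rate,
                              smooth_window = NULL, standardize = FALSE,
                              thin = thin)
  # reuse the prepared (smoothed) log2speed rather than recomputing raw
  tab$log2speed <- unlist(lapply(run$sessions, function(s) {
    s$log2speed[seq(1L, length(s$log2speed), by = as.integer(thin))]
  }))
  fit <- fit_lmm(tab, random_spec = random_spec)
  contrast <- novelty_contrast(fit)
  out <- list(table = tab, fit = fit, contrast = contrast)
  if (sliding) {
    sl <- sliding_lmm(tab, video_rate = run$sessions[[1]]$rate)
    out$sliding <- sl
    out$meta <- tryCatch(ols_meta(sl), error = function(e) NULL)
  }
  out
}

#' Summary tables for a completed experiment
#'
#' Bundles the speed-coding, discrimination-index, recency, bout-cluster and
#' mixed-model analyses into the tables a study report needs.
#'
#' @param run an `experiment_run`.
#' @param seed seed for the permutation analyses.
#' @param n_perm_recency,n_perm_bouts permutation counts (defaults 500 and
#'   1000).
#' @param lmm_thin frame thinning for the mixed-model fits.
#' @return list of class `experiment_summary`.
#' @export
summarize_experiment <- function(run, seed = 1, n_perm_recency = 500,
                                 n_perm_bouts = 1000, lmm_thin = 1L) {
  speed <- analyze_speed(run)
  di <- analyze_di(run)
  recency <- analyze_recency(run, n_perm = n_perm_recency, seed = seed)
  bouts <- analyze_bout_clusters(run, n_perm = n_perm_bouts,
                                 seed = derive_seed(seed, 7L))
  lmm <- analyze_lmm(run, thin = lmm_thin)
  structure(list(speed = speed, di = di, recency = recency,
                 bout_clusters = bouts, lmm = lmm),
            class = "experiment_summary")
}
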