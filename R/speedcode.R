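#' Floored log2 speed transform
#'
#' `log2(max(speed, floor))`.  The floor (default 1 cm/s, giving log2 = 0)
#' keeps near-zero speeds from mapping to minus infinity; it is recorded in
#' downstream outputs and configurable.
#'
#' @param speed speed series (cm/s, >= 0).
#' @param floor floor in cm/s (default 1).
#' @return numeric series.
#' @export
log2_speed <- function(speed, floor = 1) {
  if (any(speed < 0, na.rm = TRUE)) stop("speed must be >= 0", call. = FALSE)
  log2(pmax(speed, floor))
}

#' Timescale-dependent speed-activity correlation curve
#'
#' Pearson correlation between delta-F/F and log2 speed after smoothing both
#' series with each window of a logarithmically spaced set (default powers
#' of two from 0.25 to 256 s in half-octave steps).  Windows longer than the
#' session yield `NA`.
#'
#' @param dff delta-F/F series on the video clock.
#' @param log2speed log2-speed series, same clock.
#' @param rate sampling rate in Hz.
#' @param windows smoothing windows in seconds (strictly increasing).
#' @return list of class `timescale_curve` with `windows`, `r`,
#'   `best_window` (argmax of r among finite entries).
#' @export
timescale_correlation <- function(dff, log2speed, rate,
                                  windows = 2^seq(-2, 8, by = 0.5)) {
  n <- length(dff)
  r <- vapply(windows, function(w) {
    if (w * rate > n) return(NA_real_)
    cor(moving_average(dff, w, rate), moving_average(log2speed, w, rate))
  }, numeric(1))
  best <- if (all(is.na(r))) NA_real_ else windows[which.max(r)]
  structure(list(windows = windows, r = r, best_window = best),
            class = "timescale_curve")
}

#' Per-session speed model: regression of activity on log2 speed
#'
#' Ordinary least squares of the (z-scored, smoothed) delta-F/F on the
#' smoothed log2-speed series.  The predicted series is the speed-predicted
#' cholinergic activity; the residual is the speed-adjusted activity.
#'
#' @param dff_z activity series.
#' @param log2speed regressor series, same length.
#' @return list of class `speed_model` with `slope`, `intercept`, `r`
#'   (Pearson correlation), `predicted` and `residual` series.
#' @export
fit_speed_model <- function(dff_z, log2speed) {
  v <- var(log2speed)
  if (!is.finite(v) || v <= 0) stop("zero-variance regressor", call. = FALSE)
  slope <- cov(dff_z, log2speed) / v
  intercept <- mean(dff_z) - slope * mean(log2speed)
  predicted <- intercept + slope * log2speed
  structure(list(slope = slope, intercept = intercept,
                 r = cor(dff_z, log2speed),
                 predicted = predicted, residual = dff_z - predicted),
            class = "speed_model")
}

#' Fit an exponential decay to the session-start signal
#'
#' Nonlinear least squares of `A * exp(-t / tau) + offset` over
#' `[0, fit_window]` seconds, with multi-start over a tau grid spanning
#' 5-120 s.  Near-constant input is flagged degenerate (`A ~ 0`, tau
#' unidentifiable) instead of erroring.
#'
#' @param x signal series.
#' @param t time in seconds, same length.
#' @param fit_window seconds from session start to fit over (default 180).
#' @param tau_grid multi-start grid for tau (seconds).
#' @param offset if `FALSE`, fit without the offset term (sensitivity mode).
#' @return list of class `decay_fit` with `A`, `tau`, `offset`, `rss`,
#'   `fit_window`, `degenerate`.
#' @export
fit_exponential_decay <- function(x, t, fit_window = 180,
                                  tau_grid = c(5, 15, 30, 60, 120),
                                  offset = TRUE) {
  sel <- t - t[1] <= fit_window
  if (sum(sel) < 10) stop("fit window must cover at least 10 samples", call. = FALSE)
  xx <- x[sel]
  tt <- t[sel] - t[1]
  if (sd(xx) < 1e-12 * (1 + abs(mean(xx)))) {
    return(structure(list(A = 0, tau = NA_real_, offset = mean(xx),
                          rss = sum((xx - mean(xx))^2),
                          fit_window = fit_window, degenerate = TRUE),
                     class = "decay_fit"))
  }
  best <- NULL
  diag_msgs <- character(0)
  head_mean <- mean(xx[tt <= max(1, tt[10])])
  tail_mean <- mean(xx[tt > 0.8 * fit_window])
  # tau is bounded away from the degenerate linear regime (tau >> window)
  tau_max <- 10 * fit_window
  resid_fn <- if (offset) {
    function(p) xx - (p[1] * exp(-tt / p[2]) + p[3])
  } else {
    function(p) xx - p[1] * exp(-tt / p[2])
  }
  for (tau0 in tau_grid) {
    A0 <- head_mean - if (offset) tail_mean else 0
    if (abs(A0) < 1e-3 * sd(xx)) A0 <- sd(xx)  # avoid a singular start
    p0 <- if (offset) c(A0, tau0, tail_mean) else c(A0, tau0)
    lo <- if (offset) c(-Inf, 1e-3, -Inf) else c(-Inf, 1e-3)
    hi <- if (offset) c(Inf, tau_max, Inf) else c(Inf, tau_max)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, sprintf("tau0=%g: %s", tau0, conditionMessage(fit)))
      next
    }
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) {
      best <- list(A = fit$par[1], tau = fit$par[2],
                   offset = if (offset) fit$par[3] else 0, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("exponential fit failed for all starts: ",
         paste(diag_msgs, collapse = "; "), call. = FALSE)
  }
  structure(c(best, list(fit_window = fit_window, degenerate = FALSE)),
            class = "decay_fit")
}

#' Recency analysis: decay fits of observed, predicted and residual activity
#'
#' Fits [fit_exponential_decay()] to the observed activity, the
#' speed-predicted activity and the speed-adjusted residual over the first
#' `fit_window` seconds of the session, giving the three decay time
#' constants that dissociate the recency signal from movement speed.
#'
#' @param observed observed activity series.
#' @param model a [fit_speed_model()] result on the same series.
#' @param t time in seconds.
#' @param fit_window seconds (default 180).
#' @return list with `decay_fit` elements `observed`, `predicted`,
#'   `residual`.
#' @export
recency_analysis <- function(observed, model, t, fit_window = 180) {
  list(observed = fit_exponential_decay(observed, t, fit_window),
       predicted = fit_exponential_decay(model$predicted, t, fit_window),
       residual = fit_exponential_decay(model$residual, t, fit_window))
}
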