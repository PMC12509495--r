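#' Adjusted isosbestic control signal
#'
#' Subtracts the isosbestic control from the calcium signal, fits a
#' second-degree polynomial in time to the difference by least squares, and
#' adds the fitted curve back to the control.  Time is centered at the
#' session midpoint for numerical conditioning; the fit is affine-invariant
#' to that choice.
#'
#' @param s calcium-dependent signal (a.u.).
#' @param c isosbestic control signal (a.u.), same length.
#' @param t time in seconds, same length.
#' @return list with `c_adj` (adjusted control series) and `poly_coeffs`
#'   (the three fitted coefficients on centered time).
#' @export
adjusted_control <- function(s, c, t) {
  n <- length(s)
  if (length(c) != n || length(t) != n) stop("length mismatch", call. = FALSE)
  if (n < 3) stop("degenerate fit: need at least 3 samples", call. = FALSE)
  tc <- t - mean(t)
  X <- cbind(1, tc, tc^2)
  fit <- lm.fit(X, s - c)
  list(c_adj = c + as.numeric(X %*% fit$coefficients),
       poly_coeffs = unname(fit$coefficients))
}

#' Scale the adjusted control against the calcium signal
#'
#' Finds `alpha` and `beta` minimizing `sum((s - (c * alpha + beta))^2)`.
#' The objective is an ordinary least-squares problem with the closed-form
#' unique minimizer `alpha = cov(s, c) / var(c)`,
#' `beta = mean(s) - alpha * mean(c)`.
#'
#' @param s calcium signal.
#' @param c_adj adjusted control from [adjusted_control()].
#' @return list of class `control_fit` with `alpha`, `beta`, `objective`
#'   (residual sum of squares).
#' @export
fit_scale <- function(s, c_adj) {
  n <- length(s)
  if (length(c_adj) != n || n < 2) stop("need equal lengths >= 2", call. = FALSE)
  v <- var(c_adj)
  if (!is.finite(v) || v <= 0) {
    stop("alpha undefined: control signal has zero variance", call. = FALSE)
  }
  alpha <- cov(s, c_adj) / v
  beta <- mean(s) - alpha * mean(c_adj)
  res <- s - (c_adj * alpha + beta)
  structure(list(alpha = alpha, beta = beta, objective = sum(res^2)),
            class = "control_fit")
}

#' @importFrom stats cov
NULL

#' Compute delta-F/F from signal and fitted control
#'
#' Element-wise `(s - f) / f` with `f = c * alpha + beta` the fitted control.
#'
#' @param s calcium signal.
#' @param fitted_control the series `c * alpha + beta` (strictly positive).
#' @return numeric delta-F/F series.
#' @export
compute_dff <- function(s, fitted_control) {
  bad <- which(fitted_control <= 0)
  if (length(bad)) {
    stop(sprintf("fitted control is nonpositive first at index %d", bad[1]),
         call. = FALSE)
  }
  (s - fitted_control) / fitted_control
}

#' Centered moving average with shrinking edges
#'
#' Boxcar smoothing with a centered window; at the series edges the window
#' shrinks (truncated averaging) so the series keeps its length and the
#' session start — where the recency analysis lives — is not biased by
#' padding.  Interior samples (a full window away from the edges) equal the
#' exact centered mean.
#'
#' @param x numeric series.
#' @param window window length in seconds.
#' @param rate sampling rate in Hz.
#' @return smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window, rate) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  w <- round(window * rate)
  if (w <= 1) {
    warning("window shorter than one sample period; returning input unchanged")
    return(x)
  }
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fourier-based resampling to a new uniform rate
#'
#' Resamples a uniformly sampled series via Fourier interpolation: the line
#' through the endpoints is removed (so the periodic extension is
#' value-continuous and edge ringing is negligible), the spectrum is
#' truncated/extended to the target length, and the line is added back
#' evaluated on the new grid.  A pure sinusoid below the target Nyquist is
#' reconstructed with relative RMS error well below 0.1%.
#'
#' @param x numeric series at rate `rate`.
#' @param rate input sampling rate (Hz).
#' @param target_rate output sampling rate (Hz).
#' @return resampled series of length `round(length(x) * target_rate / rate)`.
#' @export
resample_series <- function(x, rate, target_rate) {
  if (target_rate <= 0) stop("target_rate must be > 0", call. = FALSE)
  n <- length(x)
  if (target_rate == rate) return(x)
  m <- round(n * target_rate / rate)
  i <- seq_len(n) - 1
  slope <- (x[n] - x[1]) / (n - 1)
  r <- x - (x[1] + slope * i)
  X <- fft(r)
  Y <- complex(length.out = m)
  h <- min(n, m) %/% 2
  Y[1] <- X[1]
  Y[2:(h + 1)] <- X[2:(h + 1)]
  Y[m:(m - h + 2)] <- X[n:(n - h + 2)]
  y <- Re(fft(Y, inverse = TRUE)) / n
  j <- (seq_len(m) - 1) * (rate / target_rate)
  y + x[1] + slope * j
}

#' Z-score a series
#'
#' @param x numeric series with positive variance.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s <= 0) stop("zero variance: z-score undefined", call. = FALSE)
  (x - mean(x)) / s
}

#' Full delta-F/F preprocessing for one session
#'
#' Applies the pipeline in fixed order: adjusted-control correction at the
#' native photometry rate, Fourier resampling to the video clock, moving
#' average smoothing, and per-session z-scoring.  Each applied transform is
#' recorded in `stage_tags`.
#'
#' @param session a `photometry_session` (fields `f465`, `f405`, `t`,
#'   `rate`, `meta`).
#' @param target_rate output rate in Hz (default 30, the video clock).
#' @param window smoothing window in seconds (default 0.5); `NULL` skips
#'   smoothing.
#' @param standardize if `TRUE` (default) z-score per session.
#' @return list of class `dff_series` with `values`, `t`, `rate`,
#'   `stage_tags` and `control_fit`.
#' @export
preprocess_session <- function(session, target_rate = 30, window = 0.5,
                               standardize = TRUE) {
  adj <- adjusted_control(session$f465, session$f405, session$t)
  fit <- fit_scale(session$f465, adj$c_adj)
  dff <- compute_dff(session$f465, adj$c_adj * fit$alpha + fit$beta)
  tags <- "corrected"
  rate <- session$rate
  if (target_rate != rate) {
    dff <- resample_series(dff, rate, target_rate)
    rate <- target_rate
    tags <- c(tags, sprintf("resampled-%g", target_rate))
  }
  if (!is.null(window)) {
    dff <- moving_average(dff, window, rate)
    tags <- c(tags, sprintf("smoothed-%g", window))
  }
  if (standardize) {
    dff <- zscore(dff)
    tags <- c(tags, "zscored")
  }
  structure(list(values = dff,
                 t = session$t[1] + (seq_along(dff) - 1) / rate,
                 rate = rate, stage_tags = tags, control_fit = fit,
                 meta = session$meta),
            class = "dff_series")
}
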