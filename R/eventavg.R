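profile_grid <- function(rate, pre, post, n_core) {
  n_pre <- round(pre * rate)
  n_post <- round(post * rate)
  c(seq(-pre, -1 / rate, length.out = n_pre),      # seconds before onset
    seq(0, 1, length.out = n_core),                # relative time within bout
    1 + seq(1 / rate, post, length.out = n_post))  # seconds after offset (+1)
}

#' Linearly time-warp one bout onto a fixed-length grid
#'
#' Copies `pre` and `post` seconds of signal at the native rate around the
#' bout and linearly interpolates the samples between onset and offset onto
#' `n_core` evenly spaced points, so bouts of different durations can be
#' averaged.  When `n_core` equals the bout's sample count the core equals
#' the original samples.
#'
#' @param signal numeric series on the video clock.
#' @param t time in seconds per sample.
#' @param rate sampling rate in Hz.
#' @param bout one row of a `bout_set` (uses `onset_i`, `offset_i`).
#' @param pre,post margins in seconds (defaults 5).
#' @param n_core core grid length (default 100).
#' @return numeric row vector of length `round(pre*rate) + n_core +
#'   round(post*rate)`, or `NULL` when the bout plus margins leaves the
#'   session.
#' @export
warp_bout <- function(signal, t, rate, bout, pre = 5, post = 5, n_core = 100) {
  n <- length(signal)
  n_pre <- round(pre * rate)
  n_post <- round(post * rate)
  i0 <- bout$onset_i
  i1 <- bout$offset_i - 1L  # last frame inside the half-open bout
  if (i1 - i0 + 1L < 2L) stop("bout shorter than 2 samples", call. = FALSE)
  if (i0 - n_pre < 1L || i1 + n_post > n) return(NULL)
  core_raw <- signal[i0:i1]
  core <- approx(seq_along(core_raw), core_raw,
                 xout = seq(1, length(core_raw), length.out = n_core))$y
  c(signal[(i0 - n_pre):(i0 - 1L)], core, signal[(i1 + 1L):(i1 + n_post)])
}

#' Event-triggered warped profile over a bout set
#'
#' Stacks [warp_bout()] rows for every bout that fits inside the session
#' (bouts too close to the edges are dropped and counted) and returns the
#' per-bout matrix with column mean and SEM.
#'
#' @inheritParams warp_bout
#' @param bouts a `bout_set`.
#' @return list of class `warped_profile` with `per_bout` (bouts x time
#'   matrix), `mean`, `sem`, `grid`, `included` (row index into `bouts`)
#'   and `n_dropped_edge`.
#' @export
build_profile <- function(signal, t, rate, bouts, pre = 5, post = 5,
                          n_core = 100) {
  rows <- lapply(seq_len(nrow(bouts)), function(k) {
    warp_bout(signal, t, rate, bouts[k, ], pre, post, n_core)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (sum(keep) < 2) stop("need at least 2 bouts inside the session", call. = FALSE)
  m <- do.call(rbind, rows[keep])
  structure(list(per_bout = m,
                 mean = colMeans(m),
                 sem = apply(m, 2, sd) / sqrt(nrow(m)),
                 grid = profile_grid(rate, pre, post, n_core),
                 included = which(keep),
                 n_dropped_edge = sum(!keep)),
            class = "warped_profile")
}

#' Threshold-crossing time of activity around a bout transition
#'
#' Estimates when the signal rises (onset side) or falls (offset side)
#' relative to a behavioral transition.  The baseline is the mean activity
#' over `baseline_win` seconds before the onset (after the offset for the
#' offset side); the threshold is `baseline + frac * (during - baseline)`
#' with `during` the mean activity over the bout.  All crossings of the
#' threshold in the direction of the effect within the search window
#' (onset: 3 s before to 1 s after; offset: 1 s before to 3 s after) are
#' located with linear interpolation between straddling samples, and their
#' median is the bout's crossing time (seconds relative to the transition).
#'
#' @param signal numeric series.
#' @param t time in seconds.
#' @param rate sampling rate (Hz).
#' @param bout one `bout_set` row.
#' @param side `"onset"` or `"offset"`.
#' @param baseline_win baseline window in seconds (default 5).
#' @param frac threshold fraction of the during-baseline difference
#'   (default 0.98).
#' @param search numeric length-2 window (seconds relative to the
#'   transition); defaults to `c(-3, 1)` for onsets and `c(-1, 3)` for
#'   offsets.
#' @return crossing time in seconds relative to the transition, or `NA`
#'   when the signal never crosses (or the effect is degenerate).
#' @export
threshold_crossing <- function(signal, t, rate, bout,
                               side = c("onset", "offset"),
                               baseline_win = 5, frac = 0.98, search = NULL) {
  side <- match.arg(side)
  n <- length(signal)
  i0 <- bout$onset_i
  i1 <- bout$offset_i - 1L
  nb <- round(baseline_win * rate)
  if (side == "onset") {
    ref_i <- i0
    base_idx <- (i0 - nb):(i0 - 1L)
    search <- search %||% c(-3, 1)
  } else {
    ref_i <- i1 + 1L
    base_idx <- (i1 + 1L):(i1 + nb)
    search <- search %||% c(-1, 3)
  }
  if (min(base_idx) < 1L || max(base_idx) > n) return(NA_real_)
  baseline <- mean(signal[base_idx])
  during <- mean(signal[i0:i1])
  if (during == baseline) return(NA_real_)
  thr <- baseline + frac * (during - baseline)
  upward <- during > baseline
  lo <- max(1L, ref_i + floor(search[1] * rate))
  hi <- min(n - 1L, ref_i + ceiling(search[2] * rate))
  if (hi <= lo) return(NA_real_)
  idx <- lo:hi
  x0 <- signal[idx]
  x1 <- signal[idx + 1L]
  crossing <- if (upward) (x0 < thr & x1 >= thr) else (x0 > thr & x1 <= thr)
  if (!any(crossing)) return(NA_real_)
  ci <- idx[crossing]
  fracstep <- (thr - signal[ci]) / (signal[ci + 1L] - signal[ci])
  times <- (ci - ref_i + fracstep) / rate
  median(times)
}

#' Per-bout response-timing estimate
#'
#' Applies [threshold_crossing()] to every bout and summarizes the crossing
#' times; bouts without a crossing are excluded and counted.
#'
#' @inheritParams threshold_crossing
#' @param bouts a `bout_set`.
#' @return list of class `timing_estimate` with `per_bout_crossing`
#'   (seconds, `NA` when absent), `median`, `sd`, `n_excluded_no_crossing`.
#' @export
timing_estimate <- function(signal, t, rate, bouts,
                            side = c("onset", "offset"),
                            baseline_win = 5, frac = 0.98, search = NULL) {
  side <- match.arg(side)
  cr <- vapply(seq_len(nrow(bouts)), function(k) {
    threshold_crossing(signal, t, rate, bouts[k, ], side,
                       baseline_win, frac, search)
  }, numeric(1))
  structure(list(per_bout_crossing = cr,
                 median = median(cr, na.rm = TRUE),
                 sd = sd(cr, na.rm = TRUE),
                 n_excluded_no_crossing = sum(is.na(cr))),
            class = "timing_estimate")
}

#' Compare observed and speed-predicted response timing
#'
#' Pairs per-bout crossing times from two [timing_estimate()]s computed on
#' the same bouts, and tests the median difference with a Wilcoxon
#' signed-rank test.
#'
#' @param observed_est,predicted_est `timing_estimate` objects over the same
#'   bout set.
#' @return list with `differences` (observed minus predicted, valid pairs),
#'   `median_diff`, `p_value`, `n`, `low_n` (fewer than 5 valid pairs).
#' @export
timing_comparison <- function(observed_est, predicted_est) {
  a <- observed_est$per_bout_crossing
  b <- predicted_est$per_bout_crossing
  if (length(a) != length(b)) stop("estimates cover different bout sets", call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  p <- if (n >= 1 && any(d != 0)) {
    suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE)$p.value)
  } else {
    1
  }
  list(differences = d, median_diff = if (n) median(d) else NA_real_,
       p_value = p, n = n, low_n = n < 5)
}
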