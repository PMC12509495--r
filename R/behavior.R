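#' Movement speed from neck positions
#'
#' Frame-to-frame Euclidean displacement of the neck marker multiplied by the
#' frame rate.  The first frame copies the second so the series keeps the
#' length of the position series and stays aligned with the photometry clock
#' at session start.
#'
#' @param traj data.frame with `neck_x`, `neck_y` columns (cm).
#' @param video_rate frames per second.
#' @return numeric vector of speeds (cm/s), same length as the trajectory.
#' @export
compute_speed <- function(traj, video_rate) {
  if (nrow(traj) < 2) stop("need at least 2 frames to compute speed", call. = FALSE)
  x <- traj$neck_x
  y <- traj$neck_y
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop("non-finite neck positions at frames: ",
         paste(utils::head(bad - 1L, 10), collapse = ", "), call. = FALSE)
  }
  d <- sqrt(diff(x)^2 + diff(y)^2) * video_rate
  c(d[1], d)
}

#' Relabel generic object exploration by nose position
#'
#' Frames flagged as generic object exploration are assigned to the
#' stationary or nonstationary object when the nose lies within `radius` cm
#' of that object's center (the nearer center when within both radii, with
#' an exact tie broken deterministically toward the stationary object).
#' Exploration frames outside both radii are relabeled background.
#'
#' @param explore 0/1 vector: generic object-exploration flag per frame.
#' @param nose_xy two-column matrix (cm) of nose positions.
#' @param objects list with `stat` and `nonstat` (x, y) centers.
#' @param radius cm; default 10.
#' @return list with 0/1 vectors `explore_stat` and `explore_nonstat`.
#' @export
classify_object_exploration <- function(explore, nose_xy, objects, radius = 10) {
  explore <- as.integer(explore > 0)
  d_stat <- sqrt((nose_xy[, 1] - objects$stat[1])^2 +
                 (nose_xy[, 2] - objects$stat[2])^2)
  d_non <- sqrt((nose_xy[, 1] - objects$nonstat[1])^2 +
                (nose_xy[, 2] - objects$nonstat[2])^2)
  in_stat <- d_stat <= radius
  in_non <- d_non <= radius
  # ties (equidistant within both radii) go to the stationary object
  to_stat <- explore == 1L & in_stat & (!in_non | d_stat <= d_non)
  to_non <- explore == 1L & in_non & !to_stat
  list(explore_stat = as.integer(to_stat),
       explore_nonstat = as.integer(to_non))
}

#' Discrimination index
#'
#' Normalized difference in exploration time between the nonstationary
#' (moved) and stationary objects:
#' `DI = (t_nonstat - t_stat) / (t_nonstat + t_stat)`.
#'
#' @param t_nonstat,t_stat exploration times in seconds (>= 0).
#' @return list with `di`, `t_nonstat`, `t_stat`.
#' @export
#' @examples
#' discrimination_index(3, 1)$di  # 0.5
discrimination_index <- function(t_nonstat, t_stat) {
  if (t_nonstat < 0 || t_stat < 0) stop("exploration times must be >= 0", call. = FALSE)
  tot <- t_nonstat + t_stat
  if (tot <= 0) stop("undefined DI: no exploration time in window", call. = FALSE)
  list(di = (t_nonstat - t_stat) / tot, t_nonstat = t_nonstat, t_stat = t_stat)
}

#' Sliding-window discrimination index
#'
#' DI computed over consecutive windows of exploration-time sums; windows
#' with zero total exploration yield `NA` rather than zero.
#'
#' @param etho ethogram data.frame with `explore_stat` and `explore_nonstat`
#'   0/1 columns on the video clock.
#' @param video_rate frames per second.
#' @param window window length in seconds (default 180).
#' @param step step between window starts in seconds (default 30).
#' @return data.frame with `start`, `end`, `t_nonstat`, `t_stat`, `di`.
#' @export
sliding_di <- function(etho, video_rate, window = 180, step = 30) {
  n <- nrow(etho)
  dur <- n / video_rate
  if (window > dur) stop("window exceeds session length", call. = FALSE)
  starts <- seq(0, dur - window, by = step)
  out <- lapply(starts, function(s) {
    i0 <- floor(s * video_rate) + 1L
    i1 <- min(n, floor((s + window) * video_rate))
    tn <- sum(etho$explore_nonstat[i0:i1]) / video_rate
    ts <- sum(etho$explore_stat[i0:i1]) / video_rate
    di <- if (tn + ts > 0) (tn - ts) / (tn + ts) else NA_real_
    data.frame(start = s, end = s + window, t_nonstat = tn, t_stat = ts, di = di)
  })
  do.call(rbind, out)
}

#' Extract filtered behavioral bouts from a binary flag series
#'
#' Maximal runs of ones become candidate bouts; bouts shorter than `min_dur`
#' are removed, and a surviving bout is excluded if any same-behavior frame
#' lies within `isolation` seconds before its onset or after its offset.
#' Onsets/offsets are half-open frame intervals `[onset, offset)` on the
#' video clock.
#'
#' @param flags 0/1 vector.
#' @param t time (seconds) per frame, uniform.
#' @param min_dur minimum bout duration in seconds (default 2).
#' @param isolation temporal-isolation margin in seconds (default 4).
#' @param behavior optional label stored with the bouts.
#' @param session_id optional session identifier.
#' @return data.frame (class `bout_set`) with `behavior`, `onset_t`,
#'   `offset_t`, `duration`, `onset_i`, `offset_i` (frame indices, 1-based,
#'   half-open) and `session_id`.
#' @export
extract_bouts <- function(flags, t, min_dur = 2, isolation = 4,
                          behavior = "behavior", session_id = NA_character_) {
  flags <- as.integer(flags > 0)
  n <- length(flags)
  dt <- if (n > 1) t[2] - t[1] else 1
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  onset_i <- starts[on]
  offset_i <- ends[on] + 1L  # half-open
  dur <- (offset_i - onset_i) * dt
  keep <- dur >= min_dur - 1e-9
  onset_i <- onset_i[keep]
  offset_i <- offset_i[keep]
  dur <- dur[keep]
  iso_n <- round(isolation / dt)
  ok <- vapply(seq_along(onset_i), function(k) {
    pre <- max(1L, onset_i[k] - iso_n):(onset_i[k] - 1L)
    post <- offset_i[k]:min(n, offset_i[k] + iso_n - 1L)
    pre_ok <- onset_i[k] == 1L || !any(flags[pre] == 1L)
    post_ok <- offset_i[k] > n || !any(flags[post] == 1L)
    pre_ok && post_ok
  }, logical(1))
  out <- data.frame(
    behavior = rep(behavior, sum(ok)),
    onset_t = t[1] + (onset_i[ok] - 1L) * dt,
    offset_t = t[1] + (offset_i[ok] - 1L) * dt,
    duration = dur[ok],
    onset_i = onset_i[ok],
    offset_i = offset_i[ok],
    session_id = rep(session_id, sum(ok)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bout_set", "data.frame")
  out
}

#' Per-behavior proportion of total behaviors on an event-aligned grid
#'
#' At each aligned time point of the warped event grid, the percentage of
#' each behavior (background included) among all behavior occurrences at
#' that point.  Percentages sum to 100 at every point.
#'
#' @param etho ethogram data.frame with one 0/1 column per behavior
#'   (including `background`).
#' @param bouts a `bout_set` defining the alignment events.
#' @param video_rate frames per second.
#' @param pre,post margins in seconds around onset/offset (defaults 5).
#' @param n_core warped core grid length (default 100).
#' @return matrix (aligned time x behaviors) of percentages, with the grid
#'   in attribute `grid` (relative time; margins in seconds, core in 0..1).
#' @export
proportion_of_total <- function(etho, bouts, video_rate, pre = 5, post = 5,
                                n_core = 100) {
  beh <- setdiff(names(etho), c("frame", "t"))
  n <- nrow(etho)
  tt <- (seq_len(n) - 1) / video_rate
  mats <- lapply(beh, function(b) {
    build_profile(etho[[b]], tt, video_rate, bouts,
                  pre = pre, post = post, n_core = n_core)$per_bout
  })
  counts <- Reduce(`+`, lapply(mats, colMeans))
  out <- vapply(mats, function(m) 100 * colMeans(m) / pmax(counts, 1e-12),
                numeric(length(counts)))
  colnames(out) <- beh
  attr(out, "grid") <- profile_grid(video_rate, pre, post, n_core)
  out
}
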