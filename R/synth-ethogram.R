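#' Simulate a frame-level ethogram for a synthetic trajectory
#'
#' Maps the trajectory's hidden behavioral states to binary frame labels.
#' Grooming, rearing and locomotion are mutually exclusive; object
#' exploration is position-gated (the nose must be within `radius` cm of the
#' episode's target object) and is the only behavior allowed to co-occur
#' with locomotion (fast approach frames within an exploration episode).
#' Approach frames outside the radius are labeled locomotion when the animal
#' is moving, background otherwise.  `background` is 1 exactly when all
#' other flags are 0.
#'
#' @param cfg a [generator_config()].
#' @param traj a trajectory from [simulate_trajectory()].
#' @param radius exploration radius in cm (default 10, matching the
#'   classification rule used on real pose data).
#' @return An `ethogram` data.frame with columns `frame`, `locomotion`,
#'   `grooming`, `rearing`, `explore_stat`, `explore_nonstat`, `background`.
#' @export
simulate_ethogram <- function(cfg, traj, radius = 10) {
  state <- attr(traj, "state")
  obj <- attr(traj, "object")
  n <- nrow(traj)
  objs <- session_objects(cfg)
  loco <- as.integer(state == "locomotion")
  groom <- as.integer(state == "grooming")
  rear <- as.integer(state == "rearing")
  expl_stat <- integer(n)
  expl_non <- integer(n)
  idx <- which(state == "explore")
  if (length(idx)) {
    for (ob in c("stat", "nonstat")) {
      sel <- idx[obj[idx] == ob]
      if (!length(sel)) next
      d <- sqrt((traj$nose_x[sel] - objs[[ob]][1])^2 +
                (traj$nose_y[sel] - objs[[ob]][2])^2)
      near <- sel[d <= radius]
      far <- setdiff(sel, near)
      if (ob == "stat") expl_stat[near] <- 1L else expl_non[near] <- 1L
      # fast frames within exploration episodes count as locomotion;
      # near-object fast frames co-occur with exploration
      fast_near <- near[traj$speed[near] > 5]
      loco[fast_near] <- 1L
      fast_far <- far[traj$speed[far] > 5]
      loco[fast_far] <- 1L
    }
  }
  background <- as.integer(loco + groom + rear + expl_stat + expl_non == 0L)
  etho <- data.frame(frame = traj$frame,
                     locomotion = loco, grooming = groom, rearing = rear,
                     explore_stat = expl_stat, explore_nonstat = expl_non,
                     background = background)
  class(etho) <- c("ethogram", "data.frame")
  etho
}
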