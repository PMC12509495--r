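#' Pointwise paired t statistics
#'
#' For each aligned time point (column), the paired t statistic
#' `t = mean(d) / (sd(d) / sqrt(n))` of the per-event differences
#' `d = a - b`.  Zero-variance columns yield `t = 0` (conservative; avoids
#' spurious infinite-mass clusters).
#'
#' @param a,b event x time matrices of equal shape (>= 2 rows).
#' @return numeric vector of t values per column.
#' @export
pointwise_paired_t <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrices must have equal shape", call. = FALSE)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 events", call. = FALSE)
  d <- a - b
  m <- colMeans(d)
  s2 <- (colSums(d^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tval <- ifelse(s2 <= .Machine$double.eps * 100, 0, m / sqrt(s2 / n))
  as.numeric(tval)
}

#' Form supra-threshold clusters from a t series
#'
#' Clusters are maximal contiguous runs where `|t|` exceeds the two-sided
#' critical value at level `alpha` with `n - 1` degrees of freedom; positive
#' and negative runs form separate clusters.  Cluster mass is the sum of t
#' values within the run; cluster length is the run duration in seconds.
#'
#' @param t_series t statistic per aligned time point.
#' @param n number of paired events (for the degrees of freedom).
#' @param dt grid spacing in seconds.
#' @param alpha cluster-forming significance level (default 0.05).
#' @return data.frame with `start_idx`, `end_idx`, `mass`, `length_s`,
#'   `sign`; zero rows when nothing exceeds the threshold.
#' @export
form_clusters <- function(t_series, n, dt, alpha = 0.05) {
  thr <- qt(1 - alpha / 2, df = n - 1)
  out <- list()
  for (sgn in c(1, -1)) {
    above <- if (sgn > 0) t_series > thr else t_series < -thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    for (k in sel) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        start_idx = starts[k], end_idx = ends[k],
        mass = sum(t_series[idx]), length_s = length(idx) * dt, sign = sgn)
    }
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      mass = numeric(0), length_s = numeric(0),
                      sign = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start_idx), , drop = FALSE]
}

# max |mass| and max length over clusters of one t series
max_cluster_stats <- function(t_series, thr, dt) {
  above <- abs(t_series) > thr
  if (!any(above)) return(c(0, 0))
  # split supra-threshold runs further wherever the sign flips
  sgn <- sign(t_series)
  grp <- cumsum(c(TRUE, diff(above) != 0 | (above[-1] & diff(sgn) != 0)))
  grp[!above] <- 0L
  masses <- tapply(t_series[above], grp[above], sum)
  lens <- tapply(t_series[above], grp[above], length)
  c(max(abs(masses)), max(lens) * dt)
}

#' Permutation null distributions of max cluster mass and length
#'
#' For a paired design (observed vs predicted per event), shuffling the
#' condition labels within an event equals flipping the sign of that event's
#' difference curve.  For each permutation the t series and clusters are
#' recomputed and the maximum absolute cluster mass and maximum cluster
#' length recorded (0 when no cluster forms), giving a single two-sided null
#' for positive and negative clusters.
#'
#' @param a,b event x time matrices.
#' @param dt grid spacing in seconds.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (mandatory; stored in the result).
#' @param alpha cluster-forming level (default 0.05).
#' @param exhaustive if `TRUE`, enumerate all `2^n` sign assignments instead
#'   of sampling (small n only).
#' @return list with `max_mass`, `max_length`, `n_perm`, `seed`.
#' @export
permutation_null <- function(a, b, dt, n_perm = 1000, seed, alpha = 0.05,
                             exhaustive = FALSE) {
  if (missing(seed)) stop("a seed is required for the permutation null", call. = FALSE)
  n <- nrow(a)
  if (!exhaustive && n_perm < 100) warning("n_perm < 100: p-values will be coarse")
  d <- a - b
  thr <- qt(1 - alpha / 2, df = n - 1)
  ss <- colSums(d^2)  # invariant under sign flips
  signs <- if (exhaustive) {
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(grid)
    grid
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                           nrow = n_perm))
  }
  sums <- signs %*% d
  m <- sums / n
  s2 <- sweep(-n * m^2, 2, ss, `+`) / (n - 1)
  s2[s2 < 0] <- 0
  tmat <- ifelse(s2 <= .Machine$double.eps * 100, 0, m / sqrt(s2 / n))
  stats <- t(vapply(seq_len(nrow(tmat)),
                    function(i) max_cluster_stats(tmat[i, ], thr, dt),
                    numeric(2)))
  list(max_mass = stats[, 1], max_length = stats[, 2],
       n_perm = n_perm, seed = seed)
}

#' Monte-Carlo cluster p-values
#'
#' For each observed cluster, `p = (1 + #{null >= observed}) / (1 + n_perm)`
#' for mass (on `|mass|`) and length separately; a cluster is significant
#' when either p-value is below `alpha_cluster`.
#'
#' @param clusters a [form_clusters()] data.frame.
#' @param null a [permutation_null()] result.
#' @param span_s duration in seconds of the tested alignment span (for the
#'   relative length of significant clusters).
#' @param alpha_cluster cluster-level significance (default 0.05).
#' @return list of class `cluster_result` with `clusters` (with `p_mass`,
#'   `p_length`, `significant` columns), `sig_clusters`,
#'   `relative_length_pct`, `n_perm`, `seed`.
#' @export
cluster_pvalues <- function(clusters, null, span_s, alpha_cluster = 0.05) {
  np <- null$n_perm
  if (nrow(clusters)) {
    # tiny tolerance so null values tied with the observed statistic (e.g.
    # the identity permutation) are not lost to floating-point noise
    clusters$p_mass <- vapply(clusters$mass, function(m) {
      eps <- 1e-9 * max(1, abs(m))
      (1 + sum(null$max_mass >= abs(m) - eps)) / (1 + np)
    }, numeric(1))
    clusters$p_length <- vapply(clusters$length_s, function(l) {
      (1 + sum(null$max_length >= l - 1e-9)) / (1 + np)
    }, numeric(1))
    clusters$significant <- clusters$p_mass < alpha_cluster |
      clusters$p_length < alpha_cluster
  } else {
    clusters$p_mass <- numeric(0)
    clusters$p_length <- numeric(0)
    clusters$significant <- logical(0)
  }
  sig <- clusters[clusters$significant, , drop = FALSE]
  structure(list(clusters = clusters, sig_clusters = sig,
                 relative_length_pct = 100 * sum(sig$length_s) / span_s,
                 n_perm = np, seed = null$seed),
            class = "cluster_result")
}

#' Cluster-based permutation test on paired aligned series
#'
#' Convenience wrapper running [pointwise_paired_t()], [form_clusters()],
#' [permutation_null()] and [cluster_pvalues()] on paired event x time
#' matrices (observed vs speed-predicted activity).
#'
#' @inheritParams permutation_null
#' @param alpha cluster-forming level (default 0.05).
#' @param alpha_cluster cluster-level Monte-Carlo significance (default 0.05).
#' @return a `cluster_result` with the pointwise `t_series` attached.
#' @export
cluster_permutation_test <- function(a, b, dt, n_perm = 1000, seed,
                                     alpha = 0.05, alpha_cluster = 0.05,
                                     exhaustive = FALSE) {
  t_series <- pointwise_paired_t(a, b)
  cl <- form_clusters(t_series, nrow(a), dt, alpha)
  null <- permutation_null(a, b, dt, n_perm, seed, alpha, exhaustive)
  res <- cluster_pvalues(cl, null, span_s = ncol(a) * dt,
                         alpha_cluster = alpha_cluster)
  res$t_series <- t_series
  res
}
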