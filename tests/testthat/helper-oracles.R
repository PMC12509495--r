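# Independent oracle implementations used to cross-check the package's
# computations.  These deliberately use naive formulations (normal
# equations, brute-force scans, exhaustive enumeration) and must stay
# independent of the code paths they verify.

# polynomial least squares via explicit normal equations
oracle_polyfit <- function(t, y, degree = 2) {
  V <- sapply(0:degree, function(k) t^k)
  solve(crossprod(V), crossprod(V, y))
}

# simple linear regression via covariance formulas
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# O(n*w) brute-force truncated-window moving average
oracle_moving_average <- function(x, w) {
  n <- length(x)
  half_lo <- (w - 1) %/% 2
  half_hi <- w %/% 2
  sapply(seq_len(n), function(i) {
    mean(x[max(1, i - half_lo):min(n, i + half_hi)])
  })
}

# brute-force bout extraction: maximal runs, min duration, isolation scan
oracle_bouts <- function(flags, dt, min_dur = 2, isolation = 4) {
  n <- length(flags)
  iso_n <- round(isolation / dt)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (flags[i] == 1) {
      j <- i
      while (j < n && flags[j + 1] == 1) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  keep <- list()
  for (r in runs) {
    dur <- (r[2] - r[1] + 1) * dt
    if (dur < min_dur - 1e-9) next
    ok <- TRUE
    for (k in seq_len(n)) {
      if (flags[k] != 1) next
      if (k >= r[1] && k <= r[2]) next
      before <- r[1] - k
      after <- k - r[2]
      if ((before >= 1 && before <= iso_n) || (after >= 1 && after <= iso_n)) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep[[length(keep) + 1]] <- r
  }
  keep
}

# textbook per-column paired t
oracle_paired_t <- function(a, b) {
  sapply(seq_len(ncol(a)), function(j) {
    d <- a[, j] - b[, j]
    if (sd(d) == 0) 0 else mean(d) / (sd(d) / sqrt(length(d)))
  })
}

# linear scan run finder for supra-threshold clusters (per sign)
oracle_clusters <- function(tser, thr, dt) {
  out <- list()
  for (sgn in c(1, -1)) {
    above <- if (sgn > 0) tser > thr else tser < -thr
    i <- 1
    n <- length(tser)
    while (i <= n) {
      if (above[i]) {
        j <- i
        while (j < n && above[j + 1]) j <- j + 1
        out[[length(out) + 1]] <- data.frame(
          start_idx = i, end_idx = j, mass = sum(tser[i:j]),
          length_s = (j - i + 1) * dt, sign = sgn)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$start_idx), ]
}

# exhaustive sign-flip null of max |cluster mass| and max cluster length
oracle_signflip_null <- function(d, thr, dt) {
  n <- nrow(d)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t(apply(grid, 1, function(s) {
    ds <- s * d
    tser <- sapply(seq_len(ncol(ds)), function(j) {
      v <- ds[, j]
      if (sd(v) == 0) 0 else mean(v) / (sd(v) / sqrt(n))
    })
    cl <- oracle_clusters(tser, thr, dt)
    if (is.null(cl)) c(0, 0) else c(max(abs(cl$mass)), max(cl$length_s))
  }))
}

# cached small fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

short_session <- function(seed = 11, phase = "sample", duration = 300,
                          render = FALSE, ...) {
  cfg <- generator_config(seed = seed, phase = phase,
                          session_duration = duration, ...)
  simulate_session(cfg, render = render)
}
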