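# Independent oracles and fixture builders used across the suite.

# Brute-force motility index: midpoint integration on a fine grid instead
# of interval arithmetic.
oracle_motility_index <- function(activity, recording_length = 120,
                                  bin_width = 20, grid = 0.01) {
  tg <- seq(grid / 2, recording_length - grid / 2, by = grid)
  act <- vapply(activity, function(a) {
    if (is.null(a) || NROW(a) == 0) return(rep(FALSE, length(tg)))
    a <- as.matrix(a)
    Reduce(`|`, lapply(seq_len(nrow(a)), function(k)
      tg > a[k, 1] & tg < a[k, 2]))
  }, logical(length(tg)))
  total <- 0
  for (b in seq_len(floor(recording_length / bin_width))) {
    idx <- tg > (b - 1) * bin_width & tg < b * bin_width
    sub <- act[idx, , drop = FALSE]
    no_seg <- sum(apply(sub, 2, any))
    dr <- sum(rowSums(sub) > 0) * grid
    total <- total + min(dr, bin_width) * no_seg
  }
  total
}

random_activity <- function(n_segments = 5, recording_length = 120) {
  lapply(seq_len(n_segments), function(s) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    starts <- sort(sample(seq(0, recording_length - 5, by = 0.5), k))
    cbind(starts, pmin(starts + sample(seq(0.5, 30, by = 0.5), k,
                                       replace = TRUE), recording_length))
  })
}

# Brute-force excursion decomposition: turning points found by explicit
# running-extremum drawdown scans rather than the incremental state
# machine used by the package.
oracle_turning_points <- function(x, tol) {
  n <- length(x)
  if (n < 2) return(integer(0))
  runmin <- cummin(x); runmax <- cummax(x)
  q_up <- which(x - runmin > tol)
  q_dn <- which(runmax - x > tol)
  if (!length(q_up) && !length(q_dn)) return(integer(0))
  if (!length(q_dn) || (length(q_up) && q_up[1] <= q_dn[1])) {
    dir <- 1L; start <- which.min(x[seq_len(q_up[1])])
  } else {
    dir <- -1L; start <- which.max(x[seq_len(q_dn[1])])
  }
  pts <- start
  repeat {
    seg <- x[start:n]
    if (dir == 1L) {
      dd <- cummax(seg) - seg
      q <- which(dd > tol)
      if (!length(q)) {
        pts <- c(pts, start - 1L + which.max(seg)); break
      }
      e <- start - 1L + which.max(seg[seq_len(q[1])])
    } else {
      du <- seg - cummin(seg)
      q <- which(du > tol)
      if (!length(q)) {
        pts <- c(pts, start - 1L + which.min(seg)); break
      }
      e <- start - 1L + which.min(seg[seq_len(q[1])])
    }
    pts <- c(pts, e)
    dir <- -dir
    start <- e
  }
  pts
}

oracle_displacements <- function(tr, threshold = 0.010, tol = 0.003) {
  pts <- oracle_turning_points(tr$x, tol)
  out <- list()
  if (length(pts) >= 2) {
    for (k in seq_len(length(pts) - 1)) {
      i <- pts[k]; j <- pts[k + 1]
      dx <- tr$x[j] - tr$x[i]
      if (abs(dx) >= threshold)
        out[[length(out) + 1]] <- c(dx = dx, dt = tr$t[j] - tr$t[i])
    }
  }
  if (!length(out))
    return(data.frame(dx = numeric(0), dt = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

# A random zig-zag axial track for excursion testing.
random_track <- function(n = 200) {
  t <- seq(0, by = 0.25, length.out = n)
  x <- cumsum(stats::rnorm(n, sd = 0.004)) +
    0.02 * sin(seq(0, sample(2:8, 1) * pi, length.out = n))
  trajectory(t, x)
}

# One clean trapezoidal contraction on an otherwise constant haustrum.
trapezoid_series <- function(baseline = 10, minimum = 6, onset = 30,
                             t_c = 2, t_r = 8, length_s = 120,
                             positions = 5) {
  tm <- 0:(length_s - 1)
  x <- rep(baseline, length_s)
  depth <- baseline - minimum
  for (i in seq_along(tm)) {
    tt <- tm[i] - onset
    if (tt >= 0 && tt < t_c) x[i] <- baseline - depth * tt / t_c
    else if (tt >= t_c && tt < t_c + t_r)
      x[i] <- minimum + depth * (tt - t_c) / t_r
  }
  haustral_series(matrix(x, nrow = 1), positions, mode = "length_cm")
}
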