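# Independent oracles used across the suite. These are deliberately written
# with different algorithms than the package implementations.

# Burst detection oracle: forward while-scan over spikes (the implementation
# uses an rle() over the ISI vector).
burst_oracle <- function(t, max_isi = 0.010, min_sep = 0.100) {
  bursts <- list()
  n <- length(t)
  i <- 1L
  last_counted_end <- -Inf
  while (i <= n) {
    j <- i
    while (j + 1L <= n && t[j + 1L] - t[j] <= max_isi) j <- j + 1L
    if (j > i && t[i] - last_counted_end > min_sep) {
      bursts[[length(bursts) + 1L]] <- i:j
      last_counted_end <- t[j]
    }
    i <- j + 1L
  }
  bursts
}

# Autocorrelogram oracle: explicit all-pairs double loop (the implementation
# uses vectorized offset sweeps).
ach_oracle <- function(t, max_lag_ms) {
  L <- as.integer(max_lag_ms)
  counts <- integer(2L * L + 1L)
  for (i in seq_along(t)) for (j in seq_along(t)) {
    if (i == j) next
    lag <- round((t[j] - t[i]) * 1000)
    if (abs(lag) <= L) counts[lag + L + 1L] <- counts[lag + L + 1L] + 1L
  }
  counts
}

# Convex hull area oracle for small point sets: a point is a hull vertex iff
# it is not strictly inside any triangle of other points; vertices are then
# angularly sorted around their centroid and the polygon area taken.
hull_area_oracle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 1e-12 & s2 > 1e-12 & s3 > 1e-12) ||
      (s1 < -1e-12 & s2 < -1e-12 & s3 < -1e-12)
  }
  is_vertex <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    combs <- utils::combn(others, 3)
    for (k in seq_len(ncol(combs))) {
      tri <- combs[, k]
      if (in_triangle(pts[p, ], pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])) {
        is_vertex[p] <- FALSE
        break
      }
    }
  }
  v <- pts[is_vertex, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Random spike train with burst-like clumps for oracle comparisons.
random_clumpy_train <- function(n_max = 200) {
  n <- sample.int(n_max, 1)
  gaps <- sample(c(stats::runif(n, 0, 0.03), stats::rexp(n, 5)), n)
  t <- cumsum(gaps)
  spike_train("r", "M1", t, max(t) + 1, 250)
}

# Compact synthetic session bundle: six units over two 204.8 s epochs plus
# tremor-bearing force-plate data.
make_acceptance_session <- function(dir, seed = 42) {
  eps <- frame_schedule(c("baseline", "harmaline"), c(20, 20))
  classes <- rep(c("os-non-burst", "irr-burst", "irr-non-burst"), each = 2)
  trains <- lapply(seq_along(classes), function(i)
    gen_spike_train(spike_gen_spec(classes[i], duration = 409.6,
                                   seed = seed + i),
                    unit_id = sprintf("u%02d", i),
                    region = if (i %% 2) "M1" else "VLT"))
  fs <- gen_forceplate_session(
    tremor_gen_spec(eps, tremor_amplitude_by_epoch = c(harmaline = 1),
                    seed = seed))
  write_session(trains, fs$recording, fs$manifest, dir)
  dir
}

# Small epoch schedule tiling a whole number of frames.
frame_schedule <- function(labels, frames_each) {
  frame_s <- 10.24
  starts <- cumsum(c(0, frames_each[-length(frames_each)])) * frame_s
  mapply(function(lb, s, k) epoch(lb, s, s + k * frame_s),
         labels, starts, frames_each, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
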