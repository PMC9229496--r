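# Shared fixtures, built in code.

# Small deterministic keypoint series with optional gaps.
make_series <- function(n = 10, fps = 10, landmarks = c("LAnkle", "RAnkle"),
                        gap_at = integer(0), gap_landmark = landmarks[1]) {
  t <- (0:(n - 1)) / fps
  p <- length(landmarks)
  x <- outer(seq_len(n), seq_len(p), function(i, j) 100 + 10 * j + i)
  y <- outer(seq_len(n), seq_len(p), function(i, j) 200 + 5 * j + sin(i))
  conf <- matrix(1, n, p)
  colnames(x) <- colnames(y) <- colnames(conf) <- landmarks
  if (length(gap_at)) {
    x[gap_at, gap_landmark] <- NA
    y[gap_at, gap_landmark] <- NA
    conf[gap_at, gap_landmark] <- 0
  }
  keypoint_series(t, landmarks, x, y, conf, fps = fps, source_id = "fixture")
}

uniform_signal <- function(f, n = 200, t_end = 2, kind = "T1") {
  t <- seq(0, t_end, length.out = n)
  gait_signal(t, f(t), kind = kind)
}

# Cached simulator exemplars (built once per test run).
sim_exemplars <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- prepare_exemplars(simulate_gait(parkinsonian_gait()),
                                  simulate_gait(normal_gait()))
    cache
  }
})

# Hand-rolled extrema set for feature-algebra oracles.
manual_extrema <- function(times, values, signs = NULL,
                           minima_times = NULL, minima_values = NULL) {
  if (is.null(signs)) signs <- rep(c(1L, -1L), length.out = length(times))
  structure(list(
    maxima_times = times[signs > 0], maxima_values = values[signs > 0],
    minima_times = if (is.null(minima_times)) times[signs < 0] else minima_times,
    minima_values = if (is.null(minima_values)) values[signs < 0] else minima_values,
    merged_times = times, merged_values = values, merged_signs = signs),
    class = "extrema_set")
}

# Independent brute-force peak scanner implementing the documented rules
# (local maxima, topographic prominence, greedy height-first separation)
# with plain loops; used as the oracle for find_extrema.
brute_peaks <- function(v, t, min_prom_frac, min_sep) {
  thr <- min_prom_frac * (max(v) - min(v))
  scan <- function(w) {
    cand <- c()
    for (i in 2:(length(w) - 1))
      if (w[i] > w[i - 1] && w[i] > w[i + 1]) cand <- c(cand, i)
    keepp <- c()
    for (i in cand) {
      lmin <- w[i]; j <- i - 1
      while (j >= 1 && w[j] <= w[i]) { lmin <- min(lmin, w[j]); j <- j - 1 }
      rmin <- w[i]; j <- i + 1
      while (j <= length(w) && w[j] <= w[i]) { rmin <- min(rmin, w[j]); j <- j + 1 }
      if (w[i] - max(lmin, rmin) >= thr) keepp <- c(keepp, i)
    }
    if (length(keepp) <= 1) return(keepp)
    ord <- keepp[order(-w[keepp], t[keepp])]
    kept <- c()
    for (i in ord) if (all(abs(t[i] - t[kept]) >= min_sep)) kept <- c(kept, i)
    sort(kept)
  }
  list(maxima = scan(v), minima = scan(-v))
}
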