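#' Construct a gait signal
#'
#' A gait signal is a named 1-D time series derived from landmark tracks:
#' Type I is the signed anterior-posterior separation of the two ankles,
#' Type II the height of one foot above its lowest observed position.
#'
#' @param times Seconds, strictly increasing.
#' @param values Numeric; pixels before normalization, dimensionless after.
#' @param kind One of `"T1"`, `"T2_foot1"`, `"T2_foot2"`, `"synthetic"`.
#' @param normalized Logical flag: `TRUE` once amplitude-normalized so that
#'   `max(abs(values)) == 1`.
#' @param meta Free-text provenance.
#' @return An object of class `gait_signal`.
#' @export
gait_signal <- function(times, values, kind = "synthetic", normalized = FALSE,
                        meta = "") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stopf("times and values lengths differ")
  if (length(times) == 0L) stopf("empty signal", class = "gaitstager_empty")
  if (any(diff(times) <= 0)) stopf("signal times must be strictly increasing")
  if (any(!is.finite(values))) stopf("signal values must be finite")
  if (normalized && abs(max(abs(values)) - 1) > 1e-9)
    stopf("normalized flag set but max |value| != 1")
  structure(list(kind = kind, times = times, values = values,
                 normalized = normalized, meta = meta),
            class = "gait_signal")
}

#' @export
print.gait_signal <- function(x, ...) {
  cat(sprintf("<gait_signal %s> %d samples on [%.3g, %.3g] s%s\n",
              x$kind, length(x$times), x$times[1], x$times[length(x$times)],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$times) == length(b$times) && all(abs(a$times - b$times) <= tol)
}

#' Build the Type I signal: signed inter-ankle separation
#'
#' `values = x_left(t) - x_right(t)` along the walking (image x) axis. The
#' sign alternates across gait cycles, so consecutive extrema correspond to
#' alternating leading feet and stride length can be formed by adding the
#' magnitudes of subsequent extrema.
#'
#' @param left_ankle,right_ankle `landmark_track`s on a common time grid.
#' @return A `gait_signal` of kind `"T1"`.
#' @export
build_type1 <- function(left_ankle, right_ankle) {
  if (length(left_ankle$times) != length(right_ankle$times) ||
      any(abs(left_ankle$times - right_ankle$times) > 1e-9))
    stopf("ankle tracks are on different time grids; resample them first")
  v <- left_ankle$x - right_ankle$x
  if (stats::sd(v) < 1e-12)
    stopf("degenerate Type I signal: inter-ankle separation has zero variance",
          class = "gaitstager_degenerate")
  gait_signal(left_ankle$times, v, kind = "T1",
              meta = sprintf("x[%s] - x[%s]", left_ankle$name, right_ankle$name))
}

#' Build a Type II signal: per-foot height
#'
#' With the default image convention (y grows downward), values are flipped
#' to `max(y) - y(t)` so that ground contact is a minimum of the signal and
#' foot lift a maximum. `orientation = "height_up"` takes `y` as already
#' being a height.
#'
#' @param foot A `landmark_track` (heel or ankle of one foot).
#' @param orientation `"image_y_down"` (default) or `"height_up"`.
#' @param kind Signal kind tag, `"T2_foot1"` or `"T2_foot2"`.
#' @return A `gait_signal`.
#' @export
build_type2 <- function(foot, orientation = c("image_y_down", "height_up"),
                        kind = "T2_foot1") {
  orientation <- match.arg(orientation)
  if (length(foot$times) == 0L) stopf("empty track", class = "gaitstager_empty")
  v <- if (orientation == "image_y_down") max(foot$y) - foot$y else foot$y
  gait_signal(foot$times, v, kind = kind,
              meta = sprintf("height of %s (%s)", foot$name, orientation))
}

#' Normalize a signal by its maximum absolute amplitude
#'
#' Divides by `max(abs(values))` so the signed Type I signal maps into
#' \[-1, 1\] and Type II into \[0, 1\]. Idempotent.
#'
#' @param signal A `gait_signal` with nonzero amplitude.
#' @return The normalized `gait_signal`.
#' @export
normalize_amplitude <- function(signal) {
  stopifnot(inherits(signal, "gait_signal"))
  m <- max(abs(signal$values))
  if (m == 0) stopf("cannot normalize an all-zero signal",
                    class = "gaitstager_degenerate")
  out <- signal
  out$values <- signal$values / m
  out$normalized <- TRUE
  out
}

#' Linearly resample a signal onto a uniform grid
#'
#' @param signal A `gait_signal`.
#' @param t_start,t_end Window bounds in seconds; must lie inside the
#'   signal's support (no extrapolation, ever).
#' @param n_points Number of uniform grid points (>= 4).
#' @return A `gait_signal` on the uniform grid.
#' @export
resample_to_grid <- function(signal, t_start, t_end, n_points = 1000L) {
  stopifnot(inherits(signal, "gait_signal"))
  if (n_points < 4L) stopf("n_points must be >= 4")
  supp <- range(signal$times)
  if (t_start < supp[1] - 1e-12 || t_end > supp[2] + 1e-12 || t_start >= t_end)
    stopf("requested window [%g, %g] outside signal support [%g, %g]",
          t_start, t_end, supp[1], supp[2], class = "gaitstager_support")
  grid <- seq(t_start, t_end, length.out = n_points)
  v <- stats::approx(signal$times, signal$values, xout = grid, method = "linear",
                     rule = 1)$y
  out <- signal
  out$times <- grid; out$values <- v
  out$normalized <- FALSE
  out
}

#' Common support window of two signals
#'
#' @param a,b `gait_signal`s.
#' @return `c(t_start, t_end)`: the intersection of the two supports.
#' @export
overlap_window <- function(a, b) {
  t0 <- max(a$times[1], b$times[1])
  t1 <- min(a$times[length(a$times)], b$times[length(b$times)])
  if (t0 >= t1) stopf("signals have no overlapping support",
                      class = "gaitstager_support")
  c(t0, t1)
}

#' Low-pass denoise a signal by Fourier truncation
#'
#' Zeroes all DFT coefficients whose frequency exceeds `keep_fraction` of
#' the Nyquist band (symmetrically, so the output is real) and inverse
#' transforms. The DC component is always kept, so the mean is preserved
#' exactly; `keep_fraction = 1` is the identity up to numerical noise.
#'
#' @param signal A `gait_signal` on a uniform grid.
#' @param keep_fraction Fraction of the Nyquist band to keep, in (0, 1\].
#' @return The denoised `gait_signal`.
#' @export
fft_denoise <- function(signal, keep_fraction = 0.1) {
  stopifnot(inherits(signal, "gait_signal"))
  if (keep_fraction <= 0 || keep_fraction > 1) stopf("keep_fraction must be in (0, 1]")
  if (!is_uniform_grid(signal$times))
    stopf("fft_denoise requires a uniform time grid; resample first")
  v <- signal$values
  n <- length(v)
  co <- stats::fft(v)
  k <- 0:(n - 1)
  m <- pmin(k, n - k)                 # symmetric frequency index
  co[m > keep_fraction * (n / 2)] <- 0+0i
  out <- signal
  out$values <- Re(stats::fft(co, inverse = TRUE)) / n
  out$normalized <- FALSE
  out
}

#' Detect gait-cycle extrema of a signal
#'
#' Finds local maxima and minima whose prominence is at least
#' `min_prominence` times the signal's peak-to-peak range and which are at
#' least `min_separation` seconds apart (per extremum type, higher peaks
#' retained first). The merged, time-ordered list is then cleaned so maxima
#' and minima strictly alternate: of two adjacent same-sign extrema the more
#' extreme one is kept.
#'
#' @param signal A `gait_signal` on a uniform grid with >= 8 samples.
#' @param min_prominence Prominence threshold as a fraction of the signal
#'   range (default 0.1).
#' @param min_separation Minimum spacing between retained extrema of the
#'   same type, in seconds (default 0.25).
#' @return An object of class `extrema_set` with fields `maxima_times`,
#'   `maxima_values`, `minima_times`, `minima_values`, `merged_times`,
#'   `merged_values`, `merged_signs` (+1 maximum, -1 minimum).
#' @export
find_extrema <- function(signal, min_prominence = 0.1, min_separation = 0.25) {
  stopifnot(inherits(signal, "gait_signal"))
  if (length(signal$values) < 8L) stopf("need >= 8 samples for extremum detection")
  if (!is_uniform_grid(signal$times))
    stopf("find_extrema requires a uniform time grid; resample first")
  v <- signal$values; t <- signal$times
  rng <- max(v) - min(v)
  thr <- min_prominence * rng

  pk_max <- select_peaks(v, t, thr, min_separation)
  pk_min <- select_peaks(-v, t, thr, min_separation)

  times <- c(t[pk_max], t[pk_min])
  vals <- c(v[pk_max], v[pk_min])
  signs <- c(rep(1L, length(pk_max)), rep(-1L, length(pk_min)))
  if (length(times) < 2L)
    stopf("insufficient cycles: found %d extrema (need >= 2)", length(times),
          class = "gaitstager_cycles")
  o <- order(times)
  times <- times[o]; vals <- vals[o]; signs <- signs[o]

  # alternation cleanup: of adjacent same-sign extrema keep the more extreme
  repeat {
    dup <- which(diff(signs) == 0L)
    if (length(dup) == 0L) break
    i <- dup[1]
    drop <- if (signs[i] > 0L) {
      if (vals[i] >= vals[i + 1]) i + 1L else i
    } else {
      if (vals[i] <= vals[i + 1]) i + 1L else i
    }
    times <- times[-drop]; vals <- vals[-drop]; signs <- signs[-drop]
  }
  if (length(times) < 2L)
    stopf("insufficient cycles after alternation cleanup",
          class = "gaitstager_cycles")

  structure(list(
    maxima_times = t[pk_max], maxima_values = v[pk_max],
    minima_times = t[pk_min], minima_values = v[pk_min],
    merged_times = times, merged_values = vals, merged_signs = signs),
    class = "extrema_set")
}

# Local maxima of v (strictly above both neighbours), filtered by absolute
# prominence `thr` and minimum time separation `min_sep`; retained greedily
# in order of decreasing height (ties: earlier first). Returns indices.
select_peaks <- function(v, t, thr, min_sep) {
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= thr]
  if (length(cand) <= 1L) return(cand)
  ord <- cand[order(-v[cand], t[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(t[i] - t[kept]) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Topographic prominence of a local maximum: on each side, scan to the
# nearest strictly higher sample (or the signal edge) and take the minimum
# over that stretch; prominence = peak - the higher of the two side minima.
peak_prominence <- function(v, i) {
  n <- length(v)
  left <- i; lmin <- v[i]
  j <- i - 1L
  while (j >= 1L && v[j] <= v[i]) { lmin <- min(lmin, v[j]); j <- j - 1L }
  rmin <- v[i]
  j <- i + 1L
  while (j <= n && v[j] <= v[i]) { rmin <- min(rmin, v[j]); j <- j + 1L }
  v[i] - max(lmin, rmin)
}
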