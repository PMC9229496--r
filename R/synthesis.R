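#' Severity stage levels
#'
#' @return `c("I", "II", "III", "IV")`.
#' @export
stage_levels <- function() c("I", "II", "III", "IV")

#' Clinical meaning of each stage level
#'
#' @return Named character vector mapping level to meaning
#'   (healthy/mild/moderate/severe).
#' @export
stage_meanings <- function() {
  c(I = "healthy", II = "mild", III = "moderate", IV = "severe")
}

#' Evenly spaced mixing-weight grid
#'
#' `n_combinations` values of the mixing weight omega, evenly spaced over
#' \[0, 1\] inclusive of both endpoints (omega = 0 is the normal exemplar,
#' omega = 1 the Parkinsonian one).
#'
#' @param n_combinations Integer >= 2.
#' @return Numeric vector of omegas.
#' @export
omega_grid <- function(n_combinations) {
  if (n_combinations < 2L) stopf("n_combinations must be >= 2")
  seq(0, 1, length.out = n_combinations)
}

#' Map a mixing weight to a severity stage
#'
#' Hoehn & Yahr-derived four-level binning of the mixing weight:
#' stage I for 0 <= omega < 0.25, II for 0.25 <= omega < 0.50,
#' III for 0.50 <= omega < 0.75 and IV for 0.75 <= omega <= 1.
#'
#' @param omega Numeric vector of mixing weights in \[0, 1\].
#' @return Factor with levels [stage_levels()].
#' @export
stage_label <- function(omega) {
  if (any(omega < 0 | omega > 1)) stopf("omega must lie in [0, 1]")
  lv <- ifelse(omega < 0.25, "I",
        ifelse(omega < 0.50, "II",
        ifelse(omega < 0.75, "III", "IV")))
  factor(lv, levels = stage_levels())
}

#' Linear combination of a Parkinsonian and a normal gait signal
#'
#' Pointwise `lC(t) = omega * lP(t) + (1 - omega) * lN(t)` on the shared
#' uniform grid. Both inputs must be amplitude-normalized; the endpoints
#' reproduce the exemplars exactly.
#'
#' @param sig_p Parkinsonian exemplar `gait_signal` (normalized).
#' @param sig_n Normal exemplar `gait_signal` (normalized, same grid).
#' @param omega Mixing weight in \[0, 1\].
#' @return The combined `gait_signal` (kind `"synthetic"`).
#' @export
linear_combine <- function(sig_p, sig_n, omega) {
  stopifnot(inherits(sig_p, "gait_signal"), inherits(sig_n, "gait_signal"))
  if (length(omega) != 1L || omega < 0 || omega > 1)
    stopf("omega must be a single value in [0, 1]")
  if (!same_grid(sig_p, sig_n))
    stopf("exemplar signals are on different grids; resample onto the overlap window first")
  if (!sig_p$normalized || !sig_n$normalized)
    stopf("exemplar signals must be amplitude-normalized before combining")
  v <- omega * sig_p$values + (1 - omega) * sig_n$values
  gait_signal(sig_p$times, v, kind = "synthetic",
              normalized = (omega == 0 && sig_n$normalized) ||
                           (omega == 1 && sig_p$normalized),
              meta = sprintf("omega=%g mix of [%s] and [%s]", omega,
                             sig_p$meta, sig_n$meta))
}

#' Build a severity-graded synthetic feature dataset
#'
#' For every omega on the even grid, combines the three exemplar signals
#' (Type I and both Type II) with that weight, extracts the per-cycle
#' feature table from the combined curves, and labels every row with the
#' omega and its severity stage.
#'
#' @param gait_p,gait_n Lists with elements `t1`, `t2_foot1`, `t2_foot2`:
#'   the exemplar `gait_signal`s, normalized on a common grid (see
#'   [prepare_exemplars()]).
#' @param n_combinations Number of omega values (>= 2).
#' @param peak_cfg Extremum-detection settings, as in
#'   [extract_feature_table()].
#' @return A labeled feature `data.frame` (columns of
#'   [gait_feature_names()], `cycle_index`, `omega`, `stage`).
#' @export
build_synthetic_dataset <- function(gait_p, gait_n, n_combinations,
                                    peak_cfg = list()) {
  omegas <- omega_grid(n_combinations)
  parts <- lapply(omegas, function(w) {
    tab <- tryCatch(
      extract_feature_table(
        linear_combine(gait_p$t1, gait_n$t1, w),
        linear_combine(gait_p$t2_foot1, gait_n$t2_foot1, w),
        linear_combine(gait_p$t2_foot2, gait_n$t2_foot2, w),
        peak_cfg),
      error = function(e) stopf("feature extraction failed at omega = %g: %s",
                                w, conditionMessage(e),
                                class = "gaitstager_cycles"))
    tab$omega <- w
    tab
  })
  out <- do.call(rbind, parts)
  out$stage <- stage_label(out$omega)
  rownames(out) <- NULL
  out
}

#' Gait simulator parameters
#'
#' Parametric model of a side-view walking recording, used to generate
#' reproducible exemplar keypoint series. Each foot advances as a sinusoid
#' of the stride frequency around the hip midline and lifts off the ground
#' as a rectified sinusoid; the second foot repeats the first with a phase
#' delay. Gaussian pixel jitter emulates pose-estimator noise and an
#' optional tremor sinusoid perturbs the horizontal coordinates.
#'
#' @param cadence_hz Stride frequency per foot in Hz (gait cycles per
#'   second; two steps per cycle).
#' @param step_amplitude_px Peak inter-ankle separation in pixels (the
#'   step length in image units).
#' @param foot_clearance_px Peak foot lift in pixels.
#' @param phase_offset_rad Phase delay of foot 2 behind foot 1, in radians
#'   of the stride cycle; `pi` is perfect antiphase.
#' @param jitter_sd_px Standard deviation of i.i.d. Gaussian pixel noise
#'   on every coordinate.
#' @param tremor_amplitude_px Amplitude of the tremor sinusoid added to
#'   x-coordinates (0 disables it).
#' @param tremor_hz Tremor frequency in Hz.
#' @param duration_s Recording length in seconds.
#' @param fps Frames per second.
#' @param seed RNG seed for the jitter.
#' @return A list of class `gait_sim_params`.
#' @export
gait_sim_params <- function(cadence_hz = 0.9, step_amplitude_px = 90,
                            foot_clearance_px = 25, phase_offset_rad = pi,
                            jitter_sd_px = 1.5, tremor_amplitude_px = 0,
                            tremor_hz = 5, duration_s = 12, fps = 30,
                            seed = 22) {
  p <- list(cadence_hz = cadence_hz, step_amplitude_px = step_amplitude_px,
            foot_clearance_px = foot_clearance_px,
            phase_offset_rad = phase_offset_rad, jitter_sd_px = jitter_sd_px,
            tremor_amplitude_px = tremor_amplitude_px, tremor_hz = tremor_hz,
            duration_s = duration_s, fps = fps, seed = seed)
  pos <- c("cadence_hz", "step_amplitude_px", "foot_clearance_px",
           "tremor_hz", "duration_s", "fps")
  for (nm in pos) if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
    stopf("invalid simulator parameter: %s must be > 0", nm)
  if (p$jitter_sd_px < 0 || p$tremor_amplitude_px < 0)
    stopf("invalid simulator parameter: noise amplitudes must be >= 0")
  if (round(p$duration_s * p$fps) < 64)
    stopf("fps x duration must give >= 64 frames")
  structure(p, class = "gait_sim_params")
}

#' Normal-gait simulator preset
#'
#' Longer steps, higher foot clearance, slower cadence, no tremor.
#'
#' @param ... Overrides passed to [gait_sim_params()].
#' @return A `gait_sim_params` object.
#' @export
normal_gait <- function(...) {
  do.call(gait_sim_params, utils::modifyList(
    list(cadence_hz = 0.9, step_amplitude_px = 90, foot_clearance_px = 25,
         jitter_sd_px = 1.5, tremor_amplitude_px = 0, seed = 22),
    list(...)))
}

#' Parkinsonian-gait simulator preset
#'
#' Shortened shuffling steps (< 0.5x the normal amplitude), reduced foot
#' clearance, faster cadence (> 1.3x) and a tremor component.
#'
#' @param ... Overrides passed to [gait_sim_params()].
#' @return A `gait_sim_params` object.
#' @export
parkinsonian_gait <- function(...) {
  do.call(gait_sim_params, utils::modifyList(
    list(cadence_hz = 1.2, step_amplitude_px = 40, foot_clearance_px = 10,
         jitter_sd_px = 2.5, tremor_amplitude_px = 3, tremor_hz = 5,
         seed = 23),
    list(...)))
}

#' Simulate a side-view walking keypoint series
#'
#' Generates hip, ankle and heel trajectories in image convention
#' (y grows downward) according to the parametric gait model of
#' [gait_sim_params()]. Deterministic given the seed.
#'
#' @param params A `gait_sim_params` object.
#' @return A [keypoint_series()] with landmarks LHip, RHip, LAnkle, RAnkle,
#'   LHeel, RHeel.
#' @export
simulate_gait <- function(params) {
  if (!inherits(params, "gait_sim_params")) params <- do.call(gait_sim_params, params)
  n <- round(params$duration_s * params$fps)
  t <- (0:(n - 1)) / params$fps
  f <- params$cadence_hz
  A <- params$step_amplitude_px
  h <- params$foot_clearance_px
  delay <- params$phase_offset_rad / (2 * pi * f)   # foot-2 time delay, s

  mid_x <- 320; ground_y <- 400; hip_y <- 200

  # foot 1 = left; foot 2 = right, the same pattern delayed
  x_l <- mid_x + (A / 2) * sin(2 * pi * f * t)
  x_r <- mid_x + (A / 2) * sin(2 * pi * f * (t - delay))
  clr_l <- h * abs(sin(pi * f * t))                 # contact once per stride
  clr_r <- h * abs(sin(pi * f * (t - delay)))

  tremor <- params$tremor_amplitude_px * sin(2 * pi * params$tremor_hz * t)

  with_seed(params$seed, {
    jit <- function() stats::rnorm(n, sd = params$jitter_sd_px)
    xm <- cbind(
      LHip = mid_x - 8 + jit(), RHip = mid_x + 8 + jit(),
      LAnkle = x_l + tremor + jit(), RAnkle = x_r + tremor + jit(),
      LHeel = x_l - 8 + tremor + jit(), RHeel = x_r - 8 + tremor + jit())
    ym <- cbind(
      LHip = hip_y + jit(), RHip = hip_y + jit(),
      LAnkle = ground_y - 6 - clr_l + jit(), RAnkle = ground_y - 6 - clr_r + jit(),
      LHeel = ground_y - clr_l + jit(), RHeel = ground_y - clr_r + jit())
    keypoint_series(frame_times = t, landmarks = colnames(xm), x = xm, y = ym,
                    confidence = matrix(1, n, ncol(xm)), fps = params$fps,
                    source_id = sprintf("simulated gait (cadence %.3g Hz, step %.3g px, seed %s)",
                                        f, A, format(params$seed)))
  })
}

#' Build normalized exemplar signals from two keypoint recordings
#'
#' The full signal-preparation pipeline applied to a Parkinsonian and a
#' normal recording: extract ankle and heel tracks, build the Type I and
#' per-foot Type II signals, restrict all six to the common overlap window,
#' resample onto one uniform grid, low-pass denoise by Fourier truncation,
#' and amplitude-normalize. The result feeds [build_synthetic_dataset()].
#'
#' @param series_p,series_n `keypoint_series` for the Parkinsonian and
#'   normal gaits.
#' @param cfg List of settings: `resample_points` (default 1000),
#'   `fft_keep_fraction` (default 0.1), `t2_landmarks` (default
#'   `c("LHeel", "RHeel")`), `gap_policy` (default "interpolate").
#' @return List with elements `p` and `n`, each a list of normalized
#'   `t1`, `t2_foot1`, `t2_foot2` signals on a shared uniform grid.
#' @export
prepare_exemplars <- function(series_p, series_n, cfg = list()) {
  n_points <- cfg$resample_points %||% 1000L
  keep <- cfg$fft_keep_fraction %||% 0.1
  t2_lm <- cfg$t2_landmarks %||% c("LHeel", "RHeel")
  gap_policy <- cfg$gap_policy %||% "interpolate"

  raw <- lapply(list(p = series_p, n = series_n), function(s) {
    tr <- select_landmarks(s, c("LAnkle", "RAnkle", t2_lm), gap_policy = gap_policy)
    # interpolation may trim different leading/trailing gaps per landmark;
    # cut all tracks of one recording back to their common frame window
    t0 <- max(vapply(tr, function(x) x$times[1], numeric(1)))
    t1 <- min(vapply(tr, function(x) x$times[length(x$times)], numeric(1)))
    tr <- lapply(tr, function(x) {
      keep <- x$times >= t0 - 1e-12 & x$times <= t1 + 1e-12
      x$times <- x$times[keep]; x$x <- x$x[keep]; x$y <- x$y[keep]
      x
    })
    list(t1 = build_type1(tr$LAnkle, tr$RAnkle),
         t2_foot1 = build_type2(tr[[t2_lm[1]]], kind = "T2_foot1"),
         t2_foot2 = build_type2(tr[[t2_lm[2]]], kind = "T2_foot2"))
  })

  sigs <- c(raw$p, raw$n)
  win <- Reduce(function(w, s) c(max(w[1], s$times[1]),
                                 min(w[2], s$times[length(s$times)])),
                sigs, c(-Inf, Inf))
  if (win[1] >= win[2]) stopf("exemplar recordings have no overlapping support",
                              class = "gaitstager_support")
  lapply(raw, function(g) {
    lapply(g, function(s) {
      normalize_amplitude(fft_denoise(
        resample_to_grid(s, win[1], win[2], n_points), keep))
    })
  })
}
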