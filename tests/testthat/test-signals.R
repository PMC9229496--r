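track <- function(t, x, y = rep(0, length(t)), name = "LAnkle") {
  structure(list(name = name, times = t, x = x, y = y),
            class = "landmark_track")
}

test_that("Type I is the signed ankle separation", {
  t <- seq(0, 2, length.out = 101)
  l <- track(t, sin(2 * pi * t))
  r <- track(t, -sin(2 * pi * t), name = "RAnkle")
  s <- build_type1(l, r)
  expect_equal(s$values, 2 * sin(2 * pi * t))
  expect_error(build_type1(l, l), class = "gaitstager_degenerate")
  r2 <- track(t + 0.01, -sin(2 * pi * t), name = "RAnkle")
  expect_error(build_type1(l, r2), "resample")
})

test_that("simulator step amplitude sets Type I peak-to-peak", {
  sim <- simulate_gait(normal_gait(jitter_sd_px = 0, step_amplitude_px = 80))
  tr <- select_landmarks(sim, c("LAnkle", "RAnkle"), "drop")
  s <- build_type1(tr$LAnkle, tr$RAnkle)
  expect_equal(max(s$values) - min(s$values), 160, tolerance = 0.01)
})

test_that("Type II flips image-y so ground contact is a minimum", {
  t <- seq(0, 3, length.out = 301)
  y_img <- 400 - 20 * abs(sin(pi * t))     # contacts at integer t
  s <- build_type2(track(t, rep(0, 301), y = y_img))
  expect_equal(min(s$values), 0)
  mins <- s$times[s$values < 1e-9]
  expect_true(all(vapply(mins, function(m) min(abs(m - 0:3)) < 0.02, logical(1))))
  # constant y: foot never lifts -> all-zero signal
  s0 <- build_type2(track(t, rep(0, 301), y = rep(7, 301)))
  expect_equal(s0$values, rep(0, 301))
  # PD preset clears the ground less than the normal preset
  clr <- function(p) {
    tr <- select_landmarks(simulate_gait(p), "LHeel", "drop")$LHeel
    max(build_type2(tr)$values)
  }
  expect_lt(clr(parkinsonian_gait(jitter_sd_px = 0, tremor_amplitude_px = 0)),
            clr(normal_gait(jitter_sd_px = 0)))
})

test_that("amplitude normalization divides by max |value| and is idempotent", {
  s <- gait_signal(0:2, c(2, -4, 1))
  n1 <- normalize_amplitude(s)
  expect_equal(n1$values, c(0.5, -1, 0.25))
  expect_true(n1$normalized)
  expect_equal(normalize_amplitude(n1)$values, n1$values)
  set.seed(1)
  r <- gait_signal(1:50, rnorm(50))
  expect_identical(normalize_amplitude(normalize_amplitude(r)),
                   normalize_amplitude(r))
  expect_error(normalize_amplitude(gait_signal(0:4, rep(0, 5))),
               class = "gaitstager_degenerate")
})

test_that("resampling is exact on affine signals and accurate on smooth ones", {
  ramp <- gait_signal(seq(0, 1, by = 0.25), seq(0, 1, by = 0.25))
  rs <- resample_to_grid(ramp, 0, 1, 11)
  expect_equal(rs$values, seq(0, 1, by = 0.1))
  # resampling onto the signal's own grid is the identity
  s <- gait_signal(seq(0, 1, length.out = 11), sin(seq(0, 1, length.out = 11)))
  expect_equal(resample_to_grid(s, 0, 1, 11)$values, s$values)
  # closed-form oracle: dense sine
  t <- seq(0, 1, by = 0.01)
  sine <- gait_signal(t, sin(2 * pi * t))
  r2 <- resample_to_grid(sine, 0, 1, 1000)
  expect_lt(max(abs(r2$values - sin(2 * pi * r2$times))), 1e-3)
  expect_error(resample_to_grid(sine, -0.5, 1, 100), class = "gaitstager_support")
})

test_that("overlap window is the support intersection", {
  a <- gait_signal(seq(0, 10, 0.5), rnorm(21))
  b <- gait_signal(seq(3, 12, 0.5), rnorm(19))
  expect_equal(overlap_window(a, b), c(3, 10))
  expect_equal(overlap_window(a, a), c(0, 10))
  d <- gait_signal(seq(11, 12, 0.5), rnorm(3))
  expect_error(overlap_window(a, d), class = "gaitstager_support")
})

test_that("FFT denoising is identity at full band, preserves the mean, removes high frequencies", {
  t <- seq(0, 1, length.out = 256)[-256]
  s <- gait_signal(t, 3 + sin(2 * pi * 4 * t))
  expect_lt(max(abs(fft_denoise(s, 1)$values - s$values)), 1e-10)
  # pure sine below the cutoff is untouched
  expect_lt(max(abs(fft_denoise(s, 0.1)$values - s$values)), 1e-8)
  # sine + spike above the cutoff: residual equals the sine
  spike <- sin(2 * pi * 60 * t)
  s2 <- gait_signal(t, s$values + spike)
  expect_lt(max(abs(fft_denoise(s2, 0.2)$values - s$values)), 1e-6)
  for (kf in c(0.05, 0.3, 0.77))
    expect_equal(mean(fft_denoise(s2, kf)$values), mean(s2$values))
  irregular <- gait_signal(c(0, 0.1, 0.3, 0.35, 0.5, 0.7, 0.9, 1.0), rnorm(8))
  expect_error(fft_denoise(irregular, 0.5), "uniform")
})

test_that("extrema of a sine land on the analytic extrema and alternate", {
  s <- uniform_signal(function(t) sin(2 * pi * t), n = 301, t_end = 3)
  es <- find_extrema(s)
  dt <- diff(s$times)[1]
  expect_equal(length(es$maxima_times), 3)
  expect_equal(length(es$minima_times), 3)
  expect_true(all(abs(es$maxima_times - c(0.25, 1.25, 2.25)) <= dt + 1e-12))
  expect_true(all(abs(es$minima_times - c(0.75, 1.75, 2.75)) <= dt + 1e-12))
  expect_true(all(abs(diff(es$merged_signs)) == 2))
  # a tiny ripple below the prominence threshold is ignored
  s2 <- uniform_signal(function(t) sin(2 * pi * t) + 0.01 * sin(2 * pi * 17 * t),
                       n = 600, t_end = 3)
  es2 <- find_extrema(s2, min_prominence = 0.1)
  expect_equal(length(es2$maxima_times), 3)
  expect_error(find_extrema(uniform_signal(function(t) t, n = 50)),
               class = "gaitstager_cycles")
})

test_that("find_extrema matches the brute-force scan on random walks", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(100:500, 1)
    t <- seq(0, 5, length.out = n)
    v <- cumsum(rnorm(n))
    s <- gait_signal(t, v)
    es <- find_extrema(s, min_prominence = 0.05, min_separation = 0.2)
    bf <- brute_peaks(v, t, 0.05, 0.2)
    expect_equal(es$maxima_times, t[bf$maxima])
    expect_equal(es$minima_times, t[bf$minima])
  }
})
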