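test_that("step and stride times/lengths follow the extremum formulas", {
  es <- manual_extrema(times = c(0.5, 1.0, 1.5, 2.0),
                       values = c(0.9, -0.8, 0.85, -0.75))
  expect_equal(step_times(es), c(0.5, 0.5, 0.5))
  expect_equal(stride_times(es), c(1.0, 1.0))
  expect_equal(step_lengths(es), c(0.9, 0.8, 0.85, 0.75))
  expect_equal(stride_lengths(es), c(1.7, 1.65, 1.6))

  es2 <- manual_extrema(times = c(0.4, 1.1, 1.5), values = c(1, -1, 1))
  expect_equal(step_times(es2), c(0.7, 0.4))
  expect_error(stride_times(manual_extrema(c(0, 1), c(1, -1))),
               class = "gaitstager_cycles")
})

test_that("Table-style formulas match a brute-force recomputation on hand-listed extrema", {
  set.seed(7)
  tt <- cumsum(runif(9, 0.3, 0.8))
  vv <- rep(c(1, -1), length.out = 9) * runif(9, 0.5, 1)
  es <- manual_extrema(tt, vv)
  # independent loops over the definition
  st <- sapply(1:8, function(i) tt[i + 1] - tt[i])
  sdt <- sapply(1:7, function(i) tt[i + 2] - tt[i])
  sl <- sapply(1:8, function(i) abs(vv[i]) + abs(vv[i + 1]))
  expect_equal(step_times(es), st)
  expect_equal(stride_times(es), sdt)
  expect_equal(stride_lengths(es), sl)
  expect_equal(step_lengths(es), abs(vv))
  # additivity identities
  expect_equal(stride_times(es), step_times(es)[-8] + step_times(es)[-1])
  expect_equal(stride_lengths(es), step_lengths(es)[-9] + step_lengths(es)[-1])
})

test_that("swing times difference successive contact minima of one foot", {
  es <- manual_extrema(c(0.7, 1.7, 2.7), c(1, 1, 1), signs = c(1L, 1L, 1L),
                       minima_times = c(0.2, 1.2, 2.2),
                       minima_values = c(0, 0, 0))
  expect_equal(swing_times(es), c(1, 1))
  es1 <- manual_extrema(c(0.7), c(1), signs = 1L,
                        minima_times = 0.2, minima_values = 0)
  expect_error(swing_times(es1), class = "gaitstager_cycles")
})

test_that("double support pairs the two feet's minima index-wise after trimming", {
  f1 <- manual_extrema(c(0.5, 1.5), c(0, 0), signs = c(-1L, -1L),
                       minima_times = c(0.5, 1.5), minima_values = c(0, 0))
  f2 <- manual_extrema(c(0.0, 1.0), c(0, 0), signs = c(-1L, -1L),
                       minima_times = c(0.0, 1.0), minima_values = c(0, 0))
  expect_equal(double_support_times(f1, f2), c(0.5, 0.5))
  expect_equal(double_support_times(f1, f1), c(0, 0))
  # leading unpaired minimum is trimmed before pairing
  f3 <- manual_extrema(c(-0.9, 0.6, 1.6), c(0, 0, 0), signs = rep(-1L, 3),
                       minima_times = c(-0.9, 0.6, 1.6), minima_values = c(0, 0, 0))
  expect_equal(double_support_times(f3, f2), c(0.6, 0.6))
})

test_that("simulator phase offset and cadence set swing and double-support times", {
  f <- 1; phi <- pi / 2
  sim <- simulate_gait(normal_gait(cadence_hz = f, phase_offset_rad = phi,
                                   jitter_sd_px = 0, fps = 40, duration_s = 10))
  tr <- select_landmarks(sim, c("LHeel", "RHeel"), "drop")
  e1 <- find_extrema(build_type2(tr$LHeel), min_separation = 0.3)
  e2 <- find_extrema(build_type2(tr$RHeel), min_separation = 0.3)
  expect_equal(mean(swing_times(e1)), 1 / f, tolerance = 0.05)
  expect_equal(mean(double_support_times(e1, e2)), phi / (2 * pi * f),
               tolerance = 0.11)
})

test_that("feature extraction aligns streams per cycle and is deterministic", {
  f <- 1
  sim <- simulate_gait(normal_gait(cadence_hz = f, duration_s = 10.5, fps = 40))
  cfg <- run_config()
  sigs <- gait_signals(sim, cfg)
  tab <- extract_feature_table(sigs$t1, sigs$t2_foot1, sigs$t2_foot2)
  # 10 full cycles observed, minus edge-cycle losses
  expect_gte(nrow(tab), 8)
  expect_true(all(tab$step_time > 0 & tab$stride_time > 0))
  expect_true(all(tab$stride_time > tab$step_time))
  expect_true(all(tab$step_length > 0 & tab$step_length <= 1))
  expect_equal(mean(tab$stride_time), 1 / f, tolerance = 0.05)
  tab2 <- extract_feature_table(sigs$t1, sigs$t2_foot1, sigs$t2_foot2)
  expect_identical(tab, tab2)
  # a single-cycle recording cannot produce features: one contact minimum
  # per foot leaves the swing stream empty
  t <- seq(0, 2, length.out = 400)
  t1s <- gait_signal(t, sin(2 * pi * 0.6 * t), kind = "T1")
  t2one <- gait_signal(t, abs(sin(pi * t / 2)), kind = "T2_foot1")
  expect_error(extract_feature_table(t1s, t2one, t2one),
               class = "gaitstager_cycles")
})

test_that("stride equals the sum of consecutive steps on extracted tables", {
  ex <- sim_exemplars()
  tab <- extract_feature_table(ex$n$t1, ex$n$t2_foot1, ex$n$t2_foot2)
  n <- nrow(tab)
  expect_equal(tab$stride_time[-n], tab$step_time[-n] + tab$step_time[-1])
  expect_equal(tab$stride_length[-n], tab$step_length[-n] + tab$step_length[-1])
})

test_that("PD preset yields shorter steps than the normal preset", {
  ex <- sim_exemplars()
  tp <- extract_feature_table(ex$p$t1, ex$p$t2_foot1, ex$p$t2_foot2)
  tn <- extract_feature_table(ex$n$t1, ex$n$t2_foot1, ex$n$t2_foot2)
  expect_lt(mean(tp$step_length), mean(tn$step_length))
})

test_that("feature CSV round-trips with stage labels", {
  ex <- sim_exemplars()
  tab <- build_synthetic_dataset(ex$p, ex$n, 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  tab2 <- read_feature_csv(path)
  expect_equal(tab2$step_length, tab$step_length)
  expect_equal(as.character(tab2$stage), as.character(tab$stage))
  writeLines("a,b", path)
  expect_error(read_feature_csv(path), class = "gaitstager_schema")
})
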