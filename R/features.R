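#' Canonical feature column order
#'
#' The seven-dimensional gait feature vector: step length, step time,
#' stride time, stride length, swing time of each foot, and double support.
#' Swing time is split per foot, so the six classical features yield seven
#' columns.
#'
#' @return Character vector of column names, in fixed order.
#' @export
gait_feature_names <- function() {
  c("step_length", "step_time", "stride_time", "stride_length",
    "swing_time_foot1", "swing_time_foot2", "double_support")
}

check_extrema <- function(es, n_min, what) {
  if (!inherits(es, "extrema_set")) stopf("expected an extrema_set")
  if (length(es$merged_times) < n_min)
    stopf("insufficient extrema for %s: have %d, need >= %d",
          what, length(es$merged_times), n_min, class = "gaitstager_cycles")
}

#' Step times from Type I extrema
#'
#' Time between consecutive heel strikes: differences of consecutive
#' merged-extremum times of the inter-ankle separation signal.
#'
#' @param t1_extrema `extrema_set` of the Type I signal.
#' @return Numeric vector of step times in seconds.
#' @export
step_times <- function(t1_extrema) {
  check_extrema(t1_extrema, 2L, "step times")
  diff(t1_extrema$merged_times)
}

#' Stride times from Type I extrema
#'
#' Time between every other extremum (`t[i+2] - t[i]`): one full gait cycle
#' of the same foot.
#'
#' @inheritParams step_times
#' @return Numeric vector of stride times in seconds.
#' @export
stride_times <- function(t1_extrema) {
  check_extrema(t1_extrema, 3L, "stride times")
  tt <- t1_extrema$merged_times
  tt[-(1:2)] - tt[1:(length(tt) - 2L)]
}

#' Step lengths from Type I extrema
#'
#' The magnitude of each inter-ankle separation extremum: the (normalized)
#' foot-to-foot distance at heel strike.
#'
#' @inheritParams step_times
#' @return Numeric vector of step lengths in normalized amplitude units.
#' @export
step_lengths <- function(t1_extrema) {
  check_extrema(t1_extrema, 1L, "step lengths")
  abs(t1_extrema$merged_values)
}

#' Stride lengths from Type I extrema
#'
#' Sum of the magnitudes of subsequent extrema, `|e[i]| + |e[i+1]|`: the
#' distance covered by one full cycle of the same foot (two steps).
#'
#' @inheritParams step_times
#' @return Numeric vector of stride lengths in normalized amplitude units.
#' @export
stride_lengths <- function(t1_extrema) {
  check_extrema(t1_extrema, 2L, "stride lengths")
  a <- abs(t1_extrema$merged_values)
  a[-length(a)] + a[-1]
}

#' Swing times from one foot's Type II extrema
#'
#' Differences of consecutive ground-contact minima of a single foot's
#' height signal. Note this interval spans a full gait cycle of that foot
#' (contact to next contact), not only the off-ground phase; it is the
#' contact-to-contact operationalization used throughout this package.
#'
#' @param t2_extrema_one_foot `extrema_set` of one foot's Type II signal.
#' @return Numeric vector of times in seconds.
#' @export
swing_times <- function(t2_extrema_one_foot) {
  if (!inherits(t2_extrema_one_foot, "extrema_set")) stopf("expected an extrema_set")
  m <- t2_extrema_one_foot$minima_times
  if (length(m) < 2L)
    stopf("insufficient minima for swing times: have %d, need >= 2", length(m),
          class = "gaitstager_cycles")
  diff(m)
}

#' Double-support times from both feet's Type II extrema
#'
#' The lag on the time axis between the paired ground-contact minima of the
#' two feet. The two minima lists are first trimmed from the front until
#' their leading entries are within half an (estimated) contact cycle of
#' each other, then paired index-wise and truncated to the shorter list;
#' absolute differences are returned so durations are positive.
#'
#' @param t2_foot1,t2_foot2 `extrema_set`s of the two feet's Type II
#'   signals.
#' @return Numeric vector of times in seconds.
#' @export
double_support_times <- function(t2_foot1, t2_foot2) {
  m1 <- t2_foot1$minima_times
  m2 <- t2_foot2$minima_times
  if (length(m1) == 0L || length(m2) == 0L)
    stopf("insufficient minima for double support: feet have %d and %d minima",
          length(m1), length(m2), class = "gaitstager_cycles")
  cyc <- if (length(m1) >= 2L) stats::median(diff(m1))
         else if (length(m2) >= 2L) stats::median(diff(m2))
         else Inf
  while (length(m1) && length(m2) && abs(m1[1] - m2[1]) > cyc / 2) {
    if (m1[1] < m2[1]) m1 <- m1[-1] else m2 <- m2[-1]
  }
  if (length(m1) == 0L || length(m2) == 0L)
    stopf("no pairable contact minima between the two feet",
          class = "gaitstager_cycles")
  k <- min(length(m1), length(m2))
  abs(m1[seq_len(k)] - m2[seq_len(k)])
}

#' Extract the per-cycle feature table from the three gait signals
#'
#' Runs extremum detection on the Type I signal and both Type II signals,
#' computes the seven feature streams, aligns them by cycle index (row k
#' takes the k-th available value of every stream) and truncates to the
#' shortest stream.
#'
#' @param t1 Type I `gait_signal`.
#' @param t2_foot1,t2_foot2 Type II `gait_signal`s, one per foot.
#' @param peak_cfg List of extremum-detection settings:
#'   `min_prominence` (default 0.1) and `min_separation` seconds
#'   (default 0.25).
#' @return A `data.frame` with the columns of [gait_feature_names()] plus
#'   `cycle_index`.
#' @export
extract_feature_table <- function(t1, t2_foot1, t2_foot2, peak_cfg = list()) {
  prom <- peak_cfg$min_prominence %||% 0.1
  sep <- peak_cfg$min_separation %||% 0.25
  es1 <- find_extrema(t1, prom, sep)
  ef1 <- find_extrema(t2_foot1, prom, sep)
  ef2 <- find_extrema(t2_foot2, prom, sep)

  streams <- list(
    step_length = step_lengths(es1),
    step_time = step_times(es1),
    stride_time = stride_times(es1),
    stride_length = stride_lengths(es1),
    swing_time_foot1 = swing_times(ef1),
    swing_time_foot2 = swing_times(ef2),
    double_support = double_support_times(ef1, ef2))

  lens <- vapply(streams, length, integer(1))
  if (any(lens == 0L))
    stopf("insufficient cycles: empty feature stream(s) %s",
          paste(names(streams)[lens == 0L], collapse = ", "),
          class = "gaitstager_cycles")
  n <- min(lens)
  out <- as.data.frame(lapply(streams, function(s) s[seq_len(n)]))
  out$cycle_index <- seq_len(n)
  out
}

#' Write a feature table to CSV
#'
#' @param table Feature `data.frame` (optionally with `omega`/`stage`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_feature_csv()].
#' @return A feature `data.frame`; `stage` (if present) is a factor with
#'   levels I-IV.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- gait_feature_names()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("feature CSV missing column(s): %s", paste(missing_cols, collapse = ", "),
          class = "gaitstager_schema")
  if ("stage" %in% names(df)) df$stage <- factor(df$stage, levels = stage_levels())
  df
}
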