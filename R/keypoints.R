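#' Landmark names of the default 25-point body model
#'
#' Landmark naming follows the widely used 25-keypoint body model of
#' markerless pose estimators (nose, neck, shoulders, ..., heels, toes).
#' Only the heel, ankle and hip landmarks are consumed downstream; the rest
#' are carried through unchanged.
#'
#' @return Character vector of 25 landmark names, in keypoint order.
#' @export
body25_landmarks <- function() {
  c("Nose", "Neck", "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist", "MidHip",
    "RHip", "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel")
}

#' Construct a keypoint series
#'
#' A keypoint series holds per-frame 2-D landmark coordinates in image
#' convention (x rightward, y downward, pixels). Missing detections are
#' `NA` in both coordinate matrices, never silent zeros.
#'
#' @param frame_times Numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param landmarks Character vector of landmark names (column order of the
#'   coordinate matrices).
#' @param x,y Numeric matrices, frames x landmarks, pixel coordinates;
#'   `NA` marks a missing detection.
#' @param confidence Optional matrix of per-detection confidences in
#'   \[0, 1\], same shape as `x`.
#' @param fps Frames per second (> 0).
#' @param source_id Free-text provenance label.
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(frame_times, landmarks, x, y, confidence = NULL,
                            fps, source_id = "") {
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) == 0L) stopf("empty input: no frames", class = "gaitstager_empty")
  if (any(diff(frame_times) <= 0)) stopf("frame_times must be strictly increasing")
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == c(length(frame_times), length(landmarks))) ||
      !all(dim(x) == dim(y)))
    stopf("coordinate matrices must be frames x landmarks")
  if (any(is.infinite(x), na.rm = TRUE) || any(is.infinite(y), na.rm = TRUE))
    stopf("coordinates must be finite or NA")
  if (!is.null(confidence)) {
    confidence <- as.matrix(confidence)
    if (!all(dim(confidence) == dim(x))) stopf("confidence must match coordinate shape")
  }
  if (!is.numeric(fps) || fps <= 0) stopf("fps must be > 0")
  colnames(x) <- colnames(y) <- landmarks
  if (!is.null(confidence)) colnames(confidence) <- landmarks
  structure(list(frame_times = frame_times, landmarks = landmarks,
                 x = x, y = y, confidence = confidence,
                 fps = fps, source_id = source_id),
            class = "keypoint_series")
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("<keypoint_series> %d frames, %d landmarks, %.4g fps%s\n",
              length(x$frame_times), length(x$landmarks), x$fps,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Read pose-estimator per-frame JSON output
#'
#' Reads the per-frame JSON dialect emitted by OpenPose-style pose
#' estimators: each frame is a JSON object with a `people` array whose
#' entries carry a flat `pose_keypoints_2d` list of
#' `(x1, y1, c1, x2, y2, c2, ...)` triplets. `path` may be a directory of
#' per-frame files (read in lexical order) or a single JSON file holding an
#' array of such frame objects. Keypoints reported with zero confidence are
#' treated as missing detections.
#'
#' @param path Directory of per-frame `.json` files, or one concatenated
#'   JSON file.
#' @param person_index Zero-based index of the person to extract when a
#'   frame contains several people (default 0; a warning is emitted when
#'   more than one person is present).
#' @param fps Frames per second used to place frames on the time axis
#'   (`frame_times = frame index / fps`).
#' @param body_model Character vector naming the keypoints in triplet
#'   order; defaults to [body25_landmarks()].
#' @return A [keypoint_series()].
#' @export
read_openpose_json <- function(path, person_index = 0L, fps = 30,
                               body_model = body25_landmarks()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (length(files) == 0L) stopf("empty input: no JSON frame files in '%s'", path,
                                   class = "gaitstager_empty")
    frames <- lapply(files, function(f) {
      obj <- tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE),
                      error = function(e) stopf("unparsable JSON in '%s': %s", f,
                                                conditionMessage(e),
                                                class = "gaitstager_format"))
      obj
    })
  } else if (file.exists(path)) {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) stopf("unparsable JSON in '%s': %s", path,
                                              conditionMessage(e),
                                              class = "gaitstager_format"))
    frames <- obj
    files <- rep(path, length(frames))
    if (length(frames) == 0L) stopf("empty input: no frames in '%s'", path,
                                    class = "gaitstager_empty")
  } else {
    stopf("path '%s' does not exist", path)
  }

  n_lm <- length(body_model)
  xm <- matrix(NA_real_, length(frames), n_lm)
  ym <- matrix(NA_real_, length(frames), n_lm)
  cm <- matrix(NA_real_, length(frames), n_lm)
  warned <- FALSE
  for (i in seq_along(frames)) {
    people <- frames[[i]]$people
    if (is.null(people)) stopf("frame %d ('%s') has no 'people' field", i, files[i],
                               class = "gaitstager_format")
    if (length(people) == 0L) next  # nobody detected: all landmarks missing
    if (person_index + 1L > length(people))
      stopf("person_index %d out of range: frame %d has %d people (indices 0..%d)",
            person_index, i, length(people), length(people) - 1L)
    if (length(people) > 1L && !warned) {
      warning(sprintf("frame %d has %d people; using person_index %d",
                      i, length(people), person_index))
      warned <- TRUE
    }
    kp <- unlist(people[[person_index + 1L]]$pose_keypoints_2d)
    if (length(kp) < 3L * n_lm) kp <- c(kp, rep(0, 3L * n_lm - length(kp)))
    kp <- kp[seq_len(3L * n_lm)]
    xs <- kp[seq(1L, by = 3L, length.out = n_lm)]
    ys <- kp[seq(2L, by = 3L, length.out = n_lm)]
    cs <- kp[seq(3L, by = 3L, length.out = n_lm)]
    miss <- cs <= 0
    xs[miss] <- NA_real_; ys[miss] <- NA_real_
    xm[i, ] <- xs; ym[i, ] <- ys; cm[i, ] <- cs
  }
  keypoint_series(frame_times = (seq_along(frames) - 1L) / fps,
                  landmarks = body_model, x = xm, y = ym, confidence = cm,
                  fps = fps, source_id = path)
}

#' Read a keypoint series from long-format CSV
#'
#' Expects columns `frame,time_s,landmark,x,y,confidence`; empty `x`/`y`
#' cells mark missing detections.
#'
#' @param path CSV file path.
#' @return A [keypoint_series()].
#' @export
read_keypoint_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("frame", "time_s", "landmark", "x", "y", "confidence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("schema error: missing column(s) %s", paste(missing_cols, collapse = ", "),
          class = "gaitstager_schema")
  if (nrow(df) == 0L) stopf("empty input: no rows in '%s'", path,
                            class = "gaitstager_empty")
  landmarks <- unique(df$landmark)
  frames <- sort(unique(df$frame))
  tmap <- tapply(df$time_s, df$frame, function(v) v[1])
  frame_times <- as.numeric(tmap[as.character(frames)])
  for (lm in landmarks) {
    tl <- df$time_s[df$landmark == lm]
    if (any(diff(tl) <= 0)) stopf("non-monotone time within landmark '%s'", lm)
  }
  n <- length(frames); p <- length(landmarks)
  xm <- matrix(NA_real_, n, p); ym <- matrix(NA_real_, n, p); cm <- matrix(NA_real_, n, p)
  ri <- match(df$frame, frames); ci <- match(df$landmark, landmarks)
  idx <- cbind(ri, ci)
  xm[idx] <- df$x; ym[idx] <- df$y; cm[idx] <- df$confidence
  fps <- if (n > 1L) 1 / stats::median(diff(frame_times)) else 30
  keypoint_series(frame_times, landmarks, xm, ym, cm, fps = fps, source_id = path)
}

#' Write a keypoint series to long-format CSV
#'
#' Rows are written frame-major (all landmarks of frame 1, then frame 2,
#' ...), with missing coordinates as empty cells, so that
#' [read_keypoint_csv()] round-trips the series exactly.
#'
#' @param series A [keypoint_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(series, path) {
  stopifnot(inherits(series, "keypoint_series"))
  n <- length(series$frame_times); p <- length(series$landmarks)
  df <- data.frame(
    frame = rep(seq_len(n) - 1L, each = p),
    time_s = rep(series$frame_times, each = p),
    landmark = rep(series$landmarks, times = n),
    x = as.vector(t(series$x)),
    y = as.vector(t(series$y)),
    confidence = if (is.null(series$confidence)) NA_real_ else as.vector(t(series$confidence)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract per-landmark coordinate tracks
#'
#' Pulls the requested landmarks out of a keypoint series as individual
#' time/x/y tracks, resolving missing detections by the chosen gap policy:
#' `"interpolate"` fills interior gaps by linear interpolation in time and
#' drops leading/trailing gaps; `"drop"` removes every frame at which any
#' requested landmark is missing (all returned tracks then share one grid).
#'
#' @param series A [keypoint_series()].
#' @param names Landmark names to extract.
#' @param gap_policy `"drop"` or `"interpolate"`.
#' @return Named list of `landmark_track` objects (fields `name`, `times`,
#'   `x`, `y`).
#' @export
select_landmarks <- function(series, names, gap_policy = c("drop", "interpolate")) {
  stopifnot(inherits(series, "keypoint_series"))
  gap_policy <- match.arg(gap_policy)
  unknown <- setdiff(names, series$landmarks)
  if (length(unknown))
    stopf("unknown landmark(s) %s; available: %s",
          paste(unknown, collapse = ", "), paste(series$landmarks, collapse = ", "))
  cols <- match(names, series$landmarks)
  miss <- is.na(series$x[, cols, drop = FALSE]) | is.na(series$y[, cols, drop = FALSE])

  make_track <- function(nm, times, xs, ys) {
    if (length(times) < 4L)
      stopf("track '%s' too short: %d surviving frames (need >= 4)", nm, length(times),
            class = "gaitstager_short")
    structure(list(name = nm, times = times, x = xs, y = ys), class = "landmark_track")
  }

  if (gap_policy == "drop") {
    keep <- !apply(miss, 1L, any)
    out <- lapply(seq_along(names), function(j) {
      make_track(names[j], series$frame_times[keep],
                 series$x[keep, cols[j]], series$y[keep, cols[j]])
    })
  } else {
    out <- lapply(seq_along(names), function(j) {
      t <- series$frame_times
      xs <- series$x[, cols[j]]; ys <- series$y[, cols[j]]
      ok <- !(is.na(xs) | is.na(ys))
      if (sum(ok) < 4L)
        stopf("track '%s' too short: %d present frames (need >= 4)", names[j], sum(ok),
              class = "gaitstager_short")
      # keep only the span between first and last present sample
      span <- which(ok)
      rng <- span[1]:span[length(span)]
      xi <- stats::approx(t[ok], xs[ok], xout = t[rng], method = "linear")$y
      yi <- stats::approx(t[ok], ys[ok], xout = t[rng], method = "linear")$y
      make_track(names[j], t[rng], xi, yi)
    })
  }
  stats::setNames(out, names)
}
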