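# Curve containers: instantaneous sampled curves (blood / plasma) and
# frame-structured tissue time-activity curves.

#' Sampled activity curve
#'
#' Container for an instantaneous activity curve sampled at (possibly
#' irregular) time points, such as a whole-blood curve from a coincidence
#' counter or a plasma input function. Times are in seconds, activities in
#' kBq/cm3. All activities are assumed decay-corrected; the package never
#' applies or removes radioactive decay.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param activity numeric vector of activities in kBq/cm3, same length as
#'   `time`, all finite.
#' @param kind curve role, `"plasma"` or `"blood"`.
#' @return A data frame of class `"sampled_curve"` with columns `time` and
#'   `activity` and a `"kind"` attribute.
#' @examples
#' sampled_curve(0:10, seq(0, 100, by = 10), kind = "blood")
#' @export
sampled_curve <- function(time, activity, kind = c("plasma", "blood")) {
  kind <- match.arg(kind)
  time <- as.numeric(time)
  activity <- as.numeric(activity)
  if (length(time) != length(activity))
    stop("'time' and 'activity' must have equal length")
  if (length(time) < 2L)
    stop("a sampled curve needs at least 2 samples")
  if (any(!is.finite(time)) || any(!is.finite(activity)))
    stop("times and activities must be finite")
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing (first violation after index ",
         which(diff(time) <= 0)[1L], ")")
  out <- data.frame(time = time, activity = activity)
  attr(out, "kind") <- kind
  class(out) <- c("sampled_curve", "data.frame")
  out
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("Sampled %s curve: %d samples, t = %g..%g s, peak %.4g kBq/cm3\n",
              attr(x, "kind"), nrow(x), x$time[1L], x$time[nrow(x)],
              max(x$activity)))
  invisible(x)
}

#' Frame-structured tissue time-activity curve
#'
#' Container for a tissue TAC as reconstructed from dynamic PET: one
#' frame-averaged activity per reconstruction frame. Frames must be
#' non-overlapping and, by default, contiguous (`end[i] == start[i+1]`);
#' gapped schedules (e.g. after deleting every second frame to reduce the
#' degrees of freedom) are accepted with `allow_gaps = TRUE`.
#'
#' @param start,end frame boundaries in seconds, `end > start` per frame.
#' @param activity frame-averaged activity in kBq/cm3 (may be omitted to
#'   describe a bare frame schedule; see [make_frame_schedule()]).
#' @param allow_gaps logical; accept non-contiguous frames.
#' @return A data frame of class `"frame_tac"` with columns `start`, `end`
#'   and `activity`.
#' @export
frame_tac <- function(start, end, activity = NA_real_, allow_gaps = FALSE) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(end) != n) stop("'start' and 'end' must have equal length")
  if (n < 1L) stop("at least one frame is required")
  bad <- which(end <= start)
  if (length(bad))
    stop("frame end must exceed frame start (row ", bad[1L], ")")
  if (n > 1L) {
    gap <- which(abs(start[-1L] - end[-n]) > 1e-9)
    if (length(gap)) {
      if (!allow_gaps)
        stop("frames must be contiguous: end of row ", gap[1L],
             " does not meet start of row ", gap[1L] + 1L)
      if (any(start[-1L] - end[-n] < -1e-9))
        stop("frames overlap at row ", gap[1L])
    }
  }
  activity <- rep_len(as.numeric(activity), n)
  out <- data.frame(start = start, end = end, activity = activity)
  class(out) <- c("frame_tac", "data.frame")
  out
}

#' @export
print.frame_tac <- function(x, ...) {
  cat(sprintf("Frame TAC: %d frames over %g..%g s (durations %g..%g s)\n",
              nrow(x), x$start[1L], x$end[nrow(x)],
              min(x$end - x$start), max(x$end - x$start)))
  invisible(x)
}

# Linear interpolation of a sampled curve onto an arbitrary time grid.
# rule = 2: constant extrapolation at both ends (used for time-shifted
# input functions whose support no longer covers the scan).
interp_curve <- function(curve, tout, rule = 2) {
  stats::approx(curve$time, curve$activity, xout = tout, rule = rule)$y
}

# Assert that a sampled curve covers [0, t_end] (within one native step).
check_coverage <- function(curve, t_end, what = "curve") {
  step <- max(diff(curve$time))
  if (curve$time[1L] > 0 + 1e-9 || curve$time[length(curve$time)] < t_end - step)
    stop(what, " does not cover the requested span [0, ", t_end, "] s")
  invisible(TRUE)
}

#' Read a curve from CSV
#'
#' Reads a sampled curve or a frame TAC from the package's plain CSV format.
#' Sampled curves have columns `time_s, activity_kBq_cm3`; frame TACs have
#' `start_s, end_s, activity_kBq_cm3`. Units are fixed by the header names.
#'
#' @param path CSV file path.
#' @param kind `"plasma"`, `"blood"`, or `"tac"`.
#' @return A [sampled_curve()] or [frame_tac()].
#' @seealso [write_curve()]
#' @export
read_curve <- function(path, kind = c("plasma", "blood", "tac")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("curve file not found: ", path)
  df <- utils::read.csv(path)
  if (kind == "tac") {
    need <- c("start_s", "end_s", "activity_kBq_cm3")
    if (!all(need %in% names(df)))
      stop("TAC file ", path, " must have columns ", paste(need, collapse = ", "))
    bad <- which(df$end_s <= df$start_s)
    if (length(bad))
      stop("TAC file ", path, ": end <= start on row ", bad[1L])
    frame_tac(df$start_s, df$end_s, df$activity_kBq_cm3, allow_gaps = TRUE)
  } else {
    need <- c("time_s", "activity_kBq_cm3")
    if (!all(need %in% names(df)))
      stop("curve file ", path, " must have columns ", paste(need, collapse = ", "))
    if (any(diff(df$time_s) <= 0))
      stop("curve file ", path, ": times not strictly increasing at row ",
           which(diff(df$time_s) <= 0)[1L] + 1L)
    sampled_curve(df$time_s, df$activity_kBq_cm3, kind = kind)
  }
}

#' Write a curve to CSV
#'
#' Inverse of [read_curve()]; a write/read round trip reproduces the curve.
#'
#' @param x a [sampled_curve()] or [frame_tac()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  if (inherits(x, "frame_tac")) {
    df <- data.frame(start_s = x$start, end_s = x$end,
                     activity_kBq_cm3 = x$activity)
  } else if (inherits(x, "sampled_curve")) {
    df <- data.frame(time_s = x$time, activity_kBq_cm3 = x$activity)
  } else stop("'x' must be a sampled_curve or frame_tac")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Evaluate the RNG-dependent expression under a fixed seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
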