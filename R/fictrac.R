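# Trackball tracking-log input: FicTrac-style delimited text, one row per
# video frame. The reader exposes a validated `trajectory`; `align()` cuts it
# into per-epoch segments against a stimulation schedule.

# Column registry. FicTrac v2 .dat files are comma-delimited with 25 columns;
# the map below names the ones the pipeline consumes (1-based indices).
.fictrac_dialects <- list(
  fictrac_v2 = list(
    n_columns = 25L,
    sep = ",",
    columns = list(
      frame_index   = 1L,
      delta_rot_lab = 6:8,    # per-frame ball rotation about lab x/y/z, rad
      heading       = 17L,    # integrated animal heading, rad, wrapped [0, 2pi)
      move_speed    = 19L,    # per-frame total ball rotation magnitude, rad
      timestamp_ms  = 22L
    )
  )
)

#' Registered trackball log dialects
#' @return character vector of dialect names accepted by [read_trackball_log()].
#' @export
trackball_dialects <- function() names(.fictrac_dialects)

#' Construct a trajectory
#'
#' A `trajectory` holds the per-frame state of a tethered animal walking on an
#' air-supported trackball: time, unwrapped integrated heading (leftward /
#' counter-clockwise positive), the per-frame ball rotation increments about
#' the three lab axes, and total movement speed. Ball diameter and nominal
#' frame rate travel with the data so path lengths can be expressed in cm.
#'
#' @param time seconds per frame, strictly increasing.
#' @param heading unwrapped integrated heading in radians, leftward positive.
#' @param delta_rot n-by-3 matrix of per-frame rotation increments (radians)
#'   about the lab x/y/z axes; `NULL` if unavailable.
#' @param move_speed per-frame total rotation magnitude in radians;
#'   recomputed from `delta_rot` when `NULL`.
#' @param frame_index frame counter; defaults to `seq_along(time)`.
#' @param ball_diameter ball diameter in cm (> 0).
#' @param frame_rate nominal camera frame rate in Hz.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(time, heading, delta_rot = NULL, move_speed = NULL,
                       frame_index = seq_along(time), ball_diameter = 5,
                       frame_rate = NA_real_) {
  n <- length(time)
  if (length(heading) != n) stop_invalid("time and heading lengths differ")
  if (n >= 2L && any(diff(time) <= 0))
    stop_invalid("time must be strictly increasing")
  if (!is.null(delta_rot)) {
    delta_rot <- as.matrix(delta_rot)
    if (nrow(delta_rot) != n || ncol(delta_rot) != 3L)
      stop_invalid("delta_rot must be an n-by-3 matrix")
  }
  if (is.null(move_speed)) {
    move_speed <- if (!is.null(delta_rot)) sqrt(rowSums(delta_rot^2))
                  else rep(NA_real_, n)
  } else if (length(move_speed) != n) {
    stop_invalid("move_speed length differs from time")
  }
  if (!is.numeric(ball_diameter) || ball_diameter <= 0)
    stop_invalid("ball_diameter must be > 0")
  structure(list(frame_index = frame_index, time = as.numeric(time),
                 heading = as.numeric(heading), delta_rot = delta_rot,
                 move_speed = as.numeric(move_speed),
                 ball_diameter = ball_diameter, frame_rate = frame_rate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %.1f s, ball %g cm%s\n",
              length(x$time), diff(range(x$time)), x$ball_diameter,
              if (is.na(x$frame_rate)) "" else sprintf(", %g fps", x$frame_rate)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$time)

#' Read a trackball tracking log
#'
#' Parses a FicTrac-style delimited text log into a validated [trajectory()].
#' The heading column (stored modulo \eqn{2\pi} in the file) is unwrapped so
#' that successive differences never jump by \eqn{\pm\pi}; leftward
#' (counter-clockwise) rotation is positive. If the timestamp column carries
#' no information (all zero or constant), frame times fall back to
#' `frame_index / frame_rate`.
#'
#' @param path path to the log file.
#' @param dialect one of [trackball_dialects()] (default `"fictrac_v2"`:
#'   25 comma-separated columns).
#' @param ball_diameter ball diameter in cm.
#' @param frame_rate nominal frame rate in Hz, used as a timestamp fallback.
#' @return a [trajectory()].
#' @export
read_trackball_log <- function(path, dialect = "fictrac_v2",
                               ball_diameter = 5, frame_rate = 50) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  dialect <- match.arg(dialect, trackball_dialects())
  d <- .fictrac_dialects[[dialect]]
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop_invalid("empty log file: ", path)
  parts <- strsplit(lines, d$sep, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != d$n_columns)
  if (length(bad))
    stop_invalid(sprintf("format error: line %d has %d fields, expected %d (%s)",
                         bad[1L], nf[bad[1L]], d$n_columns, dialect))
  m <- matrix(as.numeric(unlist(parts)), nrow = length(parts),
              ncol = d$n_columns, byrow = TRUE)
  nonnum <- which(rowSums(is.na(m)) > 0L)
  if (length(nonnum))
    stop_invalid(sprintf("format error: non-numeric field on line %d", nonnum[1L]))
  cols <- d$columns
  ts <- m[, cols$timestamp_ms] / 1000
  if (length(ts) > 1L && (all(ts == 0) || length(unique(ts)) == 1L)) {
    time <- (m[, cols$frame_index] - m[1L, cols$frame_index]) / frame_rate
  } else {
    time <- ts
    if (any(diff(time) <= 0)) stop_invalid("data error: non-monotone timestamps")
  }
  trajectory(time = time,
             heading = unwrap_angle(m[, cols$heading]),
             delta_rot = m[, cols$delta_rot_lab, drop = FALSE],
             move_speed = m[, cols$move_speed],
             frame_index = m[, cols$frame_index],
             ball_diameter = ball_diameter, frame_rate = frame_rate)
}

#' Write a trajectory as a FicTrac v2 log
#'
#' Inverse of [read_trackball_log()] for the `fictrac_v2` dialect: produces a
#' 25-column comma-delimited .dat file with the heading wrapped to
#' \eqn{[0, 2\pi)} and timestamps in milliseconds. Columns the trajectory does
#' not carry are written as zeros.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trackball_log <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$time)
  m <- matrix(0, nrow = n, ncol = 25L)
  cols <- .fictrac_dialects$fictrac_v2$columns
  m[, cols$frame_index] <- traj$frame_index
  if (!is.null(traj$delta_rot)) m[, cols$delta_rot_lab] <- traj$delta_rot
  m[, cols$heading] <- traj$heading %% (2 * pi)
  m[, cols$move_speed] <- ifelse(is.na(traj$move_speed), 0, traj$move_speed)
  m[, cols$timestamp_ms] <- traj$time * 1000
  m[, 23L] <- seq_len(n)  # sequence counter
  txt <- do.call(paste, c(lapply(seq_len(25L), function(j)
    formatC(m[, j], format = "g", digits = 15)), sep = ","))
  writeLines(txt, path)
  invisible(path)
}

#' Align a trajectory to a stimulation schedule
#'
#' Cuts a trajectory into one contiguous segment per schedule epoch. Frames
#' falling outside every epoch (inter-stimulus intervals, lead-in) are
#' excluded. A trajectory that ends before the schedule does yields segments
#' for the covered epochs only, plus a coverage warning recorded on the result.
#'
#' @param traj a [trajectory()].
#' @param schedule a [build_schedule()] object.
#' @param t0 trajectory time (seconds) at which schedule time 0 occurs.
#' @return a list of `stimulus_segment` objects (fields: `spec`,
#'   `stimulus_index`, `epoch`, plus per-frame `time`, `heading`, `delta_rot`,
#'   `move_speed`, and `ball_diameter`), ordered by onset, with attribute
#'   `coverage_warning` (character or `NULL`).
#' @export
align <- function(traj, schedule, t0 = 0) {
  stopifnot(inherits(traj, "trajectory"), inherits(schedule, "schedule"))
  segs <- list()
  missed <- 0L
  for (i in seq_along(schedule$stimuli)) {
    st <- schedule$stimuli[[i]]
    for (ep in st$epochs) {
      lo <- t0 + ep$onset
      hi <- lo + ep$duration
      idx <- which(traj$time >= lo & traj$time < hi)
      if (length(idx) == 0L) { missed <- missed + 1L; next }
      segs[[length(segs) + 1L]] <- structure(
        list(spec = st$spec, stimulus_index = i, epoch = ep,
             time = traj$time[idx], heading = traj$heading[idx],
             delta_rot = if (!is.null(traj$delta_rot))
               traj$delta_rot[idx, , drop = FALSE] else NULL,
             move_speed = traj$move_speed[idx],
             ball_diameter = traj$ball_diameter),
        class = "stimulus_segment")
    }
  }
  warn <- if (missed > 0L)
    sprintf("partial coverage: %d epoch(s) have no trajectory frames", missed)
  else NULL
  if (!is.null(warn)) warning(warn, call. = FALSE)
  structure(segs, coverage_warning = warn)
}
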