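# Behavioral response features extracted per animal and stimulus from aligned
# trackball segments. Accumulated rotation is reset to 0 at each direction
# switch, leftward turning positive. Five features summarize each response:
# maximum accumulated rotation (ymax), path tortuosity (mean R^2 of the
# per-replicate linear fits), walking pace, absolute turning velocity (|mean
# signed slope| across replicates), and rotation asymmetry
# y.sym = |ymax_r - ymax_l| / max(ymax_r, ymax_l).

#' Convert an aligned segment into a replicate path
#'
#' Re-zeroes time and accumulated rotation at the epoch onset, keeping the
#' raw sign convention (leftward turning positive, rightward negative).
#'
#' @param seg a `stimulus_segment` from [align()].
#' @return a `replicate_path`: list with `t` (s, starting at 0), `y`
#'   (accumulated rotation, rad, leftward positive) and `direction`.
#' @export
segment_to_path <- function(seg) {
  stopifnot(inherits(seg, "stimulus_segment"))
  if (length(seg$time) == 0L) stop_invalid("empty segment")
  structure(list(t = seg$time - seg$time[1L],
                 y = seg$heading - seg$heading[1L],
                 direction = seg$epoch$direction),
            class = "replicate_path")
}

# Least squares of y on t. Returns slope and R^2; r_squared is NA when y has
# no variance (R^2 is 0/0 there).
ols_fit <- function(t, y, fit_intercept = TRUE) {
  n <- length(t)
  if (fit_intercept) {
    tc <- t - mean(t); yc <- y - mean(y)
    sxx <- sum(tc^2)
    slope <- if (sxx > 0) sum(tc * yc) / sxx else NA_real_
    sst <- sum(yc^2)
    ssr <- if (is.na(slope)) NA_real_ else slope^2 * sxx
  } else {
    sxx <- sum(t^2)
    slope <- if (sxx > 0) sum(t * y) / sxx else NA_real_
    sst <- sum(y^2)
    ssr <- if (is.na(slope)) NA_real_ else slope^2 * sxx
  }
  r2 <- if (is.na(slope) || sst <= 0) NA_real_ else max(0, min(1, ssr / sst))
  list(slope = slope, r_squared = r2, n = n)
}

#' Fit linear regressions to replicate paths
#'
#' Ordinary least squares of accumulated rotation on time, one fit per
#' replicate epoch. By default the fit includes an intercept: although each
#' path starts at 0, a reaction latency shifts the straight-line portion, and
#' the intercept keeps R^2 interpretable as path tortuosity rather than a
#' lack-of-fit to a line through the origin.
#'
#' @param paths list of [segment_to_path()] results (8 under the standard
#'   4-repeat protocol).
#' @param fit_intercept include an intercept term (default `TRUE`).
#' @return data.frame with one row per path: `direction`, `slope` (rad/s),
#'   `r_squared`, `n_points`, `valid`. Paths with fewer than 3 points are
#'   flagged invalid and excluded from downstream means, with a warning.
#' @export
fit_replicates <- function(paths, fit_intercept = TRUE) {
  stopifnot(length(paths) >= 1L)
  rows <- lapply(paths, function(p) {
    stopifnot(inherits(p, "replicate_path"))
    if (length(p$t) < 3L)
      return(data.frame(direction = p$direction, slope = NA_real_,
                        r_squared = NA_real_, n_points = length(p$t),
                        valid = FALSE))
    f <- ols_fit(p$t, p$y, fit_intercept)
    data.frame(direction = p$direction, slope = f$slope,
               r_squared = f$r_squared, n_points = f$n,
               valid = is.finite(f$slope))
  })
  out <- do.call(rbind, rows)
  if (any(!out$valid))
    warning(sprintf("%d replicate(s) with undefined fits excluded",
                    sum(!out$valid)), call. = FALSE)
  out
}

#' Absolute turning velocity
#'
#' The signed replicate slopes are averaged first, then the absolute value is
#' taken, so perfectly symmetric leftward/rightward responses cancel to 0
#' while a consistent turn bias survives.
#'
#' @param fits data.frame from [fit_replicates()].
#' @return |mean signed slope| in rad/s, or `NA` when no fit is valid.
#' @export
turning_velocity <- function(fits) {
  s <- fits$slope[fits$valid & is.finite(fits$slope)]
  if (length(s) == 0L) return(NA_real_)
  abs(mean(s))
}

#' Path tortuosity
#'
#' Mean R^2 across the replicate fits. Values near 1 indicate responses that
#' switch direction promptly and hold a consistent yaw; wavering or
#' slow-switching paths score lower.
#'
#' @param fits data.frame from [fit_replicates()].
#' @return mean R^2 in \[0, 1\], or `NA` when no fit has a defined R^2.
#' @export
tortuosity <- function(fits) {
  r2 <- fits$r_squared[fits$valid & is.finite(fits$r_squared)]
  if (length(r2) == 0L) return(NA_real_)
  mean(r2)
}

#' Rotation asymmetry
#'
#' Rightward-epoch paths are sign-inverted so both directions are on the same
#' (non-negative) scale; the maximum accumulated rotation of each corrected
#' path is averaged per direction, giving `ymax_left` and `ymax_right`, and
#' the asymmetry index is
#' \deqn{y_{sym} = |ymax_r - ymax_l| / \max(ymax_r, ymax_l),}
#' 0 for symmetric responses and 1 for fully one-sided ones. When both
#' direction averages are 0 (no response at all) the index is defined as 0
#' with `degenerate = TRUE`.
#'
#' @param paths list of [segment_to_path()] results covering both directions.
#' @param tie_tol absolute tolerance (rad) below which the two direction
#'   averages are declared tied (`bias_direction = "NONE"`).
#' @return list with `ymax_left`, `ymax_right`, `ymax` (mean of the two),
#'   `y_sym`, `bias_direction` (`"LEFT"`, `"RIGHT"` or `"NONE"`), `degenerate`.
#' @export
rotation_asymmetry <- function(paths, tie_tol = 1e-9) {
  dirs <- vapply(paths, function(p) p$direction, character(1))
  if (!all(c("LEFT", "RIGHT") %in% dirs))
    stop_invalid("paths must include both LEFT and RIGHT epochs")
  ymax_rep <- vapply(paths, function(p) {
    yc <- if (p$direction == "RIGHT") -p$y else p$y
    max(yc)
  }, numeric(1))
  ymax_l <- mean(ymax_rep[dirs == "LEFT"])
  ymax_r <- mean(ymax_rep[dirs == "RIGHT"])
  degenerate <- FALSE
  mx <- max(ymax_r, ymax_l)
  if (mx <= 0) {
    y_sym <- 0
    degenerate <- TRUE
  } else {
    y_sym <- abs(ymax_r - ymax_l) / mx
  }
  bias <- if (abs(ymax_r - ymax_l) <= tie_tol) "NONE"
          else if (ymax_r > ymax_l) "RIGHT" else "LEFT"
  list(ymax_left = ymax_l, ymax_right = ymax_r, ymax = mean(c(ymax_l, ymax_r)),
       y_sym = y_sym, bias_direction = bias, degenerate = degenerate)
}

#' Walking pace over a stimulus
#'
#' Path length is the per-frame total ball rotation magnitude (norm of the
#' three-axis rotation increment) times the ball radius, summed over frames;
#' pace is path length divided by stimulation time, averaged across the
#' replicate presentations. If the three-axis increments are absent the
#' tracker's movement-speed column is used instead.
#'
#' @param segs list of `stimulus_segment`s belonging to one stimulus.
#' @return mean pace in cm/s.
#' @export
walking_pace <- function(segs) {
  stopifnot(length(segs) >= 1L)
  paces <- vapply(segs, function(s) {
    r <- s$ball_diameter / 2
    rot <- if (!is.null(s$delta_rot)) sqrt(rowSums(s$delta_rot^2))
           else s$move_speed
    if (all(is.na(rot))) return(NA_real_)
    n <- length(s$time)
    dt <- if (n >= 2L) stats::median(diff(s$time)) else s$epoch$duration
    sum(rot, na.rm = TRUE) * r / (n * dt)
  }, numeric(1))
  mean(paces, na.rm = TRUE)
}

#' Extract behavioral response features
#'
#' End-to-end feature extraction for one animal: aligns the trajectory to the
#' schedule, builds replicate paths per stimulus, and computes the five
#' response features for every stimulus with at least one covered epoch.
#' Stimuli whose epochs are only partially covered, or with fewer than 2
#' valid replicate fits per direction, are flagged.
#'
#' @param traj a [trajectory()].
#' @param schedule a [build_schedule()] object.
#' @param t0 trajectory time at schedule time 0.
#' @param animal_id identifier copied into the output.
#' @param fit_intercept passed to [fit_replicates()].
#' @return data.frame with one row per stimulus: `animal_id`,
#'   `stimulus_label`, `spatial_frequency`, `temporal_frequency`,
#'   `angular_velocity`, `ymax_left`, `ymax_right`, `ymax`,
#'   `rotation_asymmetry`, `tortuosity`, `walking_pace`,
#'   `abs_turning_velocity`, `bias_direction`, `n_replicates`, `qc_flag`.
#' @export
extract_features <- function(traj, schedule, t0 = 0, animal_id = "animal",
                             fit_intercept = TRUE) {
  segs <- suppressWarnings(align(traj, schedule, t0))
  if (length(segs) == 0L)
    stop_invalid("no schedule epoch is covered by the trajectory")
  idx <- vapply(segs, function(s) s$stimulus_index, integer(1))
  expected <- 2L * schedule$repeats
  rows <- lapply(sort(unique(idx)), function(i) {
    ss <- segs[idx == i]
    spec <- ss[[1L]]$spec
    paths <- lapply(ss, segment_to_path)
    fits <- suppressWarnings(fit_replicates(paths, fit_intercept))
    dirs <- vapply(paths, function(p) p$direction, character(1))
    flags <- character(0)
    if (length(ss) < expected) flags <- c(flags, "partial_coverage")
    for (d in c("LEFT", "RIGHT"))
      if (sum(fits$valid[dirs == d]) < 2L)
        flags <- c(flags, "low_confidence")
    asym <- if (all(c("LEFT", "RIGHT") %in% dirs)) rotation_asymmetry(paths)
            else list(ymax_left = NA_real_, ymax_right = NA_real_,
                      ymax = NA_real_, y_sym = NA_real_,
                      bias_direction = NA_character_, degenerate = FALSE)
    if (isTRUE(asym$degenerate)) flags <- c(flags, "degenerate_asymmetry")
    data.frame(
      animal_id = animal_id, stimulus_label = spec$label,
      spatial_frequency = spec$spatial_frequency,
      temporal_frequency = spec$temporal_frequency,
      angular_velocity = angular_velocity(spec),
      ymax_left = asym$ymax_left, ymax_right = asym$ymax_right,
      ymax = asym$ymax, rotation_asymmetry = asym$y_sym,
      tortuosity = tortuosity(fits), walking_pace = walking_pace(ss),
      abs_turning_velocity = turning_velocity(fits),
      bias_direction = asym$bias_direction, n_replicates = length(ss),
      qc_flag = if (length(flags)) paste(unique(flags), collapse = ";") else "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
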