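# Open-loop visual stimulation protocol: translating sine-wave gratings shown
# in alternating leftward/rightward epochs, several stimuli per session in a
# seeded pseudo-random order separated by an inter-stimulus interval.

#' Define a grating stimulus
#'
#' A translating vertical sine-wave grating is characterized by its spatial
#' frequency (cycles per degree, cpd) and temporal frequency (Hz). Their ratio
#' gives the angular velocity of the pattern in degrees per second.
#'
#' @param spatial_frequency spatial frequency in cycles per degree; must be > 0.
#' @param temporal_frequency temporal frequency in Hz; must be > 0 unless
#'   `static = TRUE`, in which case it must be 0 (a stationary grating used as
#'   a no-optic-flow control).
#' @param label optional free-text label; defaults to `"tf<Hz>_sf<cpd>"`.
#' @param static logical; `TRUE` marks a stationary-grating control condition.
#' @return an object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(0.0625, 16)
#' angular_velocity(stimulus_spec(0.0625, 16))  # 256 deg/s
#' @export
stimulus_spec <- function(spatial_frequency, temporal_frequency, label = NULL,
                          static = FALSE) {
  if (!is.numeric(spatial_frequency) || length(spatial_frequency) != 1L ||
      !is.finite(spatial_frequency) || spatial_frequency <= 0)
    stop_invalid("spatial_frequency must be a single positive number (cpd)")
  if (!is.numeric(temporal_frequency) || length(temporal_frequency) != 1L ||
      !is.finite(temporal_frequency))
    stop_invalid("temporal_frequency must be a single finite number (Hz)")
  if (static) {
    if (temporal_frequency != 0)
      stop_invalid("a static stimulus must have temporal_frequency = 0")
  } else if (temporal_frequency <= 0) {
    stop_invalid("temporal_frequency must be > 0 for a moving grating; ",
                 "use static = TRUE for a stationary control")
  }
  label <- label %||% sprintf("tf%g_sf%g", temporal_frequency, spatial_frequency)
  structure(list(spatial_frequency = spatial_frequency,
                 temporal_frequency = temporal_frequency,
                 label = label, static = static),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s: %g cpd, %g Hz%s\n", x$label,
              x$spatial_frequency, x$temporal_frequency,
              if (x$static) " (static)" else
                sprintf(" (%g deg/s)", angular_velocity(x))))
  invisible(x)
}

#' Angular velocity of a grating
#'
#' The pattern velocity of a translating grating is its temporal frequency
#' divided by its spatial frequency, in degrees per second.
#'
#' @param spec a [stimulus_spec()].
#' @return angular velocity in degrees per second (0 for a static grating).
#' @export
angular_velocity <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  spec$temporal_frequency / spec$spatial_frequency
}

#' Default grating battery
#'
#' A 12-stimulus battery spanning the ranges used in walking optomotor assays:
#' seven temporal frequencies (4--48 Hz) at a fixed spatial frequency of
#' 0.0625 cpd, and five additional spatial frequencies (0.5--0.0039 cpd) at a
#' fixed temporal frequency of 16 Hz. The 16 Hz / 0.0625 cpd combination is
#' shared between the two sweeps and appears once.
#'
#' @return list of 12 [stimulus_spec()] objects.
#' @export
default_stimulus_battery <- function() {
  tf <- c(4, 8, 12, 16, 24, 32, 48)
  sf <- c(0.5, 0.125, 0.03125, 0.0078, 0.0039)
  c(lapply(tf, function(f) stimulus_spec(0.0625, f)),
    lapply(sf, function(s) stimulus_spec(s, 16)))
}

new_epoch <- function(direction, onset, duration) {
  stopifnot(direction %in% c("LEFT", "RIGHT"), duration > 0)
  structure(list(direction = direction, onset = onset, duration = duration),
            class = "epoch")
}

#' Build a stimulation schedule
#'
#' Arranges grating stimuli into an open-loop protocol: each stimulus is
#' presented as `repeats` pairs of alternating epochs (leftward first, then an
#' instantaneous switch to rightward), and stimuli follow each other in a
#' seeded pseudo-random order separated by `isi` seconds. With the standard
#' protocol of 4 repeats of 10-s epochs, each stimulus delivers
#' 4 x (10 s left + 10 s right) = 80 s of stimulation split into 8 replicate
#' epochs.
#'
#' @param specs list of [stimulus_spec()] objects.
#' @param epoch_duration duration of one direction epoch in seconds.
#' @param repeats number of left/right pairs per stimulus (default 4).
#' @param isi inter-stimulus interval in seconds (default 180).
#' @param order_seed integer seed for the Fisher-Yates presentation-order
#'   permutation; recorded in the schedule. `NULL` keeps the given order.
#' @return an object of class `schedule`: a list with elements `stimuli`
#'   (each a list with `spec`, `onset`, `epochs`), `epoch_duration`, `repeats`,
#'   `isi`, `order_seed`, and `duration` (total schedule length in seconds).
#' @examples
#' sch <- build_schedule(default_stimulus_battery(), 10, 4, 180, order_seed = 1)
#' schedule_stimulation_time(sch)  # 80 s per stimulus
#' @export
build_schedule <- function(specs, epoch_duration = 10, repeats = 4, isi = 180,
                           order_seed = NULL) {
  if (length(specs) == 0L) stop_invalid("specs must contain at least one stimulus")
  if (inherits(specs, "stimulus_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), "stimulus_spec")
  if (!all(ok)) stop_invalid("specs must all be stimulus_spec objects")
  if (epoch_duration <= 0) stop_invalid("epoch_duration must be > 0")
  if (repeats < 1) stop_invalid("repeats must be >= 1")
  if (isi < 0) stop_invalid("isi must be >= 0")

  ord <- seq_along(specs)
  if (!is.null(order_seed))
    ord <- with_seed(order_seed, sample.int(length(specs)))
  specs <- specs[ord]

  block <- 2 * repeats * epoch_duration
  stimuli <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    onset <- (i - 1L) * (block + isi)
    epochs <- vector("list", 2L * repeats)
    for (j in seq_len(2L * repeats)) {
      dir <- if (j %% 2L == 1L) "LEFT" else "RIGHT"
      epochs[[j]] <- new_epoch(dir, onset + (j - 1L) * epoch_duration,
                               epoch_duration)
    }
    stimuli[[i]] <- list(spec = specs[[i]], onset = onset, epochs = epochs)
  }
  structure(list(stimuli = stimuli, epoch_duration = epoch_duration,
                 repeats = repeats, isi = isi, order_seed = order_seed,
                 duration = length(specs) * block +
                   max(0L, length(specs) - 1L) * isi),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("<schedule> %d stimuli, %d x (L+R) epochs of %g s, ISI %g s, total %g s\n",
              length(x$stimuli), x$repeats, x$epoch_duration, x$isi, x$duration))
  invisible(x)
}

#' Stimulation time per stimulus
#'
#' @param schedule a [build_schedule()] object.
#' @return seconds of grating motion delivered per stimulus
#'   (`repeats * 2 * epoch_duration`).
#' @export
schedule_stimulation_time <- function(schedule) {
  stopifnot(inherits(schedule, "schedule"))
  schedule$repeats * 2 * schedule$epoch_duration
}

#' Write / read a schedule as a plain-text YAML config
#'
#' @param schedule a `schedule` object.
#' @param path file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   the reconstructed `schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "schedule"))
  cfg <- list(
    epoch_duration = schedule$epoch_duration,
    repeats = schedule$repeats,
    isi = schedule$isi,
    order_seed = schedule$order_seed,
    stimuli = lapply(schedule$stimuli, function(s)
      list(label = s$spec$label,
           spatial_frequency = s$spec$spatial_frequency,
           temporal_frequency = s$spec$temporal_frequency,
           static = s$spec$static)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(cfg$stimuli, function(s)
    stimulus_spec(s$spatial_frequency, s$temporal_frequency, s$label,
                  isTRUE(s$static)))
  # Order in the file is the realized presentation order; don't re-permute.
  sch <- build_schedule(specs, cfg$epoch_duration, cfg$repeats, cfg$isi,
                        order_seed = NULL)
  sch$order_seed <- cfg$order_seed
  sch
}
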