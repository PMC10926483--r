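# Ground-truthed synthetic trackball trajectories. A simple kinematic model
# of a tethered walker under rotational optic flow: per frame the heading
# increment is stimulus-following turning (gain, after a reaction latency)
# plus a direction-independent turn bias plus Gaussian rotational noise,
# integrated by Euler steps at the frame rate; forward walking turns the ball
# about its pitch axis at a rate set by the walking pace. Cohorts mix three
# behavioral archetypes in treatment-dependent proportions:
#   FOLLOWER      robust, symmetric stimulus-following responses
#   BIASED_TURNER fast, strongly one-sided turning regardless of stimulus
#   SHALLOW_WALKER low-magnitude responses, mostly forward walking

#' Archetype generative parameters
#'
#' @param name one of `"FOLLOWER"`, `"BIASED_TURNER"`, `"SHALLOW_WALKER"`,
#'   or any label for a custom archetype.
#' @param optomotor_gain stimulus-following turning rate in rad/s.
#' @param reaction_latency delay (s) before the heading follows a direction
#'   switch; implemented as a pure delay of the direction signal.
#' @param bias_rate direction-independent turning rate in rad/s (signed;
#'   positive = leftward).
#' @param forward_pace forward walking pace in cm/s.
#' @param rotational_noise_sd rotational noise intensity in rad per sqrt(s);
#'   per-frame noise scales with sqrt(dt) so feature statistics are
#'   frame-rate-invariant.
#' @return an object of class `archetype_params`.
#' @export
archetype_params <- function(name, optomotor_gain, reaction_latency = 0,
                             bias_rate = 0, forward_pace = 1,
                             rotational_noise_sd = 0) {
  if (reaction_latency < 0) stop_invalid("reaction_latency must be >= 0")
  if (forward_pace < 0) stop_invalid("forward_pace must be >= 0")
  if (rotational_noise_sd < 0) stop_invalid("rotational_noise_sd must be >= 0")
  structure(list(name = name, optomotor_gain = optomotor_gain,
                 reaction_latency = reaction_latency, bias_rate = bias_rate,
                 forward_pace = forward_pace,
                 rotational_noise_sd = rotational_noise_sd),
            class = "archetype_params")
}

#' Default archetype parameter sets
#'
#' Free synthetic choices tuned so the three archetypes are separable at the
#' level of the five response features while showing realistic within-type
#' noise; see the methods vignette for the rationale behind each value.
#'
#' @return named list of three [archetype_params()].
#' @export
default_archetypes <- function() {
  list(
    FOLLOWER = archetype_params("FOLLOWER", optomotor_gain = 0.5,
                                reaction_latency = 0.5, bias_rate = 0.02,
                                forward_pace = 1.0, rotational_noise_sd = 0.15),
    BIASED_TURNER = archetype_params("BIASED_TURNER", optomotor_gain = 0.1,
                                     reaction_latency = 1.0, bias_rate = 0.6,
                                     forward_pace = 2.5,
                                     rotational_noise_sd = 0.2),
    SHALLOW_WALKER = archetype_params("SHALLOW_WALKER", optomotor_gain = 0.04,
                                      reaction_latency = 1.5, bias_rate = 0.06,
                                      forward_pace = 0.8,
                                      rotational_noise_sd = 0.12))
}

# Direction sign over a time grid: +1 during LEFT epochs, -1 during RIGHT,
# 0 between stimuli and during static-grating stimuli.
schedule_direction_signal <- function(times, schedule, t0) {
  s <- numeric(length(times))
  for (st in schedule$stimuli) {
    if (isTRUE(st$spec$static)) next
    for (ep in st$epochs) {
      lo <- t0 + ep$onset
      inside <- times >= lo & times < lo + ep$duration
      s[inside] <- if (ep$direction == "LEFT") 1 else -1
    }
  }
  s
}

#' Simulate a trackball trajectory
#'
#' Euler-integrates the kinematic archetype model over a stimulation
#' schedule. The heading increment per frame is
#' `(sign(t - latency) * gain + bias) * dt + noise_sd * sqrt(dt) * N(0,1)`,
#' where `sign` follows the schedule's epochs (leftward positive, 0 outside
#' stimulation); forward walking adds a pitch-axis ball rotation of
#' `pace / radius` rad/s.
#'
#' @param params an [archetype_params()].
#' @param schedule a [build_schedule()] object.
#' @param frame_rate camera frame rate in Hz.
#' @param ball_diameter ball diameter in cm.
#' @param seed integer seed.
#' @param t0 lead-in (s) before schedule time 0.
#' @param tail extra recording (s) after the schedule ends.
#' @return a [trajectory()] with attributes `t0` (the true alignment offset)
#'   and `archetype` (the params used).
#' @export
simulate_trajectory <- function(params, schedule, frame_rate = 50,
                                ball_diameter = 5, seed = NULL, t0 = 2,
                                tail = 2) {
  stopifnot(inherits(params, "archetype_params"),
            inherits(schedule, "schedule"))
  if (frame_rate <= 0) stop_invalid("frame_rate must be > 0")
  dt <- 1 / frame_rate
  n <- ceiling((t0 + schedule$duration + tail) * frame_rate) + 1L
  times <- (seq_len(n) - 1L) * dt
  s <- schedule_direction_signal(times - params$reaction_latency, schedule, t0)
  noise <- with_seed(seed, stats::rnorm(n, 0, params$rotational_noise_sd)) *
    sqrt(dt)
  dtheta <- (s * params$optomotor_gain + params$bias_rate) * dt + noise
  dtheta[1L] <- 0
  heading <- cumsum(dtheta)
  r <- ball_diameter / 2
  pitch <- rep(params$forward_pace / r * dt, n)
  pitch[1L] <- 0
  delta_rot <- cbind(pitch, 0, dtheta)
  colnames(delta_rot) <- NULL
  traj <- trajectory(time = times, heading = heading, delta_rot = delta_rot,
                     frame_index = seq_len(n), ball_diameter = ball_diameter,
                     frame_rate = frame_rate)
  attr(traj, "t0") <- t0
  attr(traj, "archetype") <- params
  traj
}

#' Describe a synthetic cohort
#'
#' @param treatments character vector of treatment labels.
#' @param n_animals integer vector, animals per treatment (recycled).
#' @param mixtures numeric matrix, one row per treatment and one column per
#'   archetype in `archetypes`, each row summing to 1: the probability that
#'   an animal of that treatment expresses each archetype.
#' @param schedule a [build_schedule()] object.
#' @param archetypes named list of [archetype_params()]
#'   (default [default_archetypes()]).
#' @param seed integer root seed for the whole cohort.
#' @param frame_rate,ball_diameter recording parameters.
#' @param param_cv coefficient of variation of the per-animal lognormal
#'   jitter applied to gain, bias magnitude and pace (biological
#'   between-animal variability); bias sign is drawn at random per animal.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(treatments, n_animals, mixtures, schedule,
                          archetypes = default_archetypes(), seed = 1,
                          frame_rate = 50, ball_diameter = 5,
                          param_cv = 0.12) {
  mixtures <- as.matrix(mixtures)
  if (nrow(mixtures) != length(treatments))
    stop_invalid("mixtures must have one row per treatment")
  if (ncol(mixtures) != length(archetypes))
    stop_invalid("mixtures must have one column per archetype")
  if (any(abs(rowSums(mixtures) - 1) > 1e-8))
    stop_invalid("each mixture row must sum to 1")
  n_animals <- rep_len(n_animals, length(treatments))
  structure(list(treatments = treatments, n_animals = n_animals,
                 mixtures = mixtures, schedule = schedule,
                 archetypes = archetypes, seed = seed,
                 frame_rate = frame_rate, ball_diameter = ball_diameter,
                 param_cv = param_cv),
            class = "cohort_design")
}

#' Default cohort design
#'
#' A four-treatment cohort (one control, three chronic-exposure groups with
#' animal counts 22/25/28/25) over the default 12-stimulus battery. The
#' control group is dominated by the FOLLOWER archetype while exposed groups
#' carry elevated BIASED_TURNER and SHALLOW_WALKER proportions across
#' stimuli. The mixture probabilities are synthetic choices that qualitatively
#' reproduce that pattern, not measured values.
#'
#' @param seed root seed recorded in the design.
#' @return a [cohort_design()].
#' @export
default_design <- function(seed = 20220901) {
  treatments <- c("CTL", "IMD", "SFX", "MIX")
  mixtures <- rbind(
    CTL = c(0.70, 0.15, 0.15),
    IMD = c(0.25, 0.40, 0.35),
    SFX = c(0.20, 0.45, 0.35),
    MIX = c(0.20, 0.40, 0.40))
  colnames(mixtures) <- names(default_archetypes())
  sch <- build_schedule(default_stimulus_battery(), epoch_duration = 10,
                        repeats = 4, isi = 180,
                        order_seed = derive_seed(seed, 7L))
  cohort_design(treatments, n_animals = c(22L, 25L, 28L, 25L),
                mixtures = mixtures, schedule = sch, seed = seed)
}

# Draw one animal: archetype assignment plus jittered parameters.
draw_animal <- function(design, treatment_idx, animal_seed) {
  with_seed(animal_seed, {
    arch_idx <- sample.int(ncol(design$mixtures), 1L,
                           prob = design$mixtures[treatment_idx, ])
    base <- design$archetypes[[arch_idx]]
    cv <- design$param_cv
    jit <- function(x) x * exp(stats::rnorm(1L, 0, cv))
    sgn <- sample(c(-1, 1), 1L)
    params <- archetype_params(
      base$name,
      optomotor_gain = jit(base$optomotor_gain),
      reaction_latency = base$reaction_latency * exp(stats::rnorm(1L, 0, cv)),
      bias_rate = sgn * jit(abs(base$bias_rate)),
      forward_pace = jit(base$forward_pace),
      rotational_noise_sd = base$rotational_noise_sd)
    list(archetype = base$name, params = params)
  })
}

#' Simulate a cohort of trackball trajectories
#'
#' Draws an archetype and jittered parameters for every animal, simulates its
#' trajectory, and either returns the trajectories in memory or writes one
#' FicTrac v2 .dat file per animal plus metadata, ground-truth label and
#' schedule files under `dir`. Byte-identical output for a fixed design seed.
#'
#' @param design a [cohort_design()].
#' @param dir output directory; `NULL` (default) keeps everything in memory.
#' @return list with `metadata` (data.frame: `animal_id`, `treatment`, `t0`,
#'   `file`), `labels` (data.frame: `animal_id`, `archetype`), `schedule`,
#'   and (when `dir` is `NULL`) `trajectories` (named list).
#' @export
simulate_cohort <- function(design, dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(); labels <- list(); trajs <- list()
  idx <- 0L
  for (ti in seq_along(design$treatments)) {
    for (ai in seq_len(design$n_animals[ti])) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", design$treatments[ti], ai)
      animal <- draw_animal(design, ti, derive_seed(design$seed, 10L * idx))
      traj <- simulate_trajectory(animal$params, design$schedule,
                                  frame_rate = design$frame_rate,
                                  ball_diameter = design$ball_diameter,
                                  seed = derive_seed(design$seed,
                                                     10L * idx + 1L))
      t0 <- attr(traj, "t0")
      file <- NA_character_
      if (!is.null(dir)) {
        file <- file.path(dir, paste0(id, ".dat"))
        write_trackball_log(traj, file)
      } else {
        trajs[[id]] <- traj
      }
      meta[[idx]] <- data.frame(animal_id = id,
                                treatment = design$treatments[ti],
                                t0 = t0, file = file,
                                stringsAsFactors = FALSE)
      labels[[idx]] <- data.frame(animal_id = id,
                                  archetype = animal$archetype,
                                  stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  labels <- do.call(rbind, labels)
  if (!is.null(dir)) {
    utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    write_schedule(design$schedule, file.path(dir, "schedule.yaml"))
  }
  out <- list(metadata = metadata, labels = labels,
              schedule = design$schedule)
  if (is.null(dir)) out$trajectories <- trajs
  out
}

#' Cohort feature table
#'
#' Simulates every animal in the design and extracts its response features,
#' holding only one trajectory in memory at a time. The returned table is the
#' direct input to [zscore_features()] and [select_k()].
#'
#' @param design a [cohort_design()].
#' @return data.frame: one row per animal-stimulus response, the
#'   [extract_features()] columns plus `treatment` and `archetype`.
#' @export
cohort_features <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  rows <- list(); idx <- 0L
  for (ti in seq_along(design$treatments)) {
    for (ai in seq_len(design$n_animals[ti])) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", design$treatments[ti], ai)
      animal <- draw_animal(design, ti, derive_seed(design$seed, 10L * idx))
      traj <- simulate_trajectory(animal$params, design$schedule,
                                  frame_rate = design$frame_rate,
                                  ball_diameter = design$ball_diameter,
                                  seed = derive_seed(design$seed,
                                                     10L * idx + 1L))
      ft <- extract_features(traj, design$schedule, t0 = attr(traj, "t0"),
                             animal_id = id)
      ft$treatment <- design$treatments[ti]
      ft$archetype <- animal$archetype
      rows[[idx]] <- ft
    }
  }
  do.call(rbind, rows)
}
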