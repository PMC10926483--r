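# Shared fixtures, built in code at test time.

# One-stimulus schedule with the standard 4 x (10 s L + 10 s R) protocol.
standard_schedule <- function(isi = 180) {
  build_schedule(list(stimulus_spec(0.0625, 16)), epoch_duration = 10,
                 repeats = 4, isi = isi)
}

# A replicate path from explicit slope over a 10-s epoch.
linear_path <- function(slope, direction = "LEFT", n = 101, noise = 0,
                        seed = NULL) {
  t <- seq(0, 10, length.out = n)
  y <- slope * t
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(n, 0, noise)
    y <- y - y[1L]
  }
  structure(list(t = t, y = y, direction = direction),
            class = "replicate_path")
}

# Eight replicate paths with given per-direction slopes (leftward-positive y).
eight_paths <- function(slope_left, slope_right) {
  c(lapply(1:4, function(i) linear_path(slope_left, "LEFT")),
    lapply(1:4, function(i) linear_path(slope_right, "RIGHT")))
}

# Independent OLS oracle: solve the normal equations directly.
ols_oracle <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- X %*% beta
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  list(slope = beta[2L], r_squared = 1 - sse / sst)
}

# Feature table of the default synthetic cohort, computed once per test run.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_features <- function() {
  if (is.null(.cohort_cache$ft))
    .cohort_cache$ft <- cohort_features(default_design())
  .cohort_cache$ft
}

# Small cohort for quick structural tests: 2 treatments x 3 animals x 2 stimuli.
tiny_design <- function(seed = 11) {
  sch <- build_schedule(list(stimulus_spec(0.0625, 16),
                             stimulus_spec(0.125, 16)),
                        epoch_duration = 10, repeats = 4, isi = 5)
  cohort_design(treatments = c("A", "B"), n_animals = 3,
                mixtures = rbind(c(0.8, 0.1, 0.1), c(0.1, 0.5, 0.4)),
                schedule = sch, seed = seed)
}
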