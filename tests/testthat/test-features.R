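make_segment <- function(heading, direction = "LEFT", t0 = 0, dt = 0.02,
                         delta_rot = NULL, ball_diameter = 5) {
  n <- length(heading)
  structure(list(spec = stimulus_spec(0.0625, 16), stimulus_index = 1L,
                 epoch = structure(list(direction = direction, onset = t0,
                                        duration = n * dt), class = "epoch"),
                 time = t0 + (0:(n - 1)) * dt, heading = heading,
                 delta_rot = delta_rot,
                 move_speed = if (is.null(delta_rot)) rep(NA_real_, n)
                              else sqrt(rowSums(delta_rot^2)),
                 ball_diameter = ball_diameter),
            class = "stimulus_segment")
}

test_that("segment_to_path re-zeroes and keeps the leftward-positive sign", {
  n <- 501
  t <- seq(0, 10, length.out = n)
  p0 <- segment_to_path(make_segment(rep(2.5, n)))
  expect_equal(p0$t[1], 0)
  expect_equal(p0$y, rep(0, n))          # constant heading -> no rotation
  pL <- segment_to_path(make_segment(1 + 0.5 * t, "LEFT", t0 = 30))
  expect_equal(pL$t[1], 0)
  expect_equal(max(pL$t), 10)
  expect_equal(pL$y[n], 5.0)             # +0.5 rad/s over 10 s
  pR <- segment_to_path(make_segment(-0.5 * t, "RIGHT"))
  expect_equal(pR$y[n], -5.0)            # rightward turning is negative
})

test_that("replicate fits match an independent normal-equations oracle", {
  exact <- fit_replicates(list(linear_path(0.5)))
  expect_equal(exact$slope, 0.5)
  expect_equal(exact$r_squared, 1)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    t <- sort(runif(n, 0, 10))
    y <- runif(1, -1, 1) * t + rnorm(n, 0, runif(1, 0.01, 2))
    p <- structure(list(t = t, y = y, direction = "LEFT"),
                   class = "replicate_path")
    f <- fit_replicates(list(p))
    o <- ols_oracle(t, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("pure noise around zero fits slope ~0 with R^2 ~0", {
  n <- 200
  t <- seq(0, 10, length.out = n)
  y <- rep_len(c(0.01, -0.01), n)
  f <- fit_replicates(list(structure(list(t = t, y = y, direction = "LEFT"),
                                     class = "replicate_path")))
  o <- ols_oracle(t, y)
  expect_equal(f$slope, o$slope, tolerance = 1e-12)
  expect_lt(abs(f$slope), 1e-4)
  expect_lt(f$r_squared, 0.01)
})

test_that("too-short paths are flagged invalid and excluded with a warning", {
  short <- structure(list(t = c(0, 1), y = c(0, 1), direction = "LEFT"),
                     class = "replicate_path")
  expect_warning(f <- fit_replicates(list(short, linear_path(0.5))),
                 "excluded")
  expect_equal(f$valid, c(FALSE, TRUE))
  expect_equal(turning_velocity(f), 0.5)
})

test_that("turning velocity averages signed slopes before the absolute value", {
  as_fits <- function(slopes)
    data.frame(direction = "LEFT", slope = slopes, r_squared = 1,
               n_points = 10, valid = TRUE)
  expect_equal(turning_velocity(as_fits(c(rep(0.5, 4), rep(-0.5, 4)))), 0)
  expect_equal(turning_velocity(as_fits(c(rep(0.5, 4), rep(-0.1, 4)))), 0.2)
  expect_equal(turning_velocity(as_fits(rep(0.3, 8))), 0.3)
  # invariant to replicate ordering
  s <- c(0.4, -0.2, 0.7, -0.6, 0.1, 0.3, -0.5, 0.2)
  expect_equal(turning_velocity(as_fits(s)),
               turning_velocity(as_fits(rev(s))))
})

test_that("tortuosity is the mean replicate R^2", {
  as_fits <- function(r2)
    data.frame(direction = "LEFT", slope = 1, r_squared = r2,
               n_points = 10, valid = TRUE)
  expect_equal(tortuosity(as_fits(rep(1, 8))), 1)
  expect_equal(tortuosity(as_fits(c(1, 1, 1, 1, 0, 0, 0, 0))), 0.5)
  expect_equal(tortuosity(as_fits(0.7)), 0.7)
})

test_that("rotation asymmetry follows the y.sym definition", {
  # symmetric: both direction averages 2.0
  sym <- rotation_asymmetry(eight_paths(0.2, -0.2))
  expect_equal(sym$ymax_left, sym$ymax_right)
  expect_equal(sym$y_sym, 0)
  expect_equal(sym$bias_direction, "NONE")
  # ymax_r = 3, ymax_l = 1 -> |3-1|/3 = 2/3
  asym <- rotation_asymmetry(eight_paths(0.1, -0.3))
  expect_equal(asym$ymax_left, 1)
  expect_equal(asym$ymax_right, 3)
  expect_equal(asym$y_sym, 2 / 3)
  expect_equal(asym$bias_direction, "RIGHT")
  expect_equal(asym$ymax, 2)
  # fully one-sided
  onesided <- rotation_asymmetry(eight_paths(0, -0.2))
  expect_equal(onesided$y_sym, 1)
  expect_equal(onesided$bias_direction, "RIGHT")
  # both-directions-zero degenerate case
  degen <- rotation_asymmetry(eight_paths(0, 0))
  expect_equal(degen$y_sym, 0)
  expect_true(degen$degenerate)
  expect_error(rotation_asymmetry(lapply(1:4, function(i) linear_path(0.1))),
               "both LEFT and RIGHT")
})

test_that("y.sym stays in [0,1] with the boundary cases it should have", {
  set.seed(3)
  for (i in 1:50) {
    sl <- runif(1, 0, 1); sr <- -runif(1, 0, 1)
    r <- rotation_asymmetry(eight_paths(sl, sr))
    expect_gte(r$y_sym, 0); expect_lte(r$y_sym, 1)
    expect_equal(r$y_sym == 0, r$ymax_right == r$ymax_left)
    expect_equal(r$y_sym == 1, min(r$ymax_right, r$ymax_left) == 0 &&
                   max(r$ymax_right, r$ymax_left) > 0)
  }
})

test_that("mirror reflection swaps direction averages but not the features", {
  set.seed(9)
  paths <- c(lapply(1:4, function(i) linear_path(runif(1, 0, 0.5), "LEFT",
                                                 noise = 0.2, seed = i)),
             lapply(1:4, function(i) linear_path(-runif(1, 0, 0.5), "RIGHT",
                                                 noise = 0.2, seed = 10 + i)))
  mirror <- lapply(paths, function(p)
    structure(list(t = p$t, y = -p$y,
                   direction = if (p$direction == "LEFT") "RIGHT" else "LEFT"),
              class = "replicate_path"))
  a <- rotation_asymmetry(paths); b <- rotation_asymmetry(mirror)
  expect_equal(b$ymax_left, a$ymax_right)
  expect_equal(b$ymax_right, a$ymax_left)
  expect_equal(b$y_sym, a$y_sym)
  expect_equal(b$bias_direction,
               c(LEFT = "RIGHT", RIGHT = "LEFT", NONE = "NONE")[[a$bias_direction]])
  fa <- fit_replicates(paths); fb <- fit_replicates(mirror)
  expect_equal(turning_velocity(fb), turning_velocity(fa))
  expect_equal(tortuosity(fb), tortuosity(fa))
})

test_that("walking pace follows the arc-length arithmetic", {
  n <- 300  # 10 s at 30 fps, constant 0.1 rad total rotation per frame
  rot <- cbind(rep(0.1, n), 0, 0)
  seg <- make_segment(rep(0, n), dt = 1 / 30, delta_rot = rot,
                      ball_diameter = 5)
  expect_equal(walking_pace(list(seg)), 0.1 * 30 * 2.5)
  # doubling the diameter doubles the pace
  seg10 <- make_segment(rep(0, n), dt = 1 / 30, delta_rot = rot,
                        ball_diameter = 10)
  expect_equal(walking_pace(list(seg10)), 2 * walking_pace(list(seg)))
  # stationary ball
  still <- make_segment(rep(0, n), dt = 1 / 30,
                        delta_rot = matrix(0, n, 3))
  expect_equal(walking_pace(list(still)), 0)
})

test_that("extract_features counts stimuli and matches generator ground truth", {
  sch <- build_schedule(default_stimulus_battery(), 10, 4, isi = 5,
                        order_seed = 2)
  follower <- archetype_params("F", optomotor_gain = 0.5)
  trf <- simulate_trajectory(follower, sch, seed = 1)
  ftf <- extract_features(trf, sch, t0 = attr(trf, "t0"), animal_id = "f1")
  expect_equal(nrow(ftf), 12L)
  expect_true(all(ftf$rotation_asymmetry < 0.01))
  expect_true(all(ftf$tortuosity > 0.99))
  expect_true(all(ftf$abs_turning_velocity < 1e-8))

  turner <- archetype_params("T", optomotor_gain = 0, bias_rate = 0.8)
  trt <- simulate_trajectory(turner, sch, seed = 2)
  ftt <- extract_features(trt, sch, t0 = attr(trt, "t0"), animal_id = "t1")
  expect_true(all(ftt$rotation_asymmetry > 0.99))
  expect_true(all(abs(ftt$abs_turning_velocity - 0.8) < 1e-6))
  expect_true(all(ftt$bias_direction == "LEFT"))
})
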