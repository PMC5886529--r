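test_that("time normalization interpolates onto 101 points exactly", {
  # already-uniform 101 samples pass through unchanged
  t <- seq(0, 600, length.out = 101)
  x <- rnorm(101)
  expect_equal(normalize_time(t, x), x)
  # constant position
  expect_equal(normalize_time(c(0, 10, 400), rep(2.5, 3)), rep(2.5, 101))
  # interpolation is exact on affine functions
  t51 <- seq(0, 500, length.out = 51)
  expect_equal(normalize_time(t51, 0.02 * t51 - 1),
               0.02 * seq(0, 500, length.out = 101) - 1)
  expect_error(normalize_time(5, 1), "at least 2")
  expect_error(normalize_time(c(0, 10, 10), 1:3), "strictly increasing")
})

test_that("correct-trial rule needs a majority of points plus the endpoint", {
  all_right <- rep(5, 101)
  expect_true(classify_correct(all_right, "right"))
  expect_false(classify_correct(all_right, "left"))
  # endpoint clause dominates
  endpoint_wrong <- c(rep(5, 100), -1)
  expect_false(classify_correct(endpoint_wrong, "right"))
  # 50 points on the correct side, 51 wrong incl. endpoint: 50/101 < 50%
  split_traj <- c(rep(1, 50), rep(-1, 51))
  expect_false(classify_correct(split_traj, "right"))
  # 51 correct-side points incl. endpoint pass (>= 50%)
  split_ok <- c(rep(-1, 50), rep(1, 51))
  expect_true(classify_correct(split_ok, "right"))
})

test_that("RT adds non-decision time to the 0.28 mm displacement onset", {
  t_ms <- 0:500
  # crosses 0.28 mm cumulative displacement at tick 120
  x <- c(rep(0, 120), seq(0.028, by = 0.028, length.out = 381))
  z <- rep(29, 501)
  rt <- compute_rt(t_ms, x, z, ndt_ms = 300)
  expect_true(rt$moved)
  expect_equal(rt$rt_ms, 120 + 300)
  # immobile trajectory flagged
  still <- compute_rt(t_ms, rep(0, 501), z)
  expect_false(still$moved)
  expect_true(is.na(still$rt_ms))
  # displacement is Euclidean over both axes
  rt_depth <- compute_rt(0:10, rep(0, 11), 29 - 0.01 * (0:10), ndt_ms = 200)
  expect_equal(rt_depth$rt_ms, 3 + 200)
})

test_that("RT shortens as a constant certainty weight grows", {
  onset_time <- function(w, tf = 0.6, dt = 1e-3) {
    state <- matrix(0, 3, 2)
    disp <- 0
    prev <- state[1, ]
    for (k in seq_len(round(tf / dt))) {
      state <- controller_step(state, c(10, 29), w, dt, tf - (k - 1) * dt, dt)
      disp <- disp + sqrt(sum((state[1, ] - prev)^2))
      prev <- state[1, ]
      if (disp >= 0.028) return(k)
    }
    Inf
  }
  onsets <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), onset_time, numeric(1))
  expect_true(all(diff(onsets) < 0))
})

test_that("changes of mind are counted from opposite-side excursions", {
  expect_equal(detect_changes_of_mind(seq(0, 10, length.out = 101), TRUE)$count, 0)
  # one 1.5 cm wrong-side dip then to target: one corrective event
  x1 <- c(seq(0, -1.5, length.out = 20), seq(-1.5, 10, length.out = 81))
  com1 <- detect_changes_of_mind(x1, correct = TRUE)
  expect_equal(com1$count, 1)
  expect_equal(com1$directions, "incorrect_to_correct")
  # sub-criterion dip does not count
  x_small <- c(seq(0, -0.8, length.out = 20), seq(-0.8, 10, length.out = 81))
  expect_equal(detect_changes_of_mind(x_small, TRUE)$count, 0)
  # double change of mind: two opposite-side excursions
  x2 <- c(seq(0, -1.5, length.out = 15), seq(-1.5, 2, length.out = 15),
          seq(2, -1.2, length.out = 15), seq(-1.2, 10, length.out = 56))
  expect_equal(detect_changes_of_mind(x2, TRUE)$count, 2)
  # wrong-side endpoint: the excursion is a correct-to-incorrect change
  x3 <- c(seq(0, 1.5, length.out = 30), seq(1.5, -10, length.out = 71))
  expect_equal(detect_changes_of_mind(x3, correct = FALSE)$directions,
               "correct_to_incorrect")
})

test_that("change-of-mind counts survive time normalization", {
  set.seed(19)
  p <- com_rich_params()
  for (i in 1:8) {
    tr <- simulate_trial(p, stimulus_pair(9, 10), tf_s = 0.8)
    raw_count <- detect_changes_of_mind(tr$x_cm, tr$correct)$count
    norm_count <- detect_changes_of_mind(
      normalize_time(tr$t_ms, tr$x_cm), tr$correct)$count
    expect_equal(norm_count, raw_count)
  }
})

test_that("heading angle is 0 straight ahead, 90 sideways, 45 on a diagonal", {
  t <- 0:100
  expect_equal(heading_angle(t, rep(0, 101), 29 - 0.1 * t), 0)
  expect_equal(abs(heading_angle(t, 0.1 * t, rep(29, 101))), 90)
  expect_equal(heading_angle(t, 0.05 * t, 29 - 0.05 * t), 45)
  # sign points toward the chosen side for left reaches too
  expect_equal(heading_angle(t, -0.05 * t, 29 - 0.05 * t), 45)
  a <- heading_angle(c(0, 1, 2), c(0, 0, 0), c(29, 29, 29))
  expect_true(is.na(a))
})

test_that("flip-and-average mirrors left trials and is mirror-invariant", {
  p <- model_params()
  design <- small_design(n = 24, ratios = c(0.5, 0.9))
  ds <- simulate_block(p, design, seed = 13)
  fa <- flip_and_average(ds)
  # mirror the whole dataset: summaries unchanged
  ds_m <- ds
  ds_m$trajectories$x_cm <- -ds_m$trajectories$x_cm
  ds_m$norm <- -ds_m$norm
  ds_m$meta$correct_side <- c(left = "right", right = "left",
                              none = "none")[ds_m$meta$correct_side]
  ds_m$meta$choice <- c(left = "right", right = "left")[ds_m$meta$choice]
  fa_m <- flip_and_average(ds_m)
  expect_equal(fa$hp_cm, fa_m$hp_cm, tolerance = 1e-12)
  expect_equal(fa$accuracy, fa_m$accuracy)
  # hp is the mean of the mean trajectory
  expect_equal(fa$hp_cm[1], mean(fa$mean_trajectory[[1]]))
})

test_that("two exact mirror trials average to either one in the flipped frame", {
  t_s <- seq(0, 0.6, length.out = 101)
  base <- minjerk_closed_form(10, 0.6, t_s)
  depth <- 29 - minjerk_closed_form(29, 0.6, t_s)
  t_ms <- t_s * 1000
  traj <- dplyr::bind_rows(
    tibble::tibble(trial_id = 1L, t_ms = t_ms, x_cm = base, depth_cm = depth),
    tibble::tibble(trial_id = 2L, t_ms = t_ms, x_cm = -base, depth_cm = depth))
  meta <- tibble::tibble(trial_id = 1:2, ratio = 0.5,
                         n_left = c(1L, 2L), n_right = c(2L, 1L),
                         correct_side = c("right", "left"), tf_s = 0.6,
                         choice = c("right", "left"), correct = TRUE,
                         rt_ms = 350, responsive = TRUE)
  ds <- structure(list(trajectories = traj, meta = meta, norm = NULL),
                  class = "reach_dataset")
  fa <- flip_and_average(ds)
  # in the flipped frame the mean equals the right trial
  expect_equal(fa$mean_trajectory[[1]], base, tolerance = 1e-12)
  # straight min-jerk reaches: hp equals the closed-form profile mean
  expect_equal(fa$hp_cm, mean(base), tolerance = 1e-12)
  # the lift-off window drops the sub-criterion prefix
  lifted <- flip_and_average(ds, window = "liftoff")
  expect_equal(lifted$mean_trajectory[[1]], normalize_liftoff(t_ms, base, depth),
               tolerance = 1e-12)
})

test_that("pull-back exclusion removes depth reversals at the injected rate", {
  design <- synthetic_design(trials_per_subject = 100, ratios = c(0.5, 0.9),
                             pullback_rate = 0.1, com_rate = 0)
  ds <- generate_dataset(design, seed = 23, n_subjects = 2)
  ex <- exclude_pullbacks(ds)
  injected <- mean(ds$meta$pullback_injected)
  expect_equal(ex$dropout_rate, injected, tolerance = 0.05)
  # flagged trials really are the injected ones
  kept <- ex$dataset$meta
  expect_lt(mean(kept$pullback_injected), 0.02)
  # monotone depth is kept
  expect_gt(nrow(kept), 0)
})
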