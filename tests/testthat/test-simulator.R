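test_that("noise-free trials head deterministically to the correct target", {
  p <- model_params(omega = 0, D = 1)
  set.seed(1)
  tr <- simulate_trial(p, stimulus_pair(1, 10), tf_s = 0.6)
  expect_equal(tr$choice, "right")
  expect_true(tr$correct)
  # certainty rises monotonically, endpoint within 1% of the target
  expect_true(all(diff(tr$belief$certainty) >= 0))
  expect_lt(abs(tail(tr$x_cm, 1) - p$x_f_cm), 0.01 * p$x_f_cm)
  expect_equal(detect_changes_of_mind(tr$x_cm, tr$correct)$count, 0)
})

test_that("trials are mirror images under a correct-side flip at fixed seed", {
  p <- model_params()
  set.seed(77)
  tr_r <- simulate_trial(p, stimulus_pair(5, 10), tf_s = 0.6)
  set.seed(77)
  tr_l <- simulate_trial(p, stimulus_pair(10, 5), tf_s = 0.6)
  expect_equal(tr_l$x_cm, -tr_r$x_cm)
  expect_equal(tr_l$depth_cm, tr_r$depth_cm)
  expect_equal(tr_l$rt_ms, tr_r$rt_ms)
})

test_that("the effector is still before the first sample; tf < R is flagged", {
  p <- model_params(R_ms = 30)
  set.seed(2)
  tr <- simulate_trial(p, stimulus_pair(5, 10), tf_s = 0.6)
  # certainty is zero until the first sample arrives at R_ms
  pre <- tr$t_ms < 30
  expect_true(all(tr$x_cm[pre] == 0))
  expect_true(all(tr$depth_cm[pre] == p$start_depth_cm))
  # RT covers the pre-lift-off micro-motion: onset after the first sample
  expect_gt(tr$rt_ms, p$ndt_ms + 30)
  # a flight shorter than the sampling interval has no evidence at all
  set.seed(2)
  tr0 <- simulate_trial(p, stimulus_pair(5, 10), tf_s = 0.02)
  expect_true(tr0$no_evidence)
  expect_false(tr0$moved)
  expect_true(all(tr0$x_cm == 0))
  expect_true(all(tr0$norm101 == 0))
  expect_true(all(is.na(tr0$norm101_liftoff)))
})

test_that("ratio-1 trials tilt to one side per trial but not in the mean", {
  p <- model_params()
  design <- sim_design(ratios = 1, trials_per_ratio = 480,
                       tf_mean_s = 0.6, tf_sd_s = 0.05)
  ds <- simulate_block(p, design, seed = 5, keep_trajectories = FALSE)
  ends <- ds$norm[rowSums(is.na(ds$norm)) == 0, 101]  # trials that lifted off
  # single trials commit to a side (stochastic evidence is limited) ...
  expect_gt(mean(abs(ends) > 1), 0.6)
  expect_gt(mean(abs(ends)), 5)
  # ... but the signed mean over many trials is small relative to the
  # per-trial tilt
  expect_lt(abs(mean(ends)), 0.2 * mean(abs(ends)))
})

test_that("satisficing releases the brake so equal-count trials reach a target", {
  design <- sim_design(ratios = 1, trials_per_ratio = 120,
                       tf_mean_s = 0.6, tf_sd_s = 0.05)
  ends_for <- function(p) {
    ds <- simulate_block(p, design, seed = 5, keep_trajectories = FALSE)
    abs(ds$norm[rowSums(is.na(ds$norm)) == 0, 101])
  }
  plain <- ends_for(model_params())
  sat_time <- ends_for(model_params(satisficing = TRUE,
                                    satisficing_distance = "time"))
  # plain certainty weighting stalls partway on maximal uncertainty;
  # the satisficing exponent lets the reach settle onto the closest target
  expect_lt(mean(abs(plain - 10) < 1), 0.8)
  expect_gt(mean(abs(sat_time - 10) < 1), 0.95)
  # depth-measured distance weakens the brake monotonically too
  sat_depth <- ends_for(model_params(satisficing = TRUE,
                                     satisficing_distance = "depth"))
  expect_gte(mean(sat_depth), mean(plain))
})

test_that("accuracy falls and RT rises with numerical ratio", {
  p <- model_params()      # omega 0.17, D 0.06, R 30 ms, W 10
  design <- small_design(n = 160)
  ds <- simulate_block(p, design, seed = 4, keep_trajectories = FALSE)
  fa <- flip_and_average(ds, compute_com = FALSE)
  expect_true(all(diff(fa$accuracy) <= 0))
  expect_gt(fa$accuracy[1], fa$accuracy[5])
  expect_true(all(diff(fa$mean_rt_ms) > 0))
  expect_true(all(diff(fa$hp_cm) < 0))
})

test_that("threshold gating: zero gate matches threshold-free, large gates delay", {
  pair <- stimulus_pair(9, 10)
  p_free <- model_params()
  p_zero <- model_params(threshold = 0)
  set.seed(31)
  tr_a <- simulate_trial(p_free, pair, 0.6)
  set.seed(31)
  tr_b <- simulate_trial(p_zero, pair, 0.6)
  expect_identical(tr_a$x_cm, tr_b$x_cm)
  # a practically-zero gate is opened by any first sample: identical flight
  p_tiny <- model_params(threshold = 0.27)
  set.seed(31)
  tr_t <- simulate_trial(p_tiny, pair, 0.6)
  expect_identical(tr_t$x_cm, tr_a$x_cm)
  # a large gate waits for several samples before movement begins
  p_gate <- model_params(threshold = 8)
  set.seed(31)
  tr_c <- simulate_trial(p_gate, pair, 0.6)
  expect_gt(tr_c$gate_ms, 30)
  expect_gt(tr_c$rt_ms, tr_a$rt_ms)
  # unreachable gate: trial ends at rest, flagged non-responsive
  p_wall <- model_params(threshold = 1e5)
  set.seed(31)
  tr_d <- simulate_trial(p_wall, pair, 0.6)
  expect_false(tr_d$responsive)
  expect_true(all(tr_d$x_cm == 0))
})

test_that("a tiny gate blocks almost no trials (first-sample lift-off)", {
  # 5 vs 10 at omega 0.17: P(first sample <= 0.27) ~ 0.006, so >= 99% of
  # trials move on the first sample
  pair <- stimulus_pair(5, 10)
  set.seed(8)
  first <- sample_evidence(pair, 0.17, n = 4000)
  expect_lt(mean(abs(first) < 0.27), 0.01)
})

test_that("drift and collapsing bound follow their closed forms", {
  expect_equal(drift_for_ratio(1, 0.28), 0)
  expect_lt(drift_for_ratio(0.5, 5e3), 1e-4)
  # arithmetic oracle for the printed expression
  direct <- 1 - erfc(abs(0.1 - 1) / (sqrt(2) * 0.28 * sqrt(0.1^2 + 1)))
  expect_equal(drift_for_ratio(0.1, 0.28), direct, tolerance = 1e-12)
  expect_equal(collapsing_threshold(0.62, 3.56, 0), 0.62)
  expect_equal(collapsing_threshold(0.62, 0, 5), 0.62)
  expect_equal(collapsing_threshold(0.62, 3.56, 1), 0.62 / 2^3.56)
})

test_that("simulated blocks are reproducible and sized by the design", {
  p <- model_params()
  design <- small_design(n = 12)
  ds1 <- simulate_block(p, design, seed = 10)
  ds2 <- simulate_block(p, design, seed = 10)
  expect_identical(ds1$meta, ds2$meta)
  expect_identical(ds1$trajectories, ds2$trajectories)
  expect_equal(nrow(ds1$meta), 12 * 5)
  # counterbalanced sides
  expect_equal(sum(ds1$meta$correct_side == "left"),
               sum(ds1$meta$correct_side == "right"))
  # ratio-1 designs carry equal-count trials
  ds3 <- simulate_block(p, sim_design(ratios = c(0.5, 1),
                                      trials_per_ratio = 6), seed = 2)
  expect_true(all(ds3$meta$correct_side[ds3$meta$ratio == 1] == "none"))
})

test_that("integer pairs realize each task ratio exactly within 25 dots", {
  for (r in c(task_ratios, 1)) {
    pr <- pairs_for_ratio(r, 25)
    expect_true(all(pr[, "small"] / pr[, "large"] == r))
    expect_true(all(pr <= 25))
  }
  expect_equal(nrow(pairs_for_ratio(0.9, 25)), 2)  # (9,10), (18,20)
})
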