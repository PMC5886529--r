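test_that("stimulus pairs validate counts and derive ratio and side", {
  p <- stimulus_pair(5, 10)
  expect_equal(p$ratio, 0.5)
  expect_equal(p$correct_side, "right")
  expect_equal(stimulus_pair(10, 5)$correct_side, "left")
  expect_equal(stimulus_pair(7, 7)$correct_side, "none")
  expect_error(stimulus_pair(0, 5), "integers")
  expect_error(stimulus_pair(5, 26), "max_dots")
  expect_error(stimulus_pair(NaN, 5), "finite")
})

test_that("evidence samples follow the Weber-scaled normal", {
  pair <- stimulus_pair(5, 10)
  # zero noise: degenerate at the true difference
  expect_equal(sample_evidence(pair, omega = 0, n = 5), rep(5, 5))
  # equal counts: mean zero
  set.seed(11)
  s_eq <- sample_evidence(stimulus_pair(7, 7), omega = 0.3, n = 2e4)
  expect_lt(abs(mean(s_eq)), 0.05)
  # moments match mean |nL-nR| and sd omega*sqrt(nL^2+nR^2)
  set.seed(12)
  s <- sample_evidence(pair, omega = 0.17, n = 2e5)
  expect_equal(mean(s), 5, tolerance = 0.005)
  expect_equal(sd(s), 0.17 * sqrt(125), tolerance = 0.01)
})

test_that("streams arrive every R ms and respect bounds", {
  pair <- stimulus_pair(1, 10)
  st <- generate_stream(pair, 0.2, R_ms = 30, duration_ms = 600)
  expect_length(st$raw, 20)
  expect_equal(st$sample_times, 30 * (1:20))
  expect_length(generate_stream(pair, 0.2, 30, 29)$raw, 0)
  st0 <- generate_stream(pair, 0, 30, 600)
  expect_equal(st0$raw, rep(9, 20))
  expect_error(generate_stream(pair, 0.2, R_ms = 0.5, 600), "bounds")
  expect_error(generate_stream(pair, 0.2, R_ms = 101, 600), "bounds")
})

test_that("EMA filter matches the recursion and its limits", {
  expect_equal(apply_ema(c(3, -1, 4), D = 1), c(3, -1, 4))
  expect_equal(apply_ema(c(3, -1, 4), D = 0), c(3, 3, 3))
  # hand-unrolled: EMA(1) = 2, EMA(2) = 0.5*4 + 0.5*2 = 3
  expect_equal(apply_ema(c(2, 4), D = 0.5), c(2, 3))
  expect_equal(apply_ema(numeric(0), 0.5), numeric(0))
  expect_error(apply_ema(1:3, D = 1.5), "0, 1")
})

test_that("EMA is shift-equivariant and bounded by running extrema", {
  set.seed(42)
  for (D in c(0.06, 0.3, 0.8)) {
    raw <- rnorm(50)
    ema <- apply_ema(raw, D)
    expect_equal(apply_ema(raw + 2.5, D), ema + 2.5)
    run_min <- cummin(raw); run_max <- cummax(raw)
    expect_true(all(ema >= run_min - 1e-12 & ema <= run_max + 1e-12))
  }
})

test_that("predicted error rate matches the erfc form and its monotonicity", {
  expect_equal(predicted_error_rate(stimulus_pair(7, 7), omega = 0.3), 0.5)
  expect_lt(predicted_error_rate(n_left = 2, n_right = 4, omega = 1e-4), 1e-10)
  # independent high-precision evaluation of the closed form
  direct <- 0.5 * erfc(abs(1 - 10) / (0.17 * sqrt(2) * sqrt(1 + 100)))
  expect_equal(predicted_error_rate(n_left = 1, n_right = 10, omega = 0.17),
               direct, tolerance = 1e-12)
  # strictly decreasing in |nL - nR| at fixed norm; increasing in omega
  e1 <- predicted_error_rate(n_left = 3, n_right = 4, omega = 0.2)
  e2 <- predicted_error_rate(n_left = 1, n_right = 10, omega = 0.2)
  expect_gt(e1, e2)
  oms <- c(0.1, 0.2, 0.4, 0.8)
  errs <- predicted_error_rate(n_left = 5, n_right = 10, omega = oms)
  expect_true(all(diff(errs) > 0))
})

test_that("single-sample sign accuracy equals the psychometric prediction", {
  # the closed form is exactly the per-sample misclassification probability
  pair <- stimulus_pair(3, 4)
  omega <- 0.25
  set.seed(5)
  s <- sample_evidence(pair, omega, n = 5e4)
  emp_err <- mean(s < 0)
  pred <- predicted_error_rate(pair, omega)
  expect_lt(abs(emp_err - pred), 4 * sqrt(pred * (1 - pred) / 5e4))
})

test_that("Weber fit recovers a generating omega and flags degeneracy", {
  pairs <- data.frame(n_left = c(1, 1, 1, 3, 9), n_right = c(10, 4, 2, 4, 10))
  # exact self-consistency
  tab <- transform(pairs, accuracy = 1 - predicted_error_rate(
    omega = 0.2, n_left = n_left, n_right = n_right))
  fit <- fit_weber(tab)
  expect_equal(fit$omega, 0.2, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.9999)
  # single ratio is under-determined
  expect_error(fit_weber(data.frame(n_left = 1, n_right = 2, accuracy = 0.9)),
               "2 distinct ratios")
  # all-chance accuracies: degenerate
  chance <- transform(pairs, accuracy = 0.5)
  expect_warning(fit_c <- fit_weber(chance), "unbounded")
  expect_true(fit_c$degenerate)
})

test_that("Weber estimator recovers omega from binomial accuracies at study n", {
  # 22 subjects x 84 trials per ratio, generating omega 0.17
  pairs <- data.frame(n_left = c(1, 1, 1, 3, 9), n_right = c(10, 4, 2, 4, 10))
  n_per <- 22 * 84
  set.seed(202)
  est <- replicate(20, {
    acc <- rbinom(5, n_per, 1 - predicted_error_rate(
      omega = 0.17, n_left = pairs$n_left, n_right = pairs$n_right)) / n_per
    fit_weber(cbind(pairs, accuracy = acc))$omega
  })
  expect_lt(max(abs(est - 0.17)), 0.02)
})
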