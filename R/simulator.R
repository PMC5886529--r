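#' Threshold-free model parameters
#'
#' Bundles the free parameters of the certainty-weighted controller model:
#' sampling interval `R_ms`, memory decay `D`, likelihood noise variance `W`,
#' Weber fraction `omega`, non-decision time, an optional accumulation
#' threshold (0 or `NULL` means threshold-free), and the satisficing flag.
#'
#' @param R_ms evidence sampling interval, ms, in \[1, 100\].
#' @param D EMA memory decay in \[0, 1\].
#' @param W likelihood noise variance (> 0).
#' @param omega Weber fraction (> 0).
#' @param ndt_ms non-decision time, ms, in \[200, 500\].
#' @param threshold optional accumulation gate on the running sum of EMA
#'   samples, numerical-difference units (>= 0).
#' @param satisficing logical; use the satisficing weight
#'   `certainty^distance` instead of plain certainty.
#' @param satisficing_distance how the normalized distance in the
#'   satisficing exponent is measured: `"depth"` (distance of the effector
#'   to the screen; can stall when low certainty keeps the depth axis from
#'   progressing) or `"time"` (remaining movement-time fraction, which
#'   guarantees the brake releases by flight end).
#' @param x_f_cm magnitude of the lateral target position (cm).
#' @param start_depth_cm depth distance from start button to screen (cm).
#' @param dt integration step (s).
#' @return an object of class `model_params`.
#' @export
model_params <- function(R_ms = 30, D = 0.06, W = 10, omega = 0.17,
                         ndt_ms = 300, threshold = 0, satisficing = FALSE,
                         satisficing_distance = c("depth", "time"),
                         x_f_cm = 10, start_depth_cm = 29, dt = 0.001) {
  if (R_ms < 1 || R_ms > 100) stop("R_ms out of bounds [1, 100]", call. = FALSE)
  if (D < 0 || D > 1) stop("D out of bounds [0, 1]", call. = FALSE)
  if (W <= 0) stop("W must be > 0", call. = FALSE)
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  if (ndt_ms < 200 || ndt_ms > 500) stop("ndt_ms out of bounds [200, 500]", call. = FALSE)
  if (is.null(threshold)) threshold <- 0
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  structure(list(R_ms = R_ms, D = D, W = W, omega = omega, ndt_ms = ndt_ms,
                 threshold = threshold, satisficing = isTRUE(satisficing),
                 satisficing_distance = match.arg(satisficing_distance),
                 x_f_cm = x_f_cm, start_depth_cm = start_depth_cm, dt = dt),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> R = %g ms, D = %g, W = %g, omega = %g, ndt = %g ms%s%s\n",
    x$R_ms, x$D, x$W, x$omega, x$ndt_ms,
    if (x$threshold > 0) sprintf(", threshold = %g", x$threshold) else "",
    if (x$satisficing) ", satisficing" else ""))
  invisible(x)
}

frame_sign <- function(correct_side) {
  # correct-positive frame mapped to screen coordinates (x > 0 = right);
  # equal-count trials default to a left-positive frame
  switch(correct_side, right = 1, left = -1, none = -1)
}

#' Simulate one trial of the threshold-free (or gated) model
#'
#' Per millisecond tick: if a new evidence sample is due (every `R_ms`), a
#' Weber-noised sample is drawn, EMA-filtered, and the Gaussian belief over
#' the numerical difference updated; heading goes to the side with the
#' larger probability; the update weight is the entropy-based certainty (or
#' `certainty^distance` in satisficing mode); and the minimum-jerk feedback
#' controller takes one Euler step on both axes. The controller clock runs
#' from stimulus onset over the whole `tf_s` horizon: before the first
#' sample certainty is zero and the effector holds still, and the early
#' low-certainty ticks produce the pre-lift-off micro-motion that the
#' displacement-onset RT is built on. With `threshold > 0` motor updates
#' are blocked until the running sum of EMA samples reaches the threshold
#' (inference still sees pre-gate samples; a vanishing threshold is
#' continuous with the threshold-free model, since motion is gated by
#' evidence alone either way). Evidence is sampled from the internal
#' representation for the whole flight; the 200 ms stimulus visibility is
#' memory-sampling metadata, not a sampling cutoff.
#'
#' @param params a [model_params()].
#' @param pair a [stimulus_pair()].
#' @param tf_s total movement time (s).
#' @return an object of class `sim_trial`: stimulus, per-tick times (ms,
#'   from stimulus onset) and screen-frame positions (`x_cm`, right
#'   positive; `depth_cm`, distance to screen), the 101-point normalized
#'   lift-off-window positions `norm101`, the gate crossing time `gate_ms`
#'   (0 in threshold-free mode, `NA` if never crossed), belief series,
#'   choice, correctness, `rt_ms`, and flags.
#' @export
simulate_trial <- function(params, pair, tf_s) {
  stopifnot(inherits(params, "model_params"), inherits(pair, "stimulus_pair"),
            tf_s > 0)
  n_samp <- floor(tf_s * 1000 / params$R_ms)
  samples <- sample_evidence(pair, params$omega, n_samp)
  eng <- cpp_run_trial(samples, params$R_ms, params$D, params$W,
                       params$threshold, params$satisficing,
                       if (identical(params$satisficing_distance, "time")) 1L else 0L,
                       tf_s, params$dt,
                       params$x_f_cm, params$start_depth_cm, params$dt)
  fs <- frame_sign(pair$correct_side)
  x_cm <- fs * eng$x
  n_tick <- length(x_cm)
  t_ms <- (seq_len(n_tick) - 1) * params$dt * 1000
  choice <- if (x_cm[n_tick] >= 0) "right" else "left"
  correct <- if (pair$correct_side == "none") NA else choice == pair$correct_side
  moved <- !is.na(eng$onset_ms)
  structure(list(
    stimulus = pair, tf_s = tf_s, dt = params$dt,
    t_ms = t_ms, x_cm = x_cm, depth_cm = eng$depth,
    norm101 = fs * eng$norm101,
    norm101_liftoff = fs * eng$norm101_liftoff, gate_ms = eng$gate_ms,
    evidence = list(raw = samples,
                    sample_times = params$R_ms * seq_len(eng$n_samples)),
    belief = list(e_bar = eng$e_bar, p_correct = eng$p_correct,
                  certainty = eng$certainty, gate_sum = eng$gate_sum),
    choice = choice, correct = correct,
    rt_ms = if (moved) eng$onset_ms + params$ndt_ms else NA_real_,
    moved = moved, n_samples = eng$n_samples,
    no_evidence = eng$n_samples == 0,
    responsive = eng$gate_open && eng$n_samples > 0), class = "sim_trial")
}

# Minimal trial runner for block summaries: same RNG draws and engine call
# as simulate_trial, returning only what the analysis stage needs.
simulate_trial_lean <- function(params, pair, tf_s) {
  n_samp <- floor(tf_s * 1000 / params$R_ms)
  samples <- sample_evidence(pair, params$omega, n_samp)
  eng <- cpp_run_trial(samples, params$R_ms, params$D, params$W,
                       params$threshold, params$satisficing,
                       if (identical(params$satisficing_distance, "time")) 1L else 0L,
                       tf_s, params$dt,
                       params$x_f_cm, params$start_depth_cm, params$dt)
  fs <- frame_sign(pair$correct_side)
  endpoint <- fs * eng$x[length(eng$x)]
  choice <- if (endpoint >= 0) "right" else "left"
  correct <- if (pair$correct_side == "none") NA else choice == pair$correct_side
  moved <- !is.na(eng$onset_ms)
  list(tf_s = tf_s, norm101 = fs * eng$norm101,
       norm101_liftoff = fs * eng$norm101_liftoff, choice = choice,
       correct = correct,
       rt_ms = if (moved) eng$onset_ms + params$ndt_ms else NA_real_,
       responsive = eng$gate_open && eng$n_samples > 0)
}

#' @rdname simulate_trial
#' @details `simulate_trial_thresholded()` requires `params$threshold > 0`
#'   and is otherwise identical to `simulate_trial()` (which already honours
#'   a positive threshold).
#' @export
simulate_trial_thresholded <- function(params, pair, tf_s) {
  if (params$threshold <= 0) stop("params$threshold must be > 0", call. = FALSE)
  simulate_trial(params, pair, tf_s)
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf(
    "<sim_trial> %d vs %d, tf = %.3g s, choice = %s%s, rt = %s ms\n",
    x$stimulus$n_left, x$stimulus$n_right, x$tf_s, x$choice,
    if (is.na(x$correct)) "" else if (x$correct) " (correct)" else " (incorrect)",
    if (is.na(x$rt_ms)) "NA" else sprintf("%.0f", x$rt_ms)))
  invisible(x)
}

#' Drift of the collapsing-bound accumulator as a function of ratio
#'
#' `1 - erfc(|ratio - 1| / (sqrt(2) * dft * sqrt(ratio^2 + 1)))`: the
#' classic number-cognition mapping from numerical ratio to accumulation
#' drift. Zero at ratio 1; approaches 0 for any ratio as `dft` grows.
#'
#' @param ratio numerical ratio in (0, 1\].
#' @param dft drift scale parameter (> 0).
#' @return drift value (vectorized over `ratio`).
#' @export
drift_for_ratio <- function(ratio, dft) {
  stopifnot(all(ratio > 0), all(ratio <= 1), dft > 0)
  1 - erfc(abs(ratio - 1) / (sqrt(2) * dft * sqrt(ratio^2 + 1)))
}

#' Collapsing decision threshold
#'
#' `thr / (1 + t)^k`, evaluated every millisecond. By default `t` is in
#' seconds: with collapse rates of order 3-4 a per-millisecond time unit
#' would flatten the bound to ~0 within a few ms, which is incompatible with
#' the response-time structure the model is meant to produce; the
#' alternative unit remains available.
#'
#' @param thr initial threshold (> 0).
#' @param k collapse rate (>= 0).
#' @param t elapsed decision time (vectorized).
#' @param t_unit `"s"` or `"ms"`: unit in which `t` enters the collapse.
#' @return threshold value(s) at `t`.
#' @export
collapsing_threshold <- function(thr, k, t, t_unit = c("s", "ms")) {
  stopifnot(thr > 0, k >= 0, all(t >= 0))
  t_unit <- match.arg(t_unit)
  thr / (1 + t)^k
}

#' Collapsing-bound accumulator parameters
#'
#' @param thr initial decision threshold (> 0).
#' @param dft drift scale (see [drift_for_ratio()]).
#' @param sig2 per-sample evidence variance (> 0).
#' @param ndt_s non-decision time (s).
#' @param k threshold collapse rate (>= 0).
#' @param second_thr optional post-lift-off threshold for target flips.
#' @param deadline_ms optional post-lift-off accumulation deadline.
#' @param t_unit time unit entering the collapse (see
#'   [collapsing_threshold()]).
#' @param max_decision_ms give-up time for the decision stage.
#' @param x_f_cm,start_depth_cm,dt controller geometry and step, as in
#'   [model_params()].
#' @return an object of class `ddm_params`. Defaults are the best-fit values
#'   reported for this task (thr 0.62, dft 0.28, ndt 0.19 s, sig2 0.14,
#'   k 3.56).
#' @export
ddm_params <- function(thr = 0.62, dft = 0.28, sig2 = 0.14, ndt_s = 0.19,
                       k = 3.56, second_thr = NULL, deadline_ms = NULL,
                       t_unit = "s", max_decision_ms = 3000, x_f_cm = 10,
                       start_depth_cm = 29, dt = 0.001) {
  stopifnot(thr > 0, sig2 > 0, k >= 0, dft > 0)
  structure(list(thr = thr, dft = dft, sig2 = sig2, ndt_s = ndt_s, k = k,
                 second_thr = second_thr, deadline_ms = deadline_ms,
                 t_unit = match.arg(t_unit, c("s", "ms")),
                 max_decision_ms = max_decision_ms, x_f_cm = x_f_cm,
                 start_depth_cm = start_depth_cm, dt = dt),
            class = "ddm_params")
}

#' Simulate one trial of the traditional collapsing-bound model
#'
#' Evidence samples arrive every millisecond from
#' `N(drift_for_ratio(ratio, dft), sig2)` (variance `sig2`) in the
#' correct-side-positive frame and are summed until the magnitude of the
#' accumulation reaches the collapsing bound. RT is the crossing time plus
#' non-decision time. The controller then moves toward the crossing side
#' for `tf_s` seconds; sampling continues in flight and the certainty of the
#' two-hypothesis posterior weights every motor update. With `second_thr`
#' set, an opposing crossing flips the target in flight; with `deadline_ms`
#' set, accumulation stops at the deadline and the target with the highest
#' posterior is locked.
#'
#' @param ddm a [ddm_params()].
#' @param ratio numerical ratio in (0, 1\].
#' @param tf_s movement time after lift-off (s).
#' @param correct_side `"left"`, `"right"`, or `"none"` (ratio-1 trials).
#' @return a `sim_trial`-like object of class `ddm_trial`; non-crossing
#'   trials are flagged `responsive = FALSE`.
#' @export
simulate_ddm_trial <- function(ddm, ratio, tf_s, correct_side = "right") {
  stopifnot(inherits(ddm, "ddm_params"), ratio > 0, ratio <= 1, tf_s > 0)
  drift <- drift_for_ratio(ratio, ddm$dft)
  n_draw <- ddm$max_decision_ms + round(tf_s * 1000)
  samples <- rnorm(n_draw, mean = drift, sd = sqrt(ddm$sig2))
  eng <- cpp_run_ddm(samples, ddm$thr, ddm$k, ddm$t_unit == "s", drift,
                     ddm$sig2, tf_s, ddm$dt, ddm$x_f_cm, ddm$start_depth_cm,
                     ddm$dt, ddm$max_decision_ms,
                     if (is.null(ddm$second_thr)) NA_real_ else ddm$second_thr,
                     if (is.null(ddm$deadline_ms)) NA_real_ else ddm$deadline_ms)
  if (!eng$crossed) {
    return(structure(list(ratio = ratio, tf_s = tf_s, responsive = FALSE,
                          choice = NA_character_, correct = NA,
                          rt_ms = NA_real_, t_ms = numeric(0),
                          x_cm = numeric(0), depth_cm = numeric(0)),
                     class = "ddm_trial"))
  }
  fs <- frame_sign(correct_side)
  x_cm <- fs * eng$x
  n_tick <- length(x_cm)
  t_ms <- (seq_len(n_tick) - 1) * ddm$dt * 1000
  choice <- if (x_cm[n_tick] >= 0) "right" else "left"
  correct <- if (correct_side == "none") NA else choice == correct_side
  structure(list(ratio = ratio, tf_s = tf_s, responsive = TRUE,
                 cross_ms = eng$cross_ms,
                 cross_side = if (fs * eng$cross_sign >= 0) "right" else "left",
                 rt_ms = eng$cross_ms + ddm$ndt_s * 1000,
                 t_ms = t_ms, x_cm = x_cm, depth_cm = eng$depth,
                 choice = choice, correct = correct),
            class = "ddm_trial")
}

#' Experiment design for simulated blocks
#'
#' @param ratios numerical ratios used in the task.
#' @param trials_per_ratio trials per ratio (correct side counterbalanced).
#' @param tf_mean_s,tf_sd_s per-ratio movement-time lognormal moments
#'   (recycled to `length(ratios)`).
#' @param pair_mode `"sampled"` draws, per trial, a uniformly random integer
#'   pair realizing the ratio exactly within `max_dots`; `"fixed"` always
#'   uses the smallest such pair.
#' @param max_dots maximum dot count per side.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(ratios = c(0.1, 0.25, 0.5, 0.75, 0.9),
                       trials_per_ratio = 480,
                       tf_mean_s = 0.6, tf_sd_s = 0.1,
                       pair_mode = c("sampled", "fixed"), max_dots = 25) {
  stopifnot(all(ratios > 0), all(ratios <= 1), trials_per_ratio >= 1)
  structure(list(ratios = ratios, trials_per_ratio = trials_per_ratio,
                 tf_mean_s = rep_len(tf_mean_s, length(ratios)),
                 tf_sd_s = rep_len(tf_sd_s, length(ratios)),
                 pair_mode = match.arg(pair_mode), max_dots = max_dots),
            class = "sim_design")
}

#' Integer dot-count pairs realizing a ratio exactly
#'
#' @param ratio numerical ratio in (0, 1\].
#' @param max_dots maximum count per side.
#' @return two-column matrix (small count, large count), one row per pair.
#' @export
pairs_for_ratio <- function(ratio, max_dots = 25) {
  stopifnot(ratio > 0, ratio <= 1)
  fr <- as_small_fraction(ratio)
  k_max <- floor(max_dots / fr[2])
  if (k_max < 1) stop("no integer pair realizes this ratio within max_dots",
                      call. = FALSE)
  cbind(small = fr[1] * seq_len(k_max), large = fr[2] * seq_len(k_max))
}

as_small_fraction <- function(ratio, max_den = 100) {
  # smallest integer p/q equal to ratio to floating tolerance
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p >= 1 && abs(p / q - ratio) < 1e-9) return(c(p, q))
  }
  stop("ratio is not a small rational", call. = FALSE)
}

draw_pair <- function(ratio, design) {
  pr <- pairs_for_ratio(ratio, design$max_dots)
  row <- if (design$pair_mode == "fixed" || nrow(pr) == 1) 1 else
    sample.int(nrow(pr), 1)
  pr[row, ]
}

#' Lognormal movement-time sampler
#'
#' Draws a positive movement time from a lognormal with the configured
#' per-ratio mean and SD (moment-matched).
#'
#' @param ratio one of the design's ratios.
#' @param design a [sim_design()] (or `synthetic_design`).
#' @return movement time in seconds.
#' @export
tf_sampler <- function(ratio, design) {
  i <- match_ratio(ratio, design$ratios)
  m <- design$tf_mean_s[i]; s <- design$tf_sd_s[i]
  if (s <= 0) return(m)
  sdlog <- sqrt(log(1 + (s / m)^2))
  rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

match_ratio <- function(ratio, ratios) {
  i <- which(abs(ratios - ratio) < 1e-9)
  if (length(i) != 1) stop("ratio not in design", call. = FALSE)
  i
}

trial_seed <- function(master_seed, index) {
  # one RNG stream per trial so per-trial reproducibility survives
  # any execution order
  (as.integer(master_seed) %% 100000L) * 20011L + as.integer(index)
}

#' Simulate a block of trials
#'
#' Runs independent trials over the design grid with counterbalanced correct
#' sides. Each trial uses its own RNG stream derived from
#' `(seed, trial index)`, so the dataset is bit-reproducible and independent
#' of execution order.
#'
#' @param params a [model_params()] or [ddm_params()].
#' @param design a [sim_design()].
#' @param seed integer master seed.
#' @param keep_trajectories logical; if `FALSE` only per-trial summaries
#'   (normalized trajectory, choice, RT) are kept, which is much lighter for
#'   fitting loops.
#' @return a `reach_dataset`: list with `trajectories` (tibble `trial_id`,
#'   `t_ms`, `x_cm`, `depth_cm`; empty when `keep_trajectories = FALSE`),
#'   `meta` (one row per trial), and `norm` (101-point time-normalized
#'   horizontal positions, trials in rows).
#' @export
simulate_block <- function(params, design, seed = 1,
                           keep_trajectories = TRUE) {
  stopifnot(inherits(design, "sim_design"))
  grid <- expand_trials(design)
  n_tr <- nrow(grid)
  norm <- matrix(NA_real_, n_tr, 101)
  norm_lift <- matrix(NA_real_, n_tr, 101)
  n_left <- n_right <- rep(NA_integer_, n_tr)
  tf_s <- rt_ms <- rep(NA_real_, n_tr)
  choice <- rep(NA_character_, n_tr)
  correct <- rep(NA, n_tr)
  responsive <- rep(FALSE, n_tr)
  trajs <- if (keep_trajectories) vector("list", n_tr) else NULL
  is_ddm <- inherits(params, "ddm_params")
  for (i in seq_len(n_tr)) {
    set.seed(trial_seed(seed, i))
    tf <- tf_sampler(grid$ratio[i], design)
    if (is_ddm) {
      tr <- simulate_ddm_trial(params, grid$ratio[i], tf,
                               correct_side = grid$side[i])
    } else if (!keep_trajectories) {
      # lean path: identical RNG stream and results, but the engine's own
      # 101-point normalization and onset time are used and no per-tick
      # tibble is built
      pr <- draw_pair(grid$ratio[i], design)
      pair <- orient_pair(pr, grid$side[i])
      tr <- simulate_trial_lean(params, pair, tf)
      n_left[i] <- pair$n_left; n_right[i] <- pair$n_right
    } else {
      pr <- draw_pair(grid$ratio[i], design)
      pair <- orient_pair(pr, grid$side[i])
      tr <- simulate_trial(params, pair, tf)
      n_left[i] <- tr$stimulus$n_left; n_right[i] <- tr$stimulus$n_right
    }
    if (!is.null(tr$norm101)) {
      norm[i, ] <- tr$norm101
      norm_lift[i, ] <- tr$norm101_liftoff
    } else if (length(tr$x_cm) >= 2) {
      # recorded-style trajectories (the collapsing-bound model's movement
      # phase) already span lift-off to arrival
      norm[i, ] <- normalize_time(tr$t_ms, tr$x_cm)
      norm_lift[i, ] <- norm[i, ]
    }
    tf_s[i] <- tr$tf_s; rt_ms[i] <- tr$rt_ms
    choice[i] <- tr$choice
    correct[i] <- if (is.na(tr$correct)) NA else tr$correct
    responsive[i] <- isTRUE(tr$responsive)
    if (keep_trajectories && length(tr$x_cm) > 0) {
      trajs[[i]] <- data.frame(trial_id = i, t_ms = tr$t_ms,
                               x_cm = tr$x_cm, depth_cm = tr$depth_cm)
    }
  }
  meta <- tibble::tibble(trial_id = seq_len(n_tr), ratio = grid$ratio,
                         n_left = n_left, n_right = n_right,
                         correct_side = grid$side, tf_s = tf_s,
                         choice = choice, correct = correct, rt_ms = rt_ms,
                         responsive = responsive)
  structure(list(
    trajectories = if (keep_trajectories)
      tibble::as_tibble(do.call(rbind, trajs)) else
      tibble::tibble(trial_id = integer(), t_ms = numeric(),
                     x_cm = numeric(), depth_cm = numeric()),
    meta = meta, norm = norm, norm_liftoff = norm_lift,
    design = design, seed = seed), class = "reach_dataset")
}

expand_trials <- function(design) {
  out <- list()
  for (r in design$ratios) {
    n <- design$trials_per_ratio
    if (abs(r - 1) < 1e-9) {
      side <- rep("none", n)
    } else {
      side <- rep(c("left", "right"), length.out = n)
    }
    out[[length(out) + 1]] <- data.frame(ratio = r, side = side)
  }
  do.call(rbind, out)
}

orient_pair <- function(pr, side) {
  small <- min(pr); large <- max(pr)
  if (side == "right") stimulus_pair(small, large)
  else if (side == "left") stimulus_pair(large, small)
  else stimulus_pair(small, small)  # ratio-1 trial
}

#' @export
print.reach_dataset <- function(x, ...) {
  cat(sprintf("<reach_dataset> %d trials, %d ratios, seed %s\n",
              nrow(x$meta), length(unique(x$meta$ratio)),
              as.character(x$seed)))
  invisible(x)
}
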