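#' Design of a synthetic human-like dataset
#'
#' Mirrors the structure of the reaching study: 5 ratios, 420 trials per
#' subject equally divided among ratios, 22 subjects, per-ratio movement
#' time distributions, accuracy following the Weber psychometric model, and
#' configurable injection rates for changes of mind and pull-backs.
#'
#' @param ratios numerical ratios (optionally including 1.0).
#' @param trials_per_subject trials per subject; must be divisible by the
#'   number of ratios.
#' @param n_subjects number of simulated subjects.
#' @param tf_mean_s,tf_sd_s per-ratio movement-time moments (s), recycled.
#' @param omega_true generating Weber fraction.
#' @param com_rate probability of injecting one change-of-mind excursion.
#' @param pullback_rate probability of injecting a depth pull-back.
#' @param noise_cm SD of positional jitter added to each sample.
#' @param x_f_cm,start_depth_cm geometry (cm).
#' @param sample_hz sampling rate of the synthetic recordings (Hz).
#' @param max_dots maximum dot count per side.
#' @param pair_mode `"sampled"` or `"fixed"`, as in [sim_design()].
#' @return an object of class `synthetic_design` (also a `sim_design`).
#' @export
synthetic_design <- function(ratios = c(0.1, 0.25, 0.5, 0.75, 0.9),
                             trials_per_subject = 420, n_subjects = 22,
                             tf_mean_s = 0.6, tf_sd_s = 0.1,
                             omega_true = 0.17, com_rate = 0.03,
                             pullback_rate = 0.0766, noise_cm = 0.05,
                             x_f_cm = 10, start_depth_cm = 29,
                             sample_hz = 200, max_dots = 25,
                             pair_mode = c("sampled", "fixed")) {
  if (trials_per_subject %% length(ratios) != 0) {
    stop("trials_per_subject must be divisible by the number of ratios",
         call. = FALSE)
  }
  stopifnot(com_rate >= 0, com_rate <= 1, pullback_rate >= 0,
            pullback_rate <= 1)
  structure(list(ratios = ratios,
                 trials_per_ratio = trials_per_subject / length(ratios),
                 trials_per_subject = trials_per_subject,
                 n_subjects = n_subjects,
                 tf_mean_s = rep_len(tf_mean_s, length(ratios)),
                 tf_sd_s = rep_len(tf_sd_s, length(ratios)),
                 omega_true = omega_true, com_rate = com_rate,
                 pullback_rate = pullback_rate, noise_cm = noise_cm,
                 x_f_cm = x_f_cm, start_depth_cm = start_depth_cm,
                 sample_hz = sample_hz, max_dots = max_dots,
                 pair_mode = match.arg(pair_mode)),
            class = c("synthetic_design", "sim_design"))
}

#' Generate a synthetic trajectory dataset with known ground truth
#'
#' Generator-side construct, independent of the decision model: per trial
#' the chosen side is sampled from the psychometric accuracy
#' `1 - predicted_error_rate(omega_true)`, the movement time from the
#' per-ratio lognormal, and the path is a minimum-jerk reach toward the
#' chosen target with optional injected change-of-mind excursions,
#' depth pull-backs, and small positional jitter. The sidecar records every
#' latent (true side, injected events), so analysis code can be validated
#' against exact ground truth.
#'
#' @param design a [synthetic_design()].
#' @param seed integer master seed.
#' @param n_subjects optionally override the design's subject count.
#' @return a `reach_dataset` whose `meta` carries ground-truth columns
#'   `subject`, `com_injected`, `pullback_injected`.
#' @export
generate_dataset <- function(design, seed = 1,
                             n_subjects = design$n_subjects) {
  stopifnot(inherits(design, "synthetic_design"))
  n_per <- design$trials_per_ratio
  grid <- expand.grid(subject = seq_len(n_subjects),
                      ratio = design$ratios,
                      rep = seq_len(n_per))
  grid <- grid[order(grid$subject, grid$ratio, grid$rep), ]
  n_tr <- nrow(grid)
  norm <- matrix(NA_real_, n_tr, 101)
  n_left <- n_right <- rep(NA_integer_, n_tr)
  correct_side <- choice <- rep(NA_character_, n_tr)
  tf_s <- rt_ms <- rep(NA_real_, n_tr)
  correct <- com_inj <- pb_inj <- rep(NA, n_tr)
  trajs <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    set.seed(trial_seed(seed, i))
    r <- grid$ratio[i]
    equal <- abs(r - 1) < 1e-9
    pr <- draw_pair(r, design)
    cs <- if (equal) "none" else sample(c("left", "right"), 1)
    p_err <- if (equal) 0.5 else
      predicted_error_rate(omega = design$omega_true,
                           n_left = min(pr), n_right = max(pr))
    err <- runif(1) < p_err
    ch <- if (equal) sample(c("left", "right"), 1)
    else if (err) setdiff(c("left", "right"), cs)
    else cs
    tf <- tf_sampler(r, design)
    ci <- runif(1) < design$com_rate
    pi <- runif(1) < design$pullback_rate
    path <- synth_path(tf, ch, ci, pi, design)
    trajs[[i]] <- data.frame(trial_id = i, t_ms = path$t_ms,
                             x_cm = path$x_cm, depth_cm = path$depth_cm)
    norm[i, ] <- normalize_time(path$t_ms, path$x_cm)
    n_left[i] <- if (cs == "left") max(pr) else min(pr)
    n_right[i] <- if (cs == "left") min(pr) else max(pr)
    correct_side[i] <- cs; choice[i] <- ch
    correct[i] <- if (equal) NA else !err
    tf_s[i] <- tf; com_inj[i] <- ci; pb_inj[i] <- pi
    rt_ms[i] <- compute_rt(path$t_ms, path$x_cm, path$depth_cm,
                           ndt_ms = 300)$rt_ms
  }
  meta <- tibble::tibble(
    trial_id = seq_len(n_tr), subject = grid$subject, ratio = grid$ratio,
    n_left = n_left, n_right = n_right, correct_side = correct_side,
    tf_s = tf_s, choice = choice, correct = correct, rt_ms = rt_ms,
    responsive = TRUE, com_injected = com_inj, pullback_injected = pb_inj)
  structure(list(trajectories = tibble::as_tibble(do.call(rbind, trajs)),
                 meta = meta, norm = norm, norm_liftoff = norm,
                 design = design, seed = seed),
            class = "reach_dataset")
}

synth_path <- function(tf_s, choice, com_inj, pb_inj, design) {
  dt <- 1 / design$sample_hz
  t <- seq(0, tf_s, by = dt)
  if (length(t) < 2) t <- c(0, tf_s)
  sgn <- if (choice == "right") 1 else -1
  x <- minjerk_closed_form(sgn * design$x_f_cm, tf_s, t)
  if (com_inj) {
    # early opposite-side excursion, peaking before the reach commits
    t_c <- 0.45 * tf_s
    amp <- 2.2 + runif(1, 0, 0.8)
    bump <- ifelse(t <= t_c, sin(pi * t / t_c)^2, 0)
    x <- x - sgn * amp * bump
  }
  # depth progress fraction 0 -> 1; a pull-back dents the progress so the
  # distance to the screen genuinely rises (~2 cm) in mid-flight
  frac <- minjerk_closed_form(1, tf_s, t)
  if (pb_inj) {
    tau <- t / tf_s
    inwin <- tau >= 0.4 & tau <= 0.6
    dent <- numeric(length(t))
    dent[inwin] <- sin(pi * (tau[inwin] - 0.4) / 0.2)^2
    frac <- frac - (0.25 + runif(1, 0, 0.1)) * dent
  }
  z <- design$start_depth_cm * (1 - frac)
  x <- x + rnorm(length(t), sd = design$noise_cm)
  z <- z + rnorm(length(t), sd = design$noise_cm)
  list(t_ms = t * 1000, x_cm = x, depth_cm = z)
}
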