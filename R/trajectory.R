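#' Time-normalize a trajectory
#'
#' Linear interpolation of positions onto `n_points` equally spaced times
#' spanning the recorded interval, so every trial has the same number of
#' points (101 by default, endpoints included).
#'
#' @param t sample times (strictly increasing, >= 2 values).
#' @param x positions at `t`.
#' @param n_points number of output points.
#' @return numeric vector of `n_points` interpolated positions.
#' @export
normalize_time <- function(t, x, n_points = 101) {
  if (length(t) < 2) stop("need at least 2 samples to normalize", call. = FALSE)
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  stopifnot(length(t) == length(x))
  approx(t, x, xout = seq(t[1], t[length(t)], length.out = n_points))$y
}

#' Time-normalize the lift-off window of a recorded trial
#'
#' Finds the displacement onset (first sample where the cumulative 2-D path
#' length reaches `disp_mm`, the same criterion RT is built on) and
#' normalizes the horizontal positions from there to the end of the trial.
#' This is the span a motion-capture recording of the reach covers; applied
#' uniformly it makes simulated and recorded datasets comparable.
#'
#' @param t_ms,x_cm,depth_cm trajectory samples.
#' @param n_points number of output points.
#' @param disp_mm displacement-onset criterion (mm).
#' @return `n_points` interpolated positions, or all-`NA` if the effector
#'   never reaches the criterion (or too few samples remain).
#' @export
normalize_liftoff <- function(t_ms, x_cm, depth_cm, n_points = 101,
                              disp_mm = 0.28) {
  n <- length(x_cm)
  if (n < 2) return(rep(NA_real_, n_points))
  cum <- cumsum(sqrt(diff(x_cm)^2 + diff(depth_cm)^2))
  idx <- which(cum >= disp_mm / 10 - 1e-12)[1]
  if (is.na(idx) || idx + 1 >= n) return(rep(NA_real_, n_points))
  keep <- (idx + 1):n
  normalize_time(t_ms[keep], x_cm[keep], n_points)
}

#' Classify a trajectory as a correct trial
#'
#' A correct trial has 50% or more of its normalized points, including the
#' end point, on the correct response side of the screen midline (x = 0).
#'
#' @param x_norm normalized horizontal positions (right positive).
#' @param correct_side `"left"` or `"right"`.
#' @return logical flag.
#' @export
classify_correct <- function(x_norm, correct_side) {
  stopifnot(correct_side %in% c("left", "right"))
  sgn <- if (correct_side == "right") 1 else -1
  on_side <- sgn * x_norm > 0
  mean(on_side) >= 0.5 && on_side[length(on_side)]
}

#' Reaction time from displacement onset
#'
#' RT is the first time the cumulative Euclidean displacement of the
#' effector (horizontal and depth axes) reaches `displacement_mm`, plus the
#' non-decision time. Trials that never reach the displacement criterion are
#' flagged immobile (`rt_ms = NA`).
#'
#' @param t_ms per-tick times (ms).
#' @param x_cm,depth_cm per-tick positions (cm).
#' @param displacement_mm onset criterion in mm (median pre-release
#'   displacement in the task: 0.28 mm).
#' @param ndt_ms non-decision time added to the onset time (ms).
#' @return list with `rt_ms` and `moved`.
#' @export
compute_rt <- function(t_ms, x_cm, depth_cm, displacement_mm = 0.28,
                       ndt_ms = 300) {
  n <- length(x_cm)
  if (n < 2) return(list(rt_ms = NA_real_, moved = FALSE))
  seg <- sqrt(diff(x_cm)^2 + diff(depth_cm)^2)
  cum <- cumsum(seg)
  idx <- which(cum >= displacement_mm / 10 - 1e-12)[1]
  if (is.na(idx)) return(list(rt_ms = NA_real_, moved = FALSE))
  list(rt_ms = t_ms[idx + 1] + ndt_ms, moved = TRUE)
}

#' Detect changes of mind in a trajectory
#'
#' A change of mind is a maximal excursion in which the horizontal position
#' crosses the midline into the half-plane opposite the endpoint side,
#' penetrates by at least `penetration_cm` (measured from the midline), and
#' subsequently returns (next midline crossing or trajectory end). Events
#' on the side opposite a correct endpoint are incorrect-to-correct
#' corrections.
#'
#' @param x horizontal positions (raw or normalized; right positive).
#' @param correct logical; was the endpoint side the correct side? `NA` for
#'   ratio-1 trials (directions are then unlabelled).
#' @param penetration_cm penetration criterion (cm).
#' @return list with `count` and `directions` (character vector,
#'   `"incorrect_to_correct"` / `"correct_to_incorrect"` / `"unlabelled"`).
#' @export
detect_changes_of_mind <- function(x, correct = NA, penetration_cm = 1) {
  n <- length(x)
  if (n < 2) return(list(count = 0L, directions = character(0)))
  end_sign <- if (x[n] >= 0) 1 else -1
  opp <- -end_sign * x          # penetration depth into the opposite side
  inside <- opp > 0
  count <- 0L
  i <- 1
  while (i <= n) {
    if (inside[i]) {
      j <- i
      while (j < n && inside[j + 1]) j <- j + 1
      if (max(opp[i:j]) >= penetration_cm) count <- count + 1L
      i <- j + 1
    } else i <- i + 1
  }
  dir <- if (count == 0L) character(0)
  else if (is.na(correct)) rep("unlabelled", count)
  else if (correct) rep("incorrect_to_correct", count)
  else rep("correct_to_incorrect", count)
  list(count = count, directions = dir)
}

#' Heading angle at peak velocity
#'
#' The signed angle (degrees) between the displacement vector from the start
#' position at the time of peak speed and the depth axis. Positive angles
#' point toward the chosen side; straight-ahead motion gives 0 and purely
#' lateral motion +/-90.
#'
#' @param t_ms,x_cm,depth_cm raw trajectory samples.
#' @return angle in degrees, or `NA` (flagged via attribute
#'   `"undefined"`) when there is no displacement at peak speed.
#' @export
heading_angle <- function(t_ms, x_cm, depth_cm) {
  stopifnot(length(t_ms) >= 2)
  dt_s <- diff(t_ms) / 1000
  vx <- diff(x_cm) / dt_s
  vz <- diff(depth_cm) / dt_s
  speed <- sqrt(vx^2 + vz^2)
  k <- which.max(speed) + 1
  dx <- x_cm[k] - x_cm[1]
  dz <- depth_cm[1] - depth_cm[k]   # progress toward the screen
  if (dx == 0 && dz == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  chosen <- if (x_cm[length(x_cm)] >= 0) 1 else -1
  atan2(chosen * dx, dz) * 180 / pi
}

#' Flip-and-average summaries per ratio
#'
#' Left trials are sign-flipped so the correct target is positive, then
#' trials are averaged pointwise over the 101 normalized positions. The
#' scalar summary `hp_cm` is the mean of the 101 points of the mean
#' trajectory. By convention only correct trials enter the trajectory
#' average (set `correct_only = FALSE` to include incorrect trials);
#' ratio-1 trials, which have no correct side, are flipped by choice.
#' Positions can be truncated at a fraction of the lateral target
#' (`truncate_frac`) to mimic recordings that stop short of the screen.
#'
#' @param dataset a `reach_dataset` (from [simulate_block()],
#'   [generate_dataset()] or [read_trajectories()]).
#' @param correct_only average correct trials only (task convention).
#' @param truncate_frac optional fraction of `x_f_cm` at which each trial's
#'   samples are truncated before normalization (e.g. 0.99); `NULL` for no
#'   truncation.
#' @param x_f_cm lateral target magnitude used with `truncate_frac`.
#' @param penetration_cm change-of-mind criterion passed to
#'   [detect_changes_of_mind()].
#' @param compute_com set `FALSE` to skip change-of-mind detection
#'   (`com_rate` is then `NA`; useful in fitting loops).
#' @param window which time normalization to summarize for simulated
#'   datasets: `"full"` spans the whole trial from stimulus onset
#'   (including the slow pre-lift-off phase that carries the certainty
#'   signature); `"liftoff"` spans displacement onset to arrival, the span
#'   a motion-capture recording covers. Recorded datasets are identical
#'   under both.
#' @return tibble with one row per ratio: `ratio`, `hp_cm`, `accuracy`,
#'   `mean_rt_ms`, `com_rate`, `n_trials`, and a list-column
#'   `mean_trajectory` of 101 values.
#' @export
flip_and_average <- function(dataset, correct_only = TRUE,
                             truncate_frac = NULL, x_f_cm = 10,
                             penetration_cm = 1, compute_com = TRUE,
                             window = c("full", "liftoff")) {
  meta <- dataset$meta
  window <- match.arg(window)
  norm <- dataset_norm(dataset, truncate_frac = truncate_frac,
                       x_f_cm = x_f_cm, window = window)
  ratios <- sort(unique(meta$ratio))
  rows <- vector("list", length(ratios))
  for (ri in seq_along(ratios)) {
    r <- ratios[ri]
    idx <- which(abs(meta$ratio - r) < 1e-9 &
                   rowSums(is.na(norm)) == 0)
    if (length(idx) == 0) {
      warning(sprintf("no usable trials for ratio %g", r))
      next
    }
    flip <- flip_signs(meta[idx, ])
    flipped <- norm[idx, , drop = FALSE] * flip
    acc <- mean(meta$correct[idx], na.rm = TRUE)
    use <- if (correct_only && any(!is.na(meta$correct[idx]))) {
      idx[which(meta$correct[idx])]
    } else idx
    if (length(use) == 0) {
      warning(sprintf("no correct trials for ratio %g", r))
      next
    }
    flipped_use <- norm[use, , drop = FALSE] * flip_signs(meta[use, ])
    mean_traj <- colMeans(flipped_use)
    com_counts <- if (compute_com) {
      vapply(seq_len(nrow(flipped)), function(i) {
        detect_changes_of_mind(flipped[i, ], correct = meta$correct[idx[i]],
                               penetration_cm = penetration_cm)$count
      }, integer(1))
    } else NA_integer_
    rows[[ri]] <- tibble::tibble(
      ratio = r, hp_cm = mean(mean_traj), accuracy = acc,
      mean_rt_ms = mean(meta$rt_ms[idx], na.rm = TRUE),
      com_rate = if (compute_com) mean(com_counts > 0) else NA_real_,
      n_trials = length(idx),
      mean_trajectory = list(mean_traj))
  }
  dplyr::bind_rows(rows)
}

flip_signs <- function(meta_rows) {
  # +1 keeps a trial, -1 mirrors it so the relevant target is positive:
  # correct side when defined, chosen side on ratio-1 trials
  side <- ifelse(meta_rows$correct_side == "none",
                 meta_rows$choice, meta_rows$correct_side)
  ifelse(side == "left", -1, 1)
}

dataset_norm <- function(dataset, truncate_frac = NULL, x_f_cm = 10,
                         n_points = 101, window = "full") {
  stored <- if (window == "liftoff" && !is.null(dataset$norm_liftoff)) {
    dataset$norm_liftoff
  } else dataset$norm
  if (is.null(truncate_frac) && !is.null(stored)) return(stored)
  traj <- dataset$trajectories
  if (nrow(traj) == 0) {
    if (!is.null(dataset$norm)) return(dataset$norm)
    stop("dataset has neither raw trajectories nor normalized positions",
         call. = FALSE)
  }
  ids <- dataset$meta$trial_id
  out <- matrix(NA_real_, length(ids), n_points)
  split_tr <- split(traj, traj$trial_id)
  for (i in seq_along(ids)) {
    tr <- split_tr[[as.character(ids[i])]]
    if (is.null(tr) || nrow(tr) < 2) next
    keep <- seq_len(nrow(tr))
    if (!is.null(truncate_frac)) {
      hit <- which(abs(tr$x_cm) >= truncate_frac * x_f_cm)[1]
      if (!is.na(hit) && hit >= 2) keep <- seq_len(hit)
    }
    out[i, ] <- if (window == "liftoff") {
      normalize_liftoff(tr$t_ms[keep], tr$x_cm[keep], tr$depth_cm[keep],
                        n_points)
    } else {
      normalize_time(tr$t_ms[keep], tr$x_cm[keep], n_points)
    }
  }
  out
}

#' Exclude pull-back trials
#'
#' Removes trials in which the effector retreats from the screen in
#' mid-flight, and reports the dropout fraction. A pull-back is a depth
#' reversal whose amplitude reaches `min_retreat_cm`: after smoothing the
#' depth trace with a short moving average (instantaneous velocity sign is
#' noise-dominated in jittered recordings), the maximum rise of the
#' distance-to-screen above its running minimum is taken as the retreat
#' amplitude.
#'
#' @param dataset a `reach_dataset` with raw trajectories.
#' @param min_retreat_cm minimum depth-reversal amplitude (cm).
#' @param smooth_ms moving-average window for the depth trace (ms).
#' @return list with `dataset` (filtered) and `dropout_rate`.
#' @export
exclude_pullbacks <- function(dataset, min_retreat_cm = 0.5, smooth_ms = 25) {
  traj <- dataset$trajectories
  if (nrow(traj) == 0) stop("raw trajectories required", call. = FALSE)
  split_tr <- split(traj, traj$trial_id)
  ids <- dataset$meta$trial_id
  bad <- vapply(seq_along(ids), function(i) {
    tr <- split_tr[[as.character(ids[i])]]
    if (is.null(tr) || nrow(tr) < 3) return(FALSE)
    dt_ms <- median(diff(tr$t_ms))
    win <- max(1L, round(smooth_ms / dt_ms))
    d <- if (win > 1) as.numeric(stats::filter(tr$depth_cm,
                                               rep(1 / win, win),
                                               sides = 2)) else tr$depth_cm
    d <- d[!is.na(d)]
    if (length(d) < 2) return(FALSE)
    max(d - cummin(d)) >= min_retreat_cm
  }, logical(1))
  keep <- which(!bad)
  filtered <- dataset
  filtered$meta <- dataset$meta[keep, , drop = FALSE]
  filtered$trajectories <- traj[traj$trial_id %in% ids[keep], , drop = FALSE]
  if (!is.null(dataset$norm)) {
    filtered$norm <- dataset$norm[keep, , drop = FALSE]
  }
  if (!is.null(dataset$norm_liftoff)) {
    filtered$norm_liftoff <- dataset$norm_liftoff[keep, , drop = FALSE]
  }
  list(dataset = filtered, dropout_rate = mean(bad))
}
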