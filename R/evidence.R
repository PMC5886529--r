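#' Complementary error function
#'
#' `erfc(x) = 2 * pnorm(-x * sqrt(2))`, the standard complementary error
#' function used by the psychometric model of numerosity discrimination.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
erfc <- function(x) 2 * pnorm(-x * sqrt(2))

#' Construct a stimulus pair
#'
#' A stimulus pair holds the two dot counts shown on a trial, their numerical
#' ratio (min/max) and which side is correct. Equal counts have no correct
#' side (`correct_side = "none"`).
#'
#' @param n_left,n_right integer dot counts (>= 1).
#' @param max_dots upper bound on either count. The task display holds at
#'   most 25 dots by default.
#' @return an object of class `stimulus_pair` with fields `n_left`,
#'   `n_right`, `ratio`, `correct_side`.
#' @examples
#' stimulus_pair(5, 10)
#' @export
stimulus_pair <- function(n_left, n_right, max_dots = 25) {
  if (!is.finite(n_left) || !is.finite(n_right)) {
    stop("invalid stimulus: dot counts must be finite", call. = FALSE)
  }
  if (n_left < 1 || n_right < 1 || n_left != round(n_left) ||
      n_right != round(n_right)) {
    stop("invalid stimulus: dot counts must be integers >= 1", call. = FALSE)
  }
  if (n_left > max_dots || n_right > max_dots) {
    stop(sprintf("invalid stimulus: counts exceed max_dots = %d", max_dots),
         call. = FALSE)
  }
  side <- if (n_left == n_right) "none" else if (n_left > n_right) "left" else "right"
  structure(
    list(n_left = as.integer(n_left), n_right = as.integer(n_right),
         ratio = min(n_left, n_right) / max(n_left, n_right),
         correct_side = side),
    class = "stimulus_pair"
  )
}

#' @export
print.stimulus_pair <- function(x, ...) {
  cat(sprintf("<stimulus_pair> %d vs %d (ratio %.3g, correct side: %s)\n",
              x$n_left, x$n_right, x$ratio, x$correct_side))
  invisible(x)
}

#' Draw evidence samples from the internal numerical representation
#'
#' Samples are Gaussian with mean `|n_left - n_right|` and standard deviation
#' `omega * sqrt(n_left^2 + n_right^2)`, the standard Weber-scaled noise model
#' of numerosity psychophysics. Samples are expressed in numerical-difference
#' units in a correct-side-positive frame: negative samples are evidence
#' favouring the wrong side.
#'
#' @param pair a [stimulus_pair()].
#' @param omega Weber fraction (>= 0); 0 gives noiseless samples.
#' @param n number of samples to draw.
#' @return numeric vector of length `n`.
#' @export
sample_evidence <- function(pair, omega, n = 1) {
  stopifnot(inherits(pair, "stimulus_pair"))
  if (!is.finite(omega) || omega < 0) stop("omega must be >= 0", call. = FALSE)
  mu <- abs(pair$n_left - pair$n_right)
  sigma <- omega * sqrt(pair$n_left^2 + pair$n_right^2)
  rnorm(n, mean = mu, sd = sigma)
}

#' Generate an evidence stream
#'
#' Draws independent evidence samples every `R_ms` milliseconds for the
#' duration of a trial. The first sample arrives at `t = R_ms`; a duration
#' shorter than `R_ms` yields a legal empty stream.
#'
#' @inheritParams sample_evidence
#' @param R_ms sampling interval in ms; must lie in \[1, 100\] (plausible
#'   inter-sample intervals for number-selective neurons).
#' @param duration_ms total sampling duration in ms (> 0).
#' @return an object of class `evidence_stream`: list with `sample_times`
#'   (ms), `raw` samples, and `ema` (`NULL` until [apply_ema()] is used).
#' @export
generate_stream <- function(pair, omega, R_ms, duration_ms) {
  if (!is.finite(R_ms) || R_ms < 1 || R_ms > 100) {
    stop("R_ms out of bounds [1, 100]", call. = FALSE)
  }
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    stop("duration_ms must be > 0", call. = FALSE)
  }
  n <- floor(duration_ms / R_ms)
  structure(
    list(sample_times = if (n > 0) R_ms * seq_len(n) else numeric(0),
         raw = sample_evidence(pair, omega, n),
         ema = NULL),
    class = "evidence_stream"
  )
}

#' Exponential-moving-average memory filter
#'
#' `EMA(i) = D * s(i) + (1 - D) * EMA(i - 1)`, initialized at
#' `EMA(0) = s(1)`. `D = 1` leaves the stream unmodified (memory-free
#' sampling); `D` near 0 locks the series onto the first sample (primacy).
#'
#' @param raw numeric vector of raw evidence samples (may be empty).
#' @param D memory decay in \[0, 1\].
#' @return numeric vector of filtered samples, same length as `raw`.
#' @examples
#' apply_ema(c(3, -1, 4), D = 1)   # unchanged
#' apply_ema(c(3, -1, 4), D = 0)   # locked to first sample
#' @export
apply_ema <- function(raw, D) {
  if (!is.finite(D) || D < 0 || D > 1) stop("D must lie in [0, 1]", call. = FALSE)
  n <- length(raw)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  prev <- raw[1]
  for (i in seq_len(n)) {
    prev <- D * raw[i] + (1 - D) * prev
    out[i] <- prev
  }
  out
}

#' Predicted error rate of a numerosity comparison
#'
#' Closed-form per-sample misclassification probability
#' `0.5 * erfc(|n_L - n_R| / (omega * sqrt(2) * sqrt(n_L^2 + n_R^2)))`.
#' Equal counts give chance (0.5); the rate depends on the counts only
#' through their ratio.
#'
#' @param pair a [stimulus_pair()], or `NULL` if `n_left`/`n_right` given.
#' @param omega Weber fraction (> 0).
#' @param n_left,n_right alternative scalar/vector count interface.
#' @return error probability in \[0, 0.5\].
#' @export
predicted_error_rate <- function(pair = NULL, omega, n_left = NULL, n_right = NULL) {
  if (!is.null(pair)) {
    stopifnot(inherits(pair, "stimulus_pair"))
    n_left <- pair$n_left; n_right <- pair$n_right
  }
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("omega must be > 0", call. = FALSE)
  # 0.5*erfc(d / (omega*sqrt(2)*sqrt(S))) == pnorm(-d / (omega*sqrt(S)))
  pnorm(-abs(n_left - n_right) / (omega * sqrt(n_left^2 + n_right^2)))
}

#' Fit a Weber fraction to accuracy data
#'
#' Least-squares fit of the psychometric error-rate curve to observed
#' accuracies: omega minimizes the summed squared deviation between observed
#' error rates (1 - accuracy) and the model error rate.
#'
#' @param accuracy_table data frame with columns `n_left`, `n_right`,
#'   `accuracy` (one row per ratio or pair; accuracies in \[0, 1\]).
#' @param interval search interval for omega.
#' @return an object of class `weber_fit`: list with `omega`, `r_squared`,
#'   and `degenerate` flag.
#' @export
fit_weber <- function(accuracy_table, interval = c(1e-4, 10)) {
  stopifnot(all(c("n_left", "n_right", "accuracy") %in% names(accuracy_table)))
  acc <- accuracy_table$accuracy
  if (any(acc < 0 | acc > 1)) stop("accuracies must lie in [0, 1]", call. = FALSE)
  ratios <- pmin(accuracy_table$n_left, accuracy_table$n_right) /
    pmax(accuracy_table$n_left, accuracy_table$n_right)
  if (length(unique(round(ratios, 10))) < 2) {
    stop("need at least 2 distinct ratios to identify omega", call. = FALSE)
  }
  obs_err <- 1 - acc
  degenerate <- all(abs(obs_err - 0.5) < 1e-12)
  if (degenerate) {
    warning("all accuracies at chance: omega is unbounded above (degenerate fit)")
  }
  sse <- function(w) {
    pred <- predicted_error_rate(omega = w,
                                 n_left = accuracy_table$n_left,
                                 n_right = accuracy_table$n_right)
    sum((obs_err - pred)^2)
  }
  opt <- optimize(sse, interval = interval)
  ss_tot <- sum((obs_err - mean(obs_err))^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_
  structure(list(omega = opt$minimum, r_squared = r2, degenerate = degenerate),
            class = "weber_fit")
}

#' @export
print.weber_fit <- function(x, ...) {
  cat(sprintf("<weber_fit> omega = %.4f (R^2 = %.3f)%s\n", x$omega,
              x$r_squared, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
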