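#' Sequential Bayesian belief about the numerical difference
#'
#' With a flat prior on the numerical difference and a normal likelihood with
#' variance `W`, the posterior after `n` filtered samples is
#' `N(e_bar, W / n)` where `e_bar` is the mean of the EMA samples. The
#' probability that the positive-frame (correct) side holds the larger
#' number is `p_correct = pnorm(e_bar * sqrt(n / W))`. Note `W` is a
#' variance, not a standard deviation.
#'
#' @param ema numeric vector of EMA-filtered evidence samples (non-empty).
#' @param W likelihood noise variance (> 0).
#' @return an object of class `belief`: list with `e_bar`, `n_samples`,
#'   `posterior_var`, `p_correct`, `certainty`.
#' @examples
#' update_belief(c(1, 1, 1, 1), W = 4)  # posterior N(1, 1)
#' @export
update_belief <- function(ema, W) {
  if (!is.finite(W) || W <= 0) stop("W must be > 0", call. = FALSE)
  n <- length(ema)
  if (n == 0) stop("ema must be non-empty", call. = FALSE)
  e_bar <- mean(ema)
  p <- pnorm(e_bar * sqrt(n / W))
  structure(
    list(e_bar = e_bar, n_samples = n, posterior_var = W / n,
         p_correct = p, certainty = certainty_of(p)),
    class = "belief"
  )
}

#' @export
print.belief <- function(x, ...) {
  cat(sprintf("<belief> e_bar = %.4g, n = %d, var = %.4g, p = %.4f, certainty = %.4f\n",
              x$e_bar, x$n_samples, x$posterior_var, x$p_correct, x$certainty))
  invisible(x)
}

#' Entropy-based certainty of a binary belief
#'
#' `(H(0.5) - H(p)) / H(0.5)` with binary entropy
#' `H(p) = -(p log p + (1 - p) log(1 - p))`. Symmetric in `p <-> 1 - p`,
#' zero at chance and 1 for a fully resolved belief. Probabilities are
#' clipped to `[eps, 1 - eps]` before taking logs.
#'
#' @param p probability (vectorized).
#' @param eps clipping bound to keep logs finite.
#' @return certainty in \[0, 1\].
#' @export
certainty_of <- function(p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  h <- -(p * log(p) + (1 - p) * log(1 - p))
  pmin(pmax(1 - h / log(2), 0), 1)
}

#' Current heading side of a belief
#'
#' The effector heads toward the side with the larger probability. Ties at
#' `p = 0.5` head to the positive-frame side; certainty is zero there so the
#' motor update vanishes and downstream results are insensitive to the rule.
#'
#' @param belief a [update_belief()] result.
#' @return `+1` (positive-frame side) or `-1`.
#' @export
heading_side <- function(belief) {
  stopifnot(inherits(belief, "belief"))
  if (belief$p_correct >= 0.5) 1L else -1L
}

#' Two-hypothesis posterior of being correct (collapsing-bound model)
#'
#' Posterior probability of the "correct" hypothesis given i.i.d. samples
#' under Gaussian likelihoods `N(dft, sig2)` (correct) vs `N(-dft, sig2)`
#' (incorrect) with equal priors. Algebraically the product of density
#' ratios collapses to `plogis(2 * dft * sum(samples) / sig2)`.
#'
#' @param samples numeric vector of evidence samples.
#' @param dft drift (likelihood mean magnitude).
#' @param sig2 evidence variance (> 0).
#' @return posterior probability in (0, 1).
#' @export
ddm_posterior_correct <- function(samples, dft, sig2) {
  if (!is.finite(sig2) || sig2 <= 0) stop("sig2 must be > 0", call. = FALSE)
  plogis(2 * dft * sum(samples) / sig2)
}
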