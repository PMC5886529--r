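#' Minimum-jerk feedback derivative
#'
#' Finite-horizon jerk-minimizing feedback law. For a single axis with state
#' `(x, v, a)`, target `x_f` and remaining movement time `delta`, the state
#' derivative is `(v, a, jerk)` with
#' `jerk = -(60/delta^3) x - (36/delta^2) v - (9/delta) a + (60/delta^3) x_f`.
#' The target at rest is a fixed point.
#'
#' @param state numeric length-3 vector `(position, velocity, acceleration)`
#'   or a 3-row matrix with one column per axis.
#' @param x_f target position(s), one per axis.
#' @param delta remaining movement time in seconds; clamped below at
#'   `delta_min` to avoid the finite-horizon singularity.
#' @param delta_min remaining-time floor in seconds.
#' @return derivative with the same shape as `state`.
#' @export
kinematic_derivative <- function(state, x_f, delta, delta_min = 1e-3) {
  delta <- max(delta, delta_min)
  m <- if (is.matrix(state)) state else matrix(state, nrow = 3)
  stopifnot(nrow(m) == 3, length(x_f) == ncol(m))
  jerk <- -(60 / delta^3) * (m[1, ] - x_f) - (36 / delta^2) * m[2, ] -
    (9 / delta) * m[3, ]
  d <- rbind(m[2, ], m[3, ], jerk)
  if (is.matrix(state)) d else as.numeric(d)
}

#' Single Euler step of the certainty-weighted controller
#'
#' Explicit Euler update `state <- state + weight * derivative * dt` applied
#' to every kinematic component of every axis. A weight of zero freezes the
#' kinematics; elapsed time advances regardless (the remaining-horizon clock
#' is owned by the caller).
#'
#' @inheritParams kinematic_derivative
#' @param weight scalar update weight in \[0, 1\] (the certainty signal).
#' @param dt integration step in seconds.
#' @return updated state, same shape as `state`.
#' @export
controller_step <- function(state, x_f, weight, dt, delta, delta_min = 1e-3) {
  stopifnot(weight >= 0, weight <= 1, dt > 0)
  state + weight * kinematic_derivative(state, x_f, delta, delta_min) * dt
}

#' Satisficing update weight
#'
#' `certainty ^ depth_distance`, where `depth_distance` is the normalized
#' remaining depth to the screen (1 at the start button, 0 at screen
#' arrival). Near the screen the exponent releases the certainty brake so
#' the movement settles onto the closest target; `0^0` is defined as 1.
#'
#' @param certainty certainty in \[0, 1\].
#' @param depth_distance normalized depth distance in \[0, 1\].
#' @return update weight in \[0, 1\].
#' @export
satisficing_weight <- function(certainty, depth_distance) {
  stopifnot(all(certainty >= 0), all(certainty <= 1),
            all(depth_distance >= 0), all(depth_distance <= 1))
  ifelse(depth_distance == 0, 1, certainty^depth_distance)
}

#' Closed-form minimum-jerk trajectory
#'
#' The classic jerk-minimizing point-to-point solution
#' `x(t) = x_f * (10 tau^3 - 15 tau^4 + 6 tau^5)`, `tau = t / tf`, used as
#' the analytic oracle for the feedback controller.
#'
#' @param x_f target position.
#' @param tf total movement time (s).
#' @param t elapsed time(s) in \[0, tf\] (vectorized).
#' @return position(s) at `t`.
#' @export
minjerk_closed_form <- function(x_f, tf, t) {
  stopifnot(all(t >= 0), all(t <= tf + 1e-12))
  tau <- t / tf
  x_f * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}
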