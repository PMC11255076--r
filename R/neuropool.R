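#' Parameters of the excitatory/inhibitory neuronal-pool model
#'
#' The model describes the balance between a self-excitatory and a
#' self-inhibitory neuronal population driving respiratory output:
#' \deqn{t_1 \dot I_1 = -I_1 + C_{11} I_1 - C_{21} I_2 + D}
#' \deqn{t_2 \dot I_2 = -I_2 + C_{12} I_1 - C_{22} I_2}
#' where \eqn{I_1} is the instantaneous average activity of the excitatory
#' pool, \eqn{I_2} of the inhibitory pool, \eqn{D} a tonic drive, and the
#' \eqn{C_{ij}} dimensionless interconnection constants.
#'
#' The stability indicator
#' \eqn{K = C_{21} C_{12} - (C_{11}-1)(1+C_{22})} must be positive for a
#' finite steady state to exist.
#'
#' @param t1,t2 time constants of the excitatory and inhibitory pools
#'   (same time unit as the simulation grid; minutes by convention). Must be
#'   positive.
#' @param C11,C12,C21,C22 dimensionless interaction constants.
#' @param D tonic drive (activity units).
#' @return An object of class \code{pool_params}.
#' @examples
#' p <- pool_params(t1 = 1, t2 = 1, C11 = 1, C12 = 1, C21 = 1, C22 = 0, D = 1)
#' stability_k(p)  # 1: stable
#' @export
pool_params <- function(t1, t2, C11, C12, C21, C22, D = 0) {
  if (!is.numeric(t1) || !is.numeric(t2) || t1 <= 0 || t2 <= 0)
    stop("pool time constants t1 and t2 must be positive", call. = FALSE)
  p <- list(t1 = t1, t2 = t2, C11 = C11, C12 = C12, C21 = C21, C22 = C22,
            D = D)
  class(p) <- "pool_params"
  p
}

#' Stability indicator of a pool parameterization
#'
#' @param params a \code{pool_params} object.
#' @return \eqn{K = C_{21} C_{12} - (C_{11}-1)(1+C_{22})}. A finite steady
#'   state exists only for \eqn{K > 0}.
#' @export
stability_k <- function(params) {
  stopifnot(inherits(params, "pool_params"))
  params$C21 * params$C12 - (params$C11 - 1) * (1 + params$C22)
}

#' Steady state of the pool model under constant drive
#'
#' @param params a \code{pool_params} object.
#' @return Named vector \code{c(I1, I2)} with
#'   \eqn{I_1^\ast = D(1+C_{22})/K} and
#'   \eqn{I_2^\ast = C_{12} I_1^\ast / (1+C_{22})}.
#' @export
pool_steady_state <- function(params) {
  K <- stability_k(params)
  if (K <= 0)
    stop("K <= 0: the pool system has no finite steady state (unstable)",
         call. = FALSE)
  I1 <- params$D * (1 + params$C22) / K
  c(I1 = I1, I2 = params$C12 * I1 / (1 + params$C22))
}

#' Simulate the excitatory/inhibitory pool ODEs
#'
#' Integrates the two-pool system with a fixed-step 4th-order Runge-Kutta
#' scheme. The drive may be a constant or a function of time, allowing
#' step and time-varying inputs.
#'
#' @param params a \code{pool_params} object. Its \code{D} field is ignored
#'   when \code{drive} is supplied.
#' @param drive constant drive value or a function \code{drive(t)} defined on
#'   \code{[0, duration]}. Defaults to \code{params$D}.
#' @param initial numeric vector \code{c(I1, I2)} at \code{t = 0}.
#' @param duration total simulated time (same unit as \code{t1}, \code{t2}).
#' @param dt fixed integration step; halving it changes trajectories by less
#'   than 1e-6 at the default.
#' @return A data frame with columns \code{t}, \code{I1}, \code{I2}; the
#'   attribute \code{"unstable"} is \code{TRUE} when \eqn{K \le 0} (a
#'   warning is also raised, since the trajectory then has no finite
#'   asymptote).
#' @export
simulate_pools <- function(params, drive = NULL, initial = c(I1 = 0, I2 = 0),
                           duration, dt = 0.01) {
  stopifnot(inherits(params, "pool_params"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(dt) || dt <= 0 || dt > duration)
    stop("dt must satisfy 0 < dt <= duration")
  if (is.null(drive)) drive <- params$D
  drive_fn <- if (is.function(drive)) drive else function(t) drive

  K <- stability_k(params)
  unstable <- K <= 0
  if (unstable)
    warning("K <= 0: pool system is unstable; trajectory may diverge",
            call. = FALSE)

  deriv <- function(t, y, parms) {
    d1 <- (-y[1] + params$C11 * y[1] - params$C21 * y[2] + drive_fn(t)) /
      params$t1
    d2 <- (-y[2] + params$C12 * y[1] - params$C22 * y[2]) / params$t2
    list(c(d1, d2))
  }
  times <- seq(0, duration, by = dt)
  y0 <- c(I1 = unname(initial[1]), I2 = unname(initial[2]))
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  traj <- data.frame(t = out[, "time"], I1 = out[, "I1"], I2 = out[, "I2"])
  attr(traj, "unstable") <- unstable
  traj
}

#' Canonical second-order description of a step response
#'
#' The pool model's excitatory output to a step drive is, in transfer-function
#' form,
#' \deqn{I_1(s) = \frac{A s + B}{s\,[(s/w_n)^2 + 2\zeta (s/w_n) + 1]}}
#' with natural frequency \eqn{w_n}, damping coefficient \eqn{\zeta},
#' numerator rate coefficient \eqn{A} and steady-state amplitude \eqn{B}.
#' The same form, with \eqn{A = 0}, describes the delayed second-order rise
#' of ventilatory long-term facilitation.
#'
#' @param wn natural frequency (rad per time unit; see \code{time_unit}).
#' @param zeta damping coefficient (dimensionless, > 0).
#' @param A numerator rate coefficient (activity x time); contributes a
#'   transient proportional to the system impulse response and nothing at
#'   steady state.
#' @param B steady-state step amplitude (activity units or L/min).
#' @param baseline constant offset added to the response (units of \code{B}).
#' @param onset_delay pure delay before the response begins (time units).
#' @param time_unit unit string carried with \code{wn} ("min" or "s").
#' @return An object of class \code{canonical_params}.
#' @export
canonical_params <- function(wn, zeta, A = 0, B, baseline = 0,
                             onset_delay = 0, time_unit = "min") {
  if (!is.numeric(wn) || wn <= 0) stop("wn must be > 0", call. = FALSE)
  if (!is.numeric(zeta) || zeta <= 0) stop("zeta must be > 0", call. = FALSE)
  if (!is.finite(B)) stop("B must be finite", call. = FALSE)
  if (onset_delay < 0) stop("onset_delay must be >= 0", call. = FALSE)
  structure(list(wn = wn, zeta = zeta, A = A, B = B, baseline = baseline,
                 onset_delay = onset_delay, time_unit = time_unit),
            class = "canonical_params")
}

#' Convert pool parameters to canonical second-order form
#'
#' Maps the ODE constants onto \eqn{(w_n, \zeta, A, B)}:
#' \deqn{w_n^2 = K/(t_1 t_2), \quad
#'       \zeta = \frac{t_1(1+C_{22}) - t_2(C_{11}-1)}{2 w_n t_1 t_2},}
#' \deqn{A = D t_2 / K, \quad B = D (1+C_{22}) / K,}
#' with \eqn{K = C_{21}C_{12} - (C_{11}-1)(1+C_{22})}. The pair
#' \eqn{(w_n, \zeta)} reproduces the roots of the characteristic polynomial
#' \eqn{t_1 t_2 s^2 + [t_1(1+C_{22}) - t_2(C_{11}-1)] s + K}.
#'
#' @param params a \code{pool_params} object with \eqn{K > 0}.
#' @return A \code{canonical_params} object (baseline 0, no onset delay),
#'   in the time unit of \code{t1}/\code{t2}.
#' @export
to_canonical <- function(params) {
  stopifnot(inherits(params, "pool_params"))
  K <- stability_k(params)
  if (K <= 0)
    stop("K <= 0: no oscillator (second-order) form exists for these ",
         "parameters", call. = FALSE)
  t1 <- params$t1; t2 <- params$t2
  wn <- sqrt(K / (t1 * t2))
  zeta <- (t1 * (1 + params$C22) - t2 * (params$C11 - 1)) / (2 * wn * t1 * t2)
  if (zeta <= 0)
    stop("non-positive damping: pool system is oscillatorily unstable",
         call. = FALSE)
  canonical_params(wn = wn, zeta = zeta,
                   A = params$D * t2 / K,
                   B = params$D * (1 + params$C22) / K)
}

# unit step response of 1/((s/wn)^2 + 2 zeta s/wn + 1), t >= 0
.step_unit <- function(t, wn, zeta) {
  if (abs(zeta - 1) < 1e-9) {
    1 - exp(-wn * t) * (1 + wn * t)
  } else if (zeta < 1) {
    wd <- wn * sqrt(1 - zeta^2)
    1 - exp(-zeta * wn * t) * (cos(wd * t) + (zeta * wn / wd) * sin(wd * t))
  } else {
    wd <- wn * sqrt(zeta^2 - 1)
    1 - exp(-zeta * wn * t) * (cosh(wd * t) + (zeta * wn / wd) * sinh(wd * t))
  }
}

# impulse response of the same normalized system (unit DC area), t >= 0
.impulse_unit <- function(t, wn, zeta) {
  if (abs(zeta - 1) < 1e-9) {
    wn^2 * t * exp(-wn * t)
  } else if (zeta < 1) {
    wd <- wn * sqrt(1 - zeta^2)
    (wn^2 / wd) * exp(-zeta * wn * t) * sin(wd * t)
  } else {
    wd <- wn * sqrt(zeta^2 - 1)
    (wn^2 / wd) * exp(-zeta * wn * t) * sinh(wd * t)
  }
}

#' Closed-form step response of the canonical second-order system
#'
#' Evaluates \code{baseline} for \code{t < onset_delay} and, for
#' \eqn{t' = t - \mathrm{onset\_delay}},
#' \deqn{y(t) = \mathrm{baseline} + B\,u(t') + A\,h(t')}
#' where \eqn{u} is the unit step response and \eqn{h} the impulse response
#' of \eqn{1/[(s/w_n)^2 + 2\zeta(s/w_n) + 1]}; the \eqn{A} term carries the
#' numerator \eqn{A s} of the transfer function and vanishes at steady
#' state, so the asymptote is \code{baseline + B}. Underdamped
#' (\eqn{\zeta < 1}), critically damped and overdamped cases are all
#' handled in closed form.
#'
#' @param params a \code{canonical_params} object.
#' @param times numeric vector of evaluation times (non-decreasing), same
#'   unit as \code{params$wn}.
#' @return Numeric vector of response values.
#' @examples
#' ltf <- canonical_params(wn = 0.375, zeta = 0.7, A = 0, B = 9,
#'                         baseline = 7.6, onset_delay = 2)
#' step_response(ltf, c(0, 2, 4, 6, 60))  # approaches 7.6 + 9 = 16.6
#' @export
step_response <- function(params, times) {
  stopifnot(inherits(params, "canonical_params"))
  if (is.unsorted(times)) stop("times must be non-decreasing", call. = FALSE)
  tp <- times - params$onset_delay
  y <- rep(params$baseline, length(times))
  on <- tp >= 0
  if (any(on)) {
    y[on] <- params$baseline +
      params$B * .step_unit(tp[on], params$wn, params$zeta) +
      params$A * .impulse_unit(tp[on], params$wn, params$zeta)
  }
  y
}

#' Steady-state (DC) gain of the canonical form
#'
#' The \eqn{A s} numerator term contributes nothing at steady state, so the
#' step amplitude reached above baseline is \eqn{B} regardless of \eqn{A}.
#'
#' @param params a \code{canonical_params} object.
#' @return The value of \code{B}.
#' @export
dc_gain <- function(params) {
  stopifnot(inherits(params, "canonical_params"))
  if (params$wn <= 0) stop("wn must be > 0", call. = FALSE)
  params$B
}

#' @export
print.canonical_params <- function(x, ...) {
  cat(sprintf(
    "Second-order response: wn = %.4g rad/%s, zeta = %.4g, A = %.4g, B = %.4g\n",
    x$wn, x$time_unit, x$zeta, x$A, x$B))
  cat(sprintf("  baseline = %.4g, onset delay = %.4g %s, asymptote = %.4g\n",
              x$baseline, x$onset_delay, x$time_unit, x$baseline + x$B))
  invisible(x)
}
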