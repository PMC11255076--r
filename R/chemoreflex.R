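#' Two-compartment chemoreflex parameters
#'
#' Central (brainstem) and peripheral (carotid body) chemoreceptor
#' compartments, each a delayed first-order system driven by the deviation
#' of end-tidal CO2 partial pressure (PetCO2) from baseline. Steady-state
#' ventilation change per mmHg is \code{Gc + Gp}.
#'
#' Only the gains are normally estimated from data; the dynamics are fixed
#' at literature values: central time constant 120 s, peripheral 15 s,
#' transport delays 10 s and 6 s.
#'
#' @param Gc,Gp central and peripheral gains, (L/min)/mmHg, >= 0 (fits may
#'   hit the zero bound).
#' @param tau_c,tau_p compartment time constants in seconds; must satisfy
#'   \code{tau_c > tau_p > 0}.
#' @param delay_c,delay_p transport delays in seconds, >= 0.
#' @return An object of class \code{chemoreflex_params}.
#' @export
chemoreflex_params <- function(Gc, Gp, tau_c = 120, tau_p = 15,
                               delay_c = 10, delay_p = 6) {
  if (Gc < 0 || Gp < 0)
    stop("chemoreflex gains must be non-negative", call. = FALSE)
  if (!(tau_c > tau_p && tau_p > 0))
    stop("time constants must satisfy tau_c > tau_p > 0", call. = FALSE)
  if (delay_c < 0 || delay_p < 0)
    stop("delays must be non-negative", call. = FALSE)
  structure(list(Gc = Gc, Gp = Gp, tau_c = tau_c, tau_p = tau_p,
                 delay_c = delay_c, delay_p = delay_p),
            class = "chemoreflex_params")
}

# Exact zero-order-hold update of tau*dx/dt = -x + G*u across one step h:
# x[j+1] = a x[j] + G u[j] (1-a), a = exp(-h/tau). On the refined grid this
# reproduces sampled step inputs exactly (delays aligned to the fine grid)
# and lags smooth inputs by at most h/2, negligible at the sub-second h used.
.zoh_filter <- function(u, h, tau, gain) {
  a <- exp(-h / tau)
  n <- length(u)
  w <- gain * (1 - a) * u[-n]
  c(0, stats::filter(w, a, method = "recursive"))
}

#' Predict the chemoreceptor-mediated ventilation component
#'
#' Runs the PetCO2 deviation signal through the central and peripheral
#' compartments,
#' \deqn{\tau_c \dot x_c = -x_c + G_c\,\Delta P(t - d_c), \qquad
#'       \tau_p \dot x_p = -x_p + G_p\,\Delta P(t - d_p),}
#' and returns \eqn{x_c + x_p} on the input grid. The input is treated as
#' piecewise linear between samples, with zero history before \code{t = 0};
#' delays index into that history by interpolation, so sub-sample delays
#' are supported. Internally the signal is refined to a sub-second grid and
#' each compartment advanced with an exact exponential update, so a
#' sustained step \eqn{\Delta P} attains the analytic per-compartment
#' response and the asymptote \eqn{(G_c + G_p)\Delta P}.
#'
#' @param params a \code{chemoreflex_params} object.
#' @param dpet numeric vector of PetCO2 deviations from baseline (mmHg),
#'   uniformly sampled; \code{dpet[1]} is the value at \code{t = 0}.
#' @param dt sampling interval in seconds.
#' @return Numeric vector of ventilation deviations (L/min), same length
#'   and grid as \code{dpet}.
#' @examples
#' p <- chemoreflex_params(Gc = 1.5, Gp = 0.5)
#' tail(predict_ventilation(p, rep(1, 120), dt = 30), 1)  # -> 2.0 L/min
#' @export
predict_ventilation <- function(params, dpet, dt) {
  stopifnot(inherits(params, "chemoreflex_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  n <- length(dpet)
  if (n < 2) stop("dpet must contain at least two samples", call. = FALSE)
  t_in <- (seq_len(n) - 1) * dt

  max_delay <- max(params$delay_c, params$delay_p)
  if (t_in[n] < max_delay)
    message("chemoreflex: input shorter than the longest delay; ",
            "zero-padded history assumed")

  # fine internal grid: <= 0.5 s and resolving the fast compartment
  h <- min(0.5, params$tau_p / 10, dt)
  refine <- ceiling(dt / h)
  h <- dt / refine
  tf <- seq(0, t_in[n], by = h)

  # delayed input on the fine grid; zero before t = 0, held after the end
  delayed <- function(delay) {
    tq <- tf - delay
    u <- stats::approx(t_in, dpet, xout = pmax(tq, 0), rule = 2)$y
    u[tq < 0] <- 0
    u
  }
  xc <- .zoh_filter(delayed(params$delay_c), h, params$tau_c, params$Gc)
  xp <- .zoh_filter(delayed(params$delay_p), h, params$tau_p, params$Gp)
  idx <- 1 + round(t_in / h)
  xc[idx] + xp[idx]
}

#' Inspired CO2 partial pressure
#'
#' Partial pressure of CO2 in humidified inspired gas:
#' \code{fico2 * (pb - ph2o)}. At 3\% CO2, sea-level pressure and body
#' temperature water vapor this is about 21 mmHg, well below the normal
#' alveolar 40 mmHg.
#'
#' @param fico2 inspired CO2 fraction in \code{[0, 1]}.
#' @param pb barometric pressure (mmHg).
#' @param ph2o water vapor pressure (mmHg); 47 mmHg at body temperature.
#' @return Inspired PCO2 in mmHg.
#' @examples
#' inspired_pco2(0.03, 760, 47)  # 21.39 mmHg
#' @export
inspired_pco2 <- function(fico2, pb = 760, ph2o = 47) {
  if (any(fico2 < 0 | fico2 > 1))
    stop("fico2 must lie in [0, 1]", call. = FALSE)
  if (any(pb <= ph2o) || any(ph2o < 0))
    stop("pressures must satisfy pb > ph2o >= 0", call. = FALSE)
  fico2 * (pb - ph2o)
}
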