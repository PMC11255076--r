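# segment boundary helpers -------------------------------------------------

# start time of a labeled segment: samples carry the end of their 30-s
# window, so the segment covering (t0, t1] starts at min(time) - 0.5
.segment_start <- function(time, segment, label) {
  tt <- time[segment == label]
  if (!length(tt)) stop("segment '", label, "' not found", call. = FALSE)
  min(tt) - 0.5
}

.value_at <- function(x, time, at, what = "reference") {
  i <- which(abs(time - at) < 1e-9)
  if (length(i) != 1)
    stop(what, " time ", at, " is not on the sampling grid", call. = FALSE)
  x[i]
}

# chemoreflex prediction over a full record, zero history before t = 0;
# the trace grid is 30 s, so dt = 30 s with an implicit t = 0 sample
.predict_full <- function(params, dpet) {
  predict_ventilation(params, c(0, dpet), dt = 30)[-1]
}

# chemoreflex gain estimation ----------------------------------------------

#' Fit central and peripheral chemoreflex gains on the initial 40 W interval
#'
#' Least-squares estimation of \eqn{(G_c, G_p)}: ventilation and PetCO2 are
#' expressed as deviations from their values at the start of the fit
#' segment (the 40 W-onset baseline), the two-compartment chemoreflex model
#' with fixed dynamics is run over the whole record, and the gains minimize
#' the sum of squared residuals over the fit segment (its onset from rest
#' included) via Nelder-Mead simplex search with non-negativity enforced by
#' reflection at zero. Only these two gains are free; time constants and
#' delays stay at their configured values.
#'
#' @param traces an \code{ltf_traces} data frame for a single series
#'   (typically the group average).
#' @param fit_segment label of the first 40 W segment.
#' @param params0 starting \code{chemoreflex_params}; supplies the fixed
#'   dynamics and the initial gains.
#' @return An object of class \code{chemo_fit}: fitted gains, residual SD
#'   over the fit segment, the predicted chemoreflex trace over the whole
#'   record, optimizer diagnostics, and an \code{identifiable} flag
#'   (near-flat PetCO2 deviations make the gains unidentifiable; the fit is
#'   then flagged rather than failing).
#' @export
fit_chemo_gains <- function(traces, fit_segment = "w40_base",
                            params0 = chemoreflex_params(Gc = 1, Gp = 1)) {
  stopifnot(inherits(traces, "data.frame"),
            inherits(params0, "chemoreflex_params"))
  if (length(unique(traces$subject)) != 1)
    stop("fit_chemo_gains expects a single series; average the group first",
         call. = FALSE)
  time <- traces$time_min
  t_base <- .segment_start(time, traces$segment, fit_segment)
  if (t_base < min(time)) t_base <- min(time)
  ve0 <- .value_at(traces$ve_lpm, time, t_base, "baseline")
  pet0 <- .value_at(traces$petco2_mmhg, time, t_base, "baseline")
  dve <- traces$ve_lpm - ve0
  dpet <- traces$petco2_mmhg - pet0
  t_end <- max(time[traces$segment == fit_segment])
  win <- time >= t_base - 1e-9 & time <= t_end + 1e-9
  m <- sum(win)

  mk <- function(g) chemoreflex_params(Gc = abs(g[1]), Gp = abs(g[2]),
                                       tau_c = params0$tau_c,
                                       tau_p = params0$tau_p,
                                       delay_c = params0$delay_c,
                                       delay_p = params0$delay_p)

  if (max(abs(dpet[win])) < 0.25) {
    fit <- list(Gc = 0, Gp = 0, params = mk(c(0, 0)),
                residual_sd_lpm = stats::sd(dve[win]),
                predicted_lpm = rep(0, length(time)),
                fit_segment = fit_segment, fit_window = win,
                baseline_time_min = t_base, time_min = time,
                sse = sum(dve[win]^2), iterations = 0L,
                converged = FALSE, identifiable = FALSE)
    class(fit) <- "chemo_fit"
    return(fit)
  }

  obj <- function(g) sum((dve[win] - .predict_full(mk(g), dpet)[win])^2)
  starts <- list(c(params0$Gc, params0$Gp),
                 c(params0$Gc, params0$Gp) * 0.5 + 0.1,
                 c(params0$Gc, params0$Gp) * 2)
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish from the incumbent
  o <- stats::optim(best$par, obj, method = "Nelder-Mead",
                    control = list(maxit = 1000, reltol = 1e-12))
  if (o$value <= best$value) best <- o

  pars <- mk(best$par)
  fit <- list(Gc = pars$Gc, Gp = pars$Gp, params = pars,
              residual_sd_lpm = sqrt(best$value / max(m - 2, 1)),
              predicted_lpm = .predict_full(pars, dpet),
              fit_segment = fit_segment, fit_window = win,
              baseline_time_min = t_base, time_min = time,
              sse = best$value,
              iterations = unname(best$counts["function"]),
              converged = best$convergence == 0, identifiable = TRUE)
  class(fit) <- "chemo_fit"
  fit
}

#' @export
print.chemo_fit <- function(x, ...) {
  cat(sprintf("Chemoreflex fit on '%s': Gc = %.3f, Gp = %.3f (L/min)/mmHg\n",
              x$fit_segment, x$Gc, x$Gp))
  cat(sprintf("  residual SD = %.3f L/min; converged: %s; identifiable: %s\n",
              x$residual_sd_lpm, x$converged, x$identifiable))
  invisible(x)
}

#' Neurally mediated ventilation component
#'
#' Subtracts the predicted chemoreceptor-mediated contribution from the
#' measured ventilation deviation over the whole record. Deviations are
#' taken from the series' own values at the chemoreflex-fit baseline time
#' (the 40 W onset), and the prediction uses the fitted gains with the
#' fixed compartment dynamics throughout.
#'
#' @param traces an \code{ltf_traces} data frame for one series (a subject
#'   or the group average) on the same grid as the fit.
#' @param chemofit a \code{chemo_fit} object.
#' @return Numeric vector: the neural component (L/min) on the trace grid.
#' @export
neural_component <- function(traces, chemofit) {
  stopifnot(inherits(chemofit, "chemo_fit"))
  time <- traces$time_min
  if (length(time) != length(chemofit$time_min) ||
      any(abs(time - chemofit$time_min) > 1e-9))
    stop("trace grid does not match the grid the chemoreflex was fitted on",
         call. = FALSE)
  ve0 <- .value_at(traces$ve_lpm, time, chemofit$baseline_time_min,
                   "baseline")
  pet0 <- .value_at(traces$petco2_mmhg, time, chemofit$baseline_time_min,
                    "baseline")
  (traces$ve_lpm - ve0) - .predict_full(chemofit$params,
                                        traces$petco2_mmhg - pet0)
}

#' Shift a series to a new control level
#'
#' Subtracts the series value at the reference time, so the series reads as
#' augmentation above that control point (e.g. the start of the 45\%
#' VO2max segment).
#'
#' @param x numeric series.
#' @param time sampling times of \code{x}.
#' @param at reference time; must lie on the grid.
#' @return The rebaselined series.
#' @export
rebaseline <- function(x, time, at) {
  x - .value_at(x, time, at)
}

#' Detect the onset of the LTF rise during recovery
#'
#' The augmentation onset is taken as the first time within the recovery
#' segment at which the series exceeds its initial-recovery plateau mean by
#' \code{2 * noise_sd} for two consecutive samples. The plateau is the mean
#' over the second minute of recovery (the first minute is skipped because
#' the exercise off-transient has not yet decayed there).
#'
#' @param x numeric series (rebaselined neural component).
#' @param time sampling times (min).
#' @param segment segment labels aligned with \code{time}.
#' @param recovery_label label of the recovery segment.
#' @param noise_sd noise scale for the threshold (L/min), > 0; typically
#'   the chemoreflex-fit residual SD.
#' @param multiplier threshold multiplier on \code{noise_sd} (default 2;
#'   exposed for sensitivity diagnostics).
#' @return The onset time (min, absolute), or \code{NA} if the threshold is
#'   never exceeded; attributes \code{"threshold"} and \code{"plateau"}
#'   carry the decision levels.
#' @export
detect_onset <- function(x, time, segment, recovery_label = "w40_recovery",
                         noise_sd, multiplier = 2) {
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  rec <- segment == recovery_label
  if (sum(rec) < 4)
    stop("recovery segment has fewer than 4 samples", call. = FALSE)
  t0 <- .segment_start(time, segment, recovery_label)
  plateau_idx <- rec & time > t0 + 1 & time <= t0 + 2
  plateau <- mean(x[plateau_idx])
  thr <- plateau + multiplier * noise_sd
  cand <- which(rec & time > t0 + 2)
  onset <- NA_real_
  for (i in cand) {
    if (x[i] > thr && (i + 1) <= max(cand) && x[i + 1] > thr) {
      onset <- time[i]
      break
    }
  }
  structure(onset, threshold = thr, plateau = plateau)
}

# delayed second-order rise used by the LTF fit (A = 0)
.ltf_model <- function(tt, wn, zeta, B, baseline, tau) {
  tp <- tt - tau
  y <- rep(baseline, length(tt))
  on <- tp >= 0
  if (any(on)) y[on] <- baseline + B * .step_unit(tp[on], wn, zeta)
  y
}

#' Fit the second-order LTF response over the recovery segment
#'
#' Least-squares fit of a delayed second-order step response (numerator
#' coefficient \eqn{A} fixed at zero) to the rebaselined neural component
#' over the full recovery segment. Free parameters: amplitude \eqn{B},
#' natural frequency \eqn{w_n} (constrained to (0.01, 5] rad/min), damping
#' \eqn{\zeta} (constrained to (0.05, 2]), baseline, and onset delay
#' \eqn{\tau} (constrained to the segment length), all via smooth
#' transforms. Nelder-Mead simplex search from multiple starts (one
#' data-driven start plus seeded jitter); the lowest-SSE solution wins.
#'
#' @param x numeric series (rebaselined neural component, full record).
#' @param time sampling times (min).
#' @param segment segment labels aligned with \code{time}.
#' @param recovery_label label of the recovery segment.
#' @param onset detected onset time (min, absolute) used to initialize
#'   \eqn{\tau}; \code{NA} or \code{NULL} falls back to a 2-min initial
#'   delay.
#' @param n_starts number of simplex starts (>= 3).
#' @param skip_min initial portion of the recovery segment excluded from
#'   the fit window (min). The decomposition pipeline skips the first
#'   minute, where the exercise off-transient still contaminates the
#'   neural component; 0 fits the segment from its start.
#' @return An object of class \code{ltf_fit}: \code{params}
#'   (\code{canonical_params} in rad/min with baseline and onset delay
#'   relative to recovery start), SSE, residual SD, fitted values over the
#'   window, recovery start time, and convergence info.
#' @export
fit_ltf <- function(x, time, segment, recovery_label = "w40_recovery",
                    onset = NULL, n_starts = 4, skip_min = 0) {
  rec <- segment == recovery_label
  t0 <- .segment_start(time, segment, recovery_label)
  rec <- rec & time > t0 + skip_min
  m <- sum(rec)
  if (m < 6) stop("LTF fit window has fewer than 6 samples", call. = FALSE)
  tt <- time[rec] - t0
  y <- x[rec]
  t_len <- max(tt)

  # parameter transforms keeping the search unconstrained: wn in (0.01, 5]
  # rad/min, zeta in (0.05, 2], tau within the segment, and B in [0, 25]
  # L/min -- a physiological plausibility ceiling on the extrapolated
  # augmentation (the asymptote is only weakly identified from a partial
  # rise, and unbounded fits can run away along a flat SSE profile)
  tr <- function(th) list(
    wn = 0.01 + 4.99 * stats::plogis(th[1]),
    zeta = 0.05 + 1.95 * stats::plogis(th[2]),
    B = 25 * stats::plogis(th[3]), baseline = th[4],
    tau = t_len * stats::plogis(th[5]))
  inv <- function(wn, zeta, B, baseline, tau) c(
    stats::qlogis(pmin(pmax((wn - 0.01) / 4.99, 1e-4), 1 - 1e-4)),
    stats::qlogis(pmin(pmax((zeta - 0.05) / 1.95, 1e-4), 1 - 1e-4)),
    stats::qlogis(pmin(pmax(B / 25, 1e-4), 1 - 1e-4)), baseline,
    stats::qlogis(pmin(pmax(tau / t_len, 1e-4), 1 - 1e-4)))
  obj <- function(th) {
    p <- tr(th)
    sum((y - .ltf_model(tt, p$wn, p$zeta, p$B, p$baseline, p$tau))^2)
  }

  plateau0 <- mean(y[tt > 1 & tt <= 2])
  if (!is.finite(plateau0)) plateau0 <- mean(y[seq_len(min(2, m))])
  tau0 <- if (is.null(onset) || is.na(onset)) 2 else
    max(min(onset - t0 - 0.25, t_len - 0.5), 0.25)
  B0 <- max(mean(y[tt >= t_len - 0.5]) - plateau0, 0.5)
  base_start <- inv(0.4, 0.7, B0, plateau0, tau0)

  jitter <- with_seed(20231L,
    matrix(stats::rnorm((n_starts - 1) * 5, 0, 0.5),
           ncol = 5))
  starts <- c(list(base_start),
              lapply(seq_len(n_starts - 1),
                     function(i) base_start + jitter[i, ]))

  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }

  p <- tr(best$par)
  # a fit whose response never departs from baseline inside the window has
  # an arbitrary (unidentified) amplitude; canonicalize it to zero
  fitted <- .ltf_model(tt, p$wn, p$zeta, p$B, p$baseline, p$tau)
  if (max(abs(fitted - p$baseline)) < 1e-6) p$B <- 0
  params <- canonical_params(wn = p$wn, zeta = p$zeta, A = 0, B = p$B,
                             baseline = p$baseline, onset_delay = p$tau,
                             time_unit = "min")
  fit <- list(params = params, sse = best$value,
              residual_sd_lpm = sqrt(best$value / max(m - 5, 1)),
              fitted = .ltf_model(tt, p$wn, p$zeta, p$B, p$baseline, p$tau),
              time_rel_min = tt, recovery_start_min = t0,
              converged = best$convergence == 0,
              n_starts = length(starts))
  class(fit) <- "ltf_fit"
  fit
}

#' @export
print.ltf_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "LTF fit: wn = %.3f rad/min, zeta = %.3f, B = %.2f L/min,\n", p$wn,
    p$zeta, p$B))
  cat(sprintf("  baseline = %.2f L/min, onset delay = %.2f min, SSE = %.3f\n",
              p$baseline, p$onset_delay, x$sse))
  cat(sprintf("  asymptote above control = %.2f L/min\n", p$baseline + p$B))
  invisible(x)
}

#' Extrapolate a fitted LTF response beyond the observation window
#'
#' @param fit an \code{ltf_fit} object.
#' @param horizon_min extrapolation horizon (min since recovery start).
#' @param dt time step of the returned series (min).
#' @return A list: \code{series} (data frame \code{time_rel_min},
#'   \code{ve_lpm}), \code{asymptote_lpm} (= baseline + B, above the
#'   rebaselined control), and \code{above_initial_lpm} (= B, above the
#'   initial augmentation plateau).
#' @export
extrapolate_ltf <- function(fit, horizon_min = 30, dt = 0.5) {
  stopifnot(inherits(fit, "ltf_fit"))
  tt <- seq(0, horizon_min, by = dt)
  list(series = data.frame(time_rel_min = tt,
                           ve_lpm = step_response(fit$params, tt)),
       asymptote_lpm = fit$params$baseline + fit$params$B,
       above_initial_lpm = fit$params$B)
}

#' Final augmentation estimate with combined standard error
#'
#' Averages per-subject final augmentations (above the 45\%-exercise-start
#' control) and propagates two variance sources: the between-subject spread
#' of the finals and the chemoreflex-fit residual SD (the model-correction
#' uncertainty, assumed to carry over to the recovery interval). The
#' combined SD is their root-sum-of-squares; SE divides by \eqn{\sqrt n}.
#' A one-sample (paired vs zero) t test of the finals is reported.
#'
#' @param finals per-subject final augmentations (L/min), length >= 2.
#' @param fit_sd chemoreflex-fit residual SD (L/min).
#' @return A list: \code{estimate_lpm}, \code{group_sd_lpm},
#'   \code{combined_sd_lpm}, \code{se_lpm}, \code{n}, \code{t}, \code{p}.
#' @export
augmentation_estimate <- function(finals, fit_sd) {
  n <- length(finals)
  if (n < 2) stop("need at least two subjects", call. = FALSE)
  group_sd <- stats::sd(finals)
  combined <- combine_sd(c(group_sd, fit_sd))
  tt <- if (group_sd > 0) paired_t(finals, rep(0, n)) else
    list(t = NA_real_, p = NA_real_)
  list(estimate_lpm = mean(finals), group_sd_lpm = group_sd,
       combined_sd_lpm = combined, se_lpm = combined / sqrt(n),
       n = n, t = tt$t, p = tt$p)
}

#' Run the full LTF decomposition pipeline
#'
#' Fits the chemoreflex gains on the group-average initial 40 W interval,
#' removes the predicted chemoreceptor contribution over the whole record,
#' shifts the control level to the start of the 45\% VO2max segment,
#' detects the augmentation onset during recovery, fits the delayed
#' second-order LTF response, and extrapolates its steady state. When
#' per-subject traces are supplied, per-subject final augmentations (at the
#' last recovery sample) feed the group estimate and its combined standard
#' error.
#'
#' @param group an \code{ltf_traces} data frame (group average).
#' @param subjects optional stacked per-subject \code{ltf_traces}.
#' @param fit_segment label of the chemoreflex-fit segment.
#' @param recovery_label label of the recovery segment.
#' @param reference_label segment whose start defines the augmentation
#'   control level.
#' @param chemo0 starting \code{chemoreflex_params} for the gain fit.
#' @param skip_min initial portion of the recovery segment excluded from
#'   the LTF fit window (min); see \code{\link{fit_ltf}}.
#' @return An object of class \code{ltf_decomposition} collecting the
#'   chemoreflex fit, neural component, onset, LTF fit, extrapolated
#'   asymptote (above control and above the initial augmentation), the
#'   end-window group estimate, and (with subjects) the final-augmentation
#'   estimate with SE.
#' @export
decompose_ltf <- function(group, subjects = NULL,
                          fit_segment = "w40_base",
                          recovery_label = "w40_recovery",
                          reference_label = "vo2_45",
                          chemo0 = chemoreflex_params(Gc = 1, Gp = 1),
                          skip_min = 1) {
  chemofit <- fit_chemo_gains(group, fit_segment, chemo0)
  time <- group$time_min
  neural <- neural_component(group, chemofit)
  t_ref <- .segment_start(time, group$segment, reference_label)
  neural_reb <- rebaseline(neural, time, t_ref)
  onset <- detect_onset(neural_reb, time, group$segment, recovery_label,
                        noise_sd = max(chemofit$residual_sd_lpm, 1e-6))
  fit <- fit_ltf(neural_reb, time, group$segment, recovery_label,
                 onset = as.numeric(onset), skip_min = skip_min)
  extra <- extrapolate_ltf(fit)

  rec_end <- max(time[group$segment == recovery_label])
  end_window <- .value_at(neural_reb, time, rec_end)

  finals <- NULL
  aug <- NULL
  if (!is.null(subjects)) {
    ids <- unique(subjects$subject)
    finals <- vapply(ids, function(id) {
      tr <- subjects[subjects$subject == id, , drop = FALSE]
      ns <- neural_component(tr, chemofit)
      nr <- rebaseline(ns, tr$time_min, t_ref)
      .value_at(nr, tr$time_min, rec_end)
    }, numeric(1))
    aug <- augmentation_estimate(finals, chemofit$residual_sd_lpm)
  }

  res <- list(chemofit = chemofit,
              neural_lpm = neural, neural_rebaselined_lpm = neural_reb,
              time_min = time, reference_time_min = t_ref,
              onset_time_min = as.numeric(onset),
              onset_threshold_lpm = attr(onset, "threshold"),
              ltf_fit = fit,
              extrapolation = extra,
              asymptote_above_control_lpm = extra$asymptote_lpm,
              asymptote_above_initial_lpm = extra$above_initial_lpm,
              end_window_estimate_lpm = end_window,
              subject_finals_lpm = finals,
              augmentation = aug)
  class(res) <- "ltf_decomposition"
  res
}

#' @export
print.ltf_decomposition <- function(x, ...) {
  print(x$chemofit)
  if (is.na(x$onset_time_min)) {
    cat("Onset: not detected during recovery\n")
  } else {
    cat(sprintf("Onset: %.1f min (%.1f min after recovery start)\n",
                x$onset_time_min,
                x$onset_time_min - x$ltf_fit$recovery_start_min))
  }
  print(x$ltf_fit)
  cat(sprintf("Extrapolated asymptote: %.2f L/min above control ",
              x$asymptote_above_control_lpm))
  cat(sprintf("(%.2f above initial augmentation)\n",
              x$asymptote_above_initial_lpm))
  cat(sprintf("End-of-window augmentation: %.2f L/min above control\n",
              x$end_window_estimate_lpm))
  if (!is.null(x$augmentation)) {
    a <- x$augmentation
    cat(sprintf(
      "Final augmentation (n = %d): %.2f +/- %.2f L/min SE (p = %.3g)\n",
      a$n, a$estimate_lpm, a$se_lpm, a$p))
  }
  invisible(x)
}
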