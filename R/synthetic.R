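# run code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Interval-exercise protocol specification
#'
#' The default protocol is the five-step interval-exercise sequence: 5 min
#' seated rest, 6 min cycling at 40 W, 6 min at 45\% VO2max, 6 min recovery
#' cycling at 40 W, and 6 min at 80\% VO2max, with respiratory variables
#' averaged every 30 s. Segment boundaries must align to the 30-s grid.
#'
#' @param segments a data frame with columns \code{label} (unique segment
#'   name), \code{duration_min}, \code{tag} (one of \code{"rest"},
#'   \code{"w40"}, \code{"light45"}, \code{"heavy80"}) and \code{fico2}
#'   (inhaled CO2 fraction). Defaults to the five-step protocol.
#' @return An object of class \code{protocol_spec}.
#' @export
protocol_spec <- function(segments = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(
      label = c("rest", "w40_base", "vo2_45", "w40_recovery", "vo2_80"),
      duration_min = c(5, 6, 6, 6, 6),
      tag = c("rest", "w40", "light45", "w40", "heavy80"),
      fico2 = 0,
      stringsAsFactors = FALSE)
  }
  need <- c("label", "duration_min", "tag", "fico2")
  if (!all(need %in% names(segments)))
    stop("protocol segments need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(segments$label))
    stop("segment labels must be unique", call. = FALSE)
  structure(list(segments = segments), class = "protocol_spec")
}

#' Build the annotated 30-s sampling grid of a protocol
#'
#' @param spec a \code{protocol_spec}. Segment durations must be positive
#'   multiples of 0.5 min so boundaries fall on the sampling grid.
#' @return A data frame with one row per 30-s sample: \code{time_min}
#'   (0.5, 1.0, ..., total duration; each sample stamps the end of its
#'   averaging window), \code{segment}, \code{tag}, and the segment start
#'   time \code{seg_start_min}. A sample at time t belongs to the segment
#'   whose interval (start, end] contains t.
#' @examples
#' grid <- build_protocol(protocol_spec())
#' nrow(grid)  # 58 samples over 29 min
#' @export
build_protocol <- function(spec = protocol_spec()) {
  stopifnot(inherits(spec, "protocol_spec"))
  seg <- spec$segments
  if (any(seg$duration_min <= 0) ||
      any(abs(seg$duration_min / 0.5 - round(seg$duration_min / 0.5)) > 1e-9))
    stop("segment durations must be positive multiples of 0.5 min ",
         "(30-s grid alignment)", call. = FALSE)
  ends <- cumsum(seg$duration_min)
  starts <- c(0, ends[-length(ends)])
  time_min <- seq(0.5, ends[length(ends)], by = 0.5)
  idx <- findInterval(time_min - 1e-9, starts)
  data.frame(time_min = time_min,
             segment = seg$label[idx],
             tag = seg$tag[idx],
             seg_start_min = starts[idx],
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic-data generator
#'
#' Defines the "truth" from which synthetic 7-subject interval-exercise
#' records are drawn: a chemoreflex component driven by the PetCO2 deviation
#' profile, a work-rate-dependent exercise drive with first-order on/off
#' kinetics, a delayed second-order LTF augmentation confined to the
#' recovery (second 40 W) segment, a constant between-subject ventilation
#' offset, and i.i.d. Gaussian 30-s measurement noise.
#'
#' @param protocol a \code{protocol_spec}.
#' @param chemo chemoreflex truth (\code{chemoreflex_params}).
#' @param drive_amp named amplitudes (L/min above rest) of the exercise
#'   drive per work-rate tag.
#' @param drive_tau_min first-order rise/decay time constant of the exercise
#'   drive (min).
#' @param ve_rest_lpm resting minute ventilation (L/min).
#' @param pet_baseline_mmhg resting end-tidal CO2 (mmHg).
#' @param pet_dev_co2_mmhg sustained PetCO2 elevation during exercise
#'   segments when breathing 3\% CO2 (mmHg).
#' @param pet_dev_air_mmhg transient PetCO2 elevation under air (mmHg).
#' @param pet_dev_air_min duration of the air transient at the start of
#'   each exercise segment (min).
#' @param ltf LTF truth (\code{canonical_params} with \code{A = 0});
#'   applied only during the recovery segment, as its baseline plus the
#'   delayed second-order step response measured from segment start.
#' @param ltf_segment label of the segment carrying the LTF component.
#' @param subject_sd_lpm SD of the constant between-subject offset (L/min).
#' @param noise_sd_lpm SD of ventilation measurement noise per 30-s sample.
#' @param pet_noise_sd_mmhg SD of PetCO2 measurement noise per sample.
#' @param n_subjects number of subjects in a group.
#' @param seed master seed for group generation.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(protocol = protocol_spec(),
                             chemo = chemoreflex_params(Gc = 2.0, Gp = 1.0),
                             drive_amp = c(rest = 0, w40 = 10,
                                           light45 = 22, heavy80 = 40),
                             drive_tau_min = 0.5,
                             ve_rest_lpm = 10,
                             pet_baseline_mmhg = 40,
                             pet_dev_co2_mmhg = 7,
                             pet_dev_air_mmhg = 1.5,
                             pet_dev_air_min = 2,
                             ltf = canonical_params(wn = 0.375, zeta = 0.7,
                                                    A = 0, B = 9,
                                                    baseline = 7.6,
                                                    onset_delay = 2),
                             ltf_segment = "w40_recovery",
                             subject_sd_lpm = 5.3,
                             noise_sd_lpm = 1.7,
                             pet_noise_sd_mmhg = 0.3,
                             n_subjects = 7,
                             seed = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(chemo, "chemoreflex_params"),
            inherits(ltf, "canonical_params"))
  if (ltf$A != 0) stop("LTF truth must have A = 0", call. = FALSE)
  if (subject_sd_lpm < 0 || noise_sd_lpm < 0 || pet_noise_sd_mmhg < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  structure(list(protocol = protocol, chemo = chemo, drive_amp = drive_amp,
                 drive_tau_min = drive_tau_min, ve_rest_lpm = ve_rest_lpm,
                 pet_baseline_mmhg = pet_baseline_mmhg,
                 pet_dev_co2_mmhg = pet_dev_co2_mmhg,
                 pet_dev_air_mmhg = pet_dev_air_mmhg,
                 pet_dev_air_min = pet_dev_air_min,
                 ltf = ltf, ltf_segment = ltf_segment,
                 subject_sd_lpm = subject_sd_lpm,
                 noise_sd_lpm = noise_sd_lpm,
                 pet_noise_sd_mmhg = pet_noise_sd_mmhg,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# exercise drive at sample times: piecewise-exponential approach to each
# segment's target amplitude, evaluated exactly
.exercise_drive <- function(grid, amp, tau) {
  seg_labels <- unique(grid$segment)
  v <- numeric(nrow(grid))
  v0 <- 0  # value entering the first segment (rest)
  for (lab in seg_labels) {
    in_seg <- grid$segment == lab
    target <- unname(amp[grid$tag[in_seg][1]])
    t0 <- grid$seg_start_min[in_seg][1]
    tt <- grid$time_min[in_seg]
    v[in_seg] <- target + (v0 - target) * exp(-(tt - t0) / tau)
    t_end <- max(tt)
    v0 <- target + (v0 - target) * exp(-(t_end - t0) / tau)
  }
  v
}

# PetCO2 deviation profile (mmHg) at sample times
.pet_deviation <- function(grid, condition, config) {
  dev <- numeric(nrow(grid))
  exercising <- grid$tag != "rest"
  if (condition == "co2_3pct") {
    dev[exercising] <- config$pet_dev_co2_mmhg
  } else {
    early <- exercising &
      (grid$time_min - grid$seg_start_min) <= config$pet_dev_air_min
    dev[early] <- config$pet_dev_air_mmhg
  }
  dev
}

# LTF component (L/min) at sample times: baseline + delayed second-order
# step response measured from the carrying segment's start, zero elsewhere
.ltf_component <- function(grid, ltf, segment) {
  v <- numeric(nrow(grid))
  in_seg <- grid$segment == segment
  if (any(in_seg)) {
    t0 <- grid$seg_start_min[in_seg][1]
    v[in_seg] <- step_response(ltf, grid$time_min[in_seg] - t0)
  }
  v
}

# chemoreflex component at sample times; prepends the implicit t = 0 sample
.chemo_component <- function(dev, chemo, dt_s = 30) {
  predict_ventilation(chemo, c(0, dev), dt = dt_s)[-1]
}

#' Generate one synthetic subject record
#'
#' Ventilation is assembled as resting baseline + exercise drive +
#' chemoreflex component + LTF component + subject offset + measurement
#' noise; PetCO2 as baseline + deviation profile + noise. Generation is a
#' pure function of \code{(config, condition, subject_seed)}: the global
#' RNG state is untouched.
#'
#' @param config a \code{generator_config}.
#' @param condition \code{"air"} or \code{"co2_3pct"}.
#' @param subject_seed integer seed identifying the subject.
#' @param subject_id subject label used in the output.
#' @return A data frame (class \code{ltf_traces}) with columns
#'   \code{subject}, \code{condition}, \code{time_min}, \code{ve_lpm},
#'   \code{petco2_mmhg}, \code{segment}; the attribute
#'   \code{"components"} holds the noise-free drive, chemoreflex, LTF and
#'   offset terms for introspection.
#' @export
generate_subject <- function(config, condition = c("co2_3pct", "air"),
                             subject_seed, subject_id = "s1") {
  stopifnot(inherits(config, "generator_config"))
  condition <- match.arg(condition)
  grid <- build_protocol(config$protocol)

  drive <- .exercise_drive(grid, config$drive_amp, config$drive_tau_min)
  dev <- .pet_deviation(grid, condition, config)
  chemo <- .chemo_component(dev, config$chemo)
  ltf <- .ltf_component(grid, config$ltf, config$ltf_segment)

  draws <- with_seed(subject_seed, {
    offset <- stats::rnorm(1, 0, config$subject_sd_lpm)
    cond_seeds <- sample.int(.Machine$integer.max - 1L, 2)
    list(offset = offset,
         noise_seed = cond_seeds[[if (condition == "air") 1L else 2L]])
  })
  noise <- with_seed(draws$noise_seed, {
    list(ve = stats::rnorm(nrow(grid), 0, config$noise_sd_lpm),
         pet = stats::rnorm(nrow(grid), 0, config$pet_noise_sd_mmhg))
  })

  ve <- config$ve_rest_lpm + drive + chemo + ltf + draws$offset + noise$ve
  ve <- pmax(ve, 0.1)  # minute ventilation is positive
  pet <- config$pet_baseline_mmhg + dev + noise$pet

  out <- data.frame(subject = subject_id, condition = condition,
                    time_min = grid$time_min, ve_lpm = ve,
                    petco2_mmhg = pet, segment = grid$segment,
                    stringsAsFactors = FALSE)
  class(out) <- c("ltf_traces", "data.frame")
  attr(out, "components") <- data.frame(
    time_min = grid$time_min, drive_lpm = drive, chemo_lpm = chemo,
    ltf_lpm = ltf, offset_lpm = draws$offset, pet_dev_mmhg = dev)
  out
}

#' Generate a synthetic subject group and its pointwise average
#'
#' Subject seeds are derived deterministically from the master seed in
#' \code{config$seed}, so the whole group is reproducible bitwise.
#'
#' @param config a \code{generator_config}.
#' @param condition \code{"air"} or \code{"co2_3pct"}.
#' @return A list with \code{subjects} (stacked per-subject
#'   \code{ltf_traces}), \code{group} (pointwise mean ventilation and
#'   PetCO2 across subjects, subject id \code{"group"}), and
#'   \code{subject_seeds}.
#' @export
generate_group <- function(config, condition = c("co2_3pct", "air")) {
  stopifnot(inherits(config, "generator_config"))
  condition <- match.arg(condition)
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L, config$n_subjects))
  subs <- lapply(seq_len(config$n_subjects), function(i)
    generate_subject(config, condition, seeds[i], sprintf("s%d", i)))
  all_subs <- do.call(rbind, lapply(subs, function(d) {
    attr(d, "components") <- NULL
    d
  }))
  class(all_subs) <- c("ltf_traces", "data.frame")

  g <- subs[[1]]
  ve_mat <- sapply(subs, function(d) d$ve_lpm)
  pet_mat <- sapply(subs, function(d) d$petco2_mmhg)
  group <- data.frame(subject = "group", condition = condition,
                      time_min = g$time_min,
                      ve_lpm = rowMeans(ve_mat),
                      petco2_mmhg = rowMeans(pet_mat),
                      segment = g$segment, stringsAsFactors = FALSE)
  class(group) <- c("ltf_traces", "data.frame")
  list(subjects = all_subs, group = group, subject_seeds = seeds)
}
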