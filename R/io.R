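.trace_columns <- c("subject", "condition", "time_min", "ve_lpm",
                    "petco2_mmhg", "segment")

#' Write interval-exercise traces to CSV
#'
#' One row per 30-s sample, header exactly
#' \code{subject,condition,time_min,ve_lpm,petco2_mmhg,segment}. Values are
#' written at full precision so a write/read round trip is lossless.
#'
#' @param traces an \code{ltf_traces} data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (!all(.trace_columns %in% names(traces)))
    stop("traces must have columns: ",
         paste(.trace_columns, collapse = ", "), call. = FALSE)
  df <- as.data.frame(traces)[, .trace_columns]
  df$time_min <- format(df$time_min, digits = 17, trim = TRUE,
                        scientific = FALSE)
  df$ve_lpm <- format(df$ve_lpm, digits = 17, trim = TRUE)
  df$petco2_mmhg <- format(df$petco2_mmhg, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read interval-exercise traces from CSV
#'
#' Validates the header, column types, time monotonicity within each
#' subject/condition series, and segment labels; malformed input is
#' rejected with the offending line number (header = line 1).
#'
#' @param path CSV file path.
#' @param segments allowed segment labels; defaults to the five-step
#'   protocol's labels.
#' @return An \code{ltf_traces} data frame. A header-only file yields an
#'   empty one with a warning.
#' @export
read_traces <- function(path,
                        segments = protocol_spec()$segments$label) {
  header <- utils::read.csv(path, nrows = 1, header = FALSE,
                            stringsAsFactors = FALSE)
  if (!identical(unname(unlist(header)), .trace_columns))
    stop("bad trace header at line 1: expected '",
         paste(.trace_columns, collapse = ","), "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("trace file '", path, "' contains a header only", call. = FALSE)
    df <- data.frame(subject = character(), condition = character(),
                     time_min = numeric(), ve_lpm = numeric(),
                     petco2_mmhg = numeric(), segment = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("ltf_traces", "data.frame")
    return(df)
  }
  num_cols <- c("time_min", "ve_lpm", "petco2_mmhg")
  for (col in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("non-numeric ", col, " at line ", bad[1] + 1, call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  bad_seg <- which(!(df$segment %in% segments))
  if (length(bad_seg))
    stop("unknown segment label '", df$segment[bad_seg[1]], "' at line ",
         bad_seg[1] + 1, call. = FALSE)
  for (key in unique(paste(df$subject, df$condition))) {
    idx <- which(paste(df$subject, df$condition) == key)
    dt <- diff(df$time_min[idx])
    if (any(dt <= 0)) {
      off <- idx[which(dt <= 0)[1] + 1]
      stop("non-increasing time at line ", off + 1, " (series ", key, ")",
           call. = FALSE)
    }
  }
  class(df) <- c("ltf_traces", "data.frame")
  df
}

#' Load a generator configuration from a YAML key-value file
#'
#' Recognized keys mirror \code{\link{generator_config}} arguments
#' (\code{n_subjects}, \code{seed}, \code{noise_sd_lpm},
#' \code{subject_sd_lpm}, \code{pet_noise_sd_mmhg}, \code{ve_rest_lpm},
#' \code{pet_baseline_mmhg}, \code{pet_dev_co2_mmhg},
#' \code{pet_dev_air_mmhg}, \code{drive_tau_min}) plus nested \code{chemo}
#' (\code{Gc}, \code{Gp}, \code{tau_c}, \code{tau_p}, \code{delay_c},
#' \code{delay_p}) and \code{ltf} (\code{wn}, \code{zeta}, \code{B},
#' \code{baseline}, \code{onset_delay}) blocks; unset keys keep their
#' defaults. Loading then dumping is idempotent.
#'
#' @param path YAML file path, or \code{NULL} for all defaults.
#' @return A \code{generator_config}.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(generator_config())
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar_keys <- c("n_subjects", "seed", "noise_sd_lpm", "subject_sd_lpm",
                   "pet_noise_sd_mmhg", "ve_rest_lpm", "pet_baseline_mmhg",
                   "pet_dev_co2_mmhg", "pet_dev_air_mmhg", "pet_dev_air_min",
                   "drive_tau_min")
  for (k in intersect(scalar_keys, names(raw))) args[[k]] <- raw[[k]]
  if (!is.null(raw$chemo))
    args$chemo <- do.call(chemoreflex_params, raw$chemo)
  if (!is.null(raw$ltf)) {
    ltf_args <- raw$ltf
    ltf_args$A <- 0
    args$ltf <- do.call(canonical_params, ltf_args)
  }
  if (!is.null(raw$drive_amp))
    args$drive_amp <- unlist(raw$drive_amp)
  do.call(generator_config, args)
}

#' Dump a generator configuration to YAML
#'
#' @param config a \code{generator_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- list(
    n_subjects = config$n_subjects, seed = config$seed,
    noise_sd_lpm = config$noise_sd_lpm,
    subject_sd_lpm = config$subject_sd_lpm,
    pet_noise_sd_mmhg = config$pet_noise_sd_mmhg,
    ve_rest_lpm = config$ve_rest_lpm,
    pet_baseline_mmhg = config$pet_baseline_mmhg,
    pet_dev_co2_mmhg = config$pet_dev_co2_mmhg,
    pet_dev_air_mmhg = config$pet_dev_air_mmhg,
    pet_dev_air_min = config$pet_dev_air_min,
    drive_tau_min = config$drive_tau_min,
    drive_amp = as.list(config$drive_amp),
    chemo = unclass(config$chemo),
    ltf = unclass(config$ltf)[c("wn", "zeta", "B", "baseline",
                                "onset_delay")])
  yaml::write_yaml(out, path)
  invisible(path)
}
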