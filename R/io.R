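# Readers and writers for the package's plain-text interchange formats.
# All files are UTF-8 CSV (decimal point, one record per row) or JSON; times
# are seconds from recording start.

config_error <- function(msg) {
  stop(structure(class = c("strainbp_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    config_error(sprintf("%s is missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Write / read a dual-channel recording as CSV
#'
#' Columns `time_s,primary_mmHg,reference_mmHg`, one sample per row.
#'
#' @param recording A `dual_channel_recording`.
#' @param path Output file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `dual_channel_recording` (sample rate recovered from the time
#'   grid).
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "dual_channel_recording"))
  df <- data.frame(time_s = recording$time,
                   primary_mmHg = recording$primary,
                   reference_mmHg = recording$reference)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) config_error(sprintf("recording file not found: %s", path))
  df <- utils::read.csv(path)
  require_columns(df, c("time_s", "primary_mmHg", "reference_mmHg"),
                  sprintf("recording file '%s'", path))
  if (nrow(df) < 2) config_error(sprintf("recording '%s' has fewer than 2 samples", path))
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    config_error(sprintf("recording '%s' does not have a uniform time grid", path))
  }
  structure(
    list(time = df$time_s, primary = df$primary_mmHg,
         reference = df$reference_mmHg,
         sample_rate = 1 / mean(dt), units = "mmHg"),
    class = "dual_channel_recording"
  )
}

#' Write / read a beat table as CSV
#'
#' Columns `beat_time_s,sbp_mmHg,dbp_mmHg,flag`.
#'
#' @param estimate A `bp_estimate` (or a data frame with those columns).
#' @param path File path.
#' @return The path (write) or the beat data frame (read).
#' @export
write_beat_table <- function(estimate, path) {
  df <- as.data.frame(estimate)
  require_columns(df, c("beat_time_s", "sbp_mmHg", "dbp_mmHg", "flag"),
                  "beat table")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  if (!file.exists(path)) config_error(sprintf("beat table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("beat_time_s", "sbp_mmHg", "dbp_mmHg", "flag"),
                  sprintf("beat table '%s'", path))
  df
}

#' Read a reference beat-to-beat BP series
#'
#' CSV with columns `time_s,sbp_mmHg,dbp_mmHg` (e.g. exported from a
#' vascular-unloading finger-cuff monitor).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_reference_bp <- function(path) {
  if (!file.exists(path)) config_error(sprintf("reference BP file not found: %s", path))
  df <- utils::read.csv(path)
  require_columns(df, c("time_s", "sbp_mmHg", "dbp_mmHg"),
                  sprintf("reference BP file '%s'", path))
  df
}

#' Read / write attenuation observations
#'
#' CSV with columns `subject_id,trial_id,contact_pressure_mmHg,alpha`.
#'
#' @param observations An [alpha_observations()] data frame.
#' @param path File path.
#' @return The path (write) or an `alpha_observations` data frame (read).
#' @export
write_alpha_observations <- function(observations, path) {
  df <- as.data.frame(observations)
  require_columns(df, c("subject_id", "trial_id", "contact_pressure_mmHg", "alpha"),
                  "alpha observations")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_alpha_observations
#' @export
read_alpha_observations <- function(path) {
  if (!file.exists(path)) config_error(sprintf("observations file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("subject_id", "trial_id", "contact_pressure_mmHg", "alpha"),
                  sprintf("observations file '%s'", path))
  alpha_observations(df$contact_pressure_mmHg, df$alpha,
                     df$subject_id, df$trial_id)
}

#' Read a calibration weight table
#'
#' CSV with columns `mass_g,adc_counts`.
#'
#' @param path File path.
#' @param gravity Gravitational acceleration (m/s^2).
#' @return A [calibration_weight_set()].
#' @export
read_weight_table <- function(path, gravity = 9.81) {
  if (!file.exists(path)) config_error(sprintf("weight table not found: %s", path))
  df <- utils::read.csv(path)
  require_columns(df, c("mass_g", "adc_counts"),
                  sprintf("weight table '%s'", path))
  calibration_weight_set(df$mass_g, df$adc_counts, gravity)
}

#' Read a JSON run configuration
#'
#' @param path Path to a JSON file.
#' @return Configuration as a nested list. Malformed JSON raises a
#'   configuration error (exit code 2 from the command-line dispatcher).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE),
    error = function(e) {
      config_error(sprintf("malformed JSON config '%s': %s", path,
                           conditionMessage(e)))
    }
  )
}

#' Write a JSON document
#'
#' @param x A list to serialize.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
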