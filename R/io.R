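#' Write / read the per-animal sensor CSV
#'
#' Columns: `timestamp_s, ax, ay, az, gx, gy, gz` (g and deg/s).
#'
#' @param series An [imu_series()].
#' @param path Output file.
#' @export
write_sensor_csv <- function(series, path) {
  stopifnot(inherits(series, "imu_series"))
  utils::write.csv(
    data.frame(timestamp_s = series$timestamps,
               ax = series$ax, ay = series$ay, az = series$az,
               gx = series$gx, gy = series$gy, gz = series$gz),
    path, row.names = FALSE)
}

#' @rdname write_sensor_csv
#' @param animal_id Identifier to attach on read.
#' @param sample_rate Sampling rate of the file; the default `NULL`
#'   infers it from the median timestamp spacing.
#' @export
read_sensor_csv <- function(path, animal_id = basename(path),
                            sample_rate = NULL) {
  d <- utils::read.csv(path)
  if (is.null(sample_rate)) {
    sample_rate <- round(1 / stats::median(diff(d$timestamp_s)))
  }
  imu_series(animal_id, sample_rate, d$ax, d$ay, d$az,
             d$gx, d$gy, d$gz, timestamps = d$timestamp_s)
}

#' Write / read the per-animal behaviour-label CSV
#'
#' Columns: `start_s, stop_s, behaviour`.
#'
#' @param track A [label_track()].
#' @param path Output file.
#' @export
write_labels_csv <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
}

#' @rdname write_labels_csv
#' @param animal_id Identifier to attach on read.
#' @param validate Check states against the ethogram.
#' @export
read_labels_csv <- function(path, animal_id = basename(path),
                            validate = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_track(animal_id, d$start_s, d$stop_s, d$behaviour,
              validate = validate)
}

#' Write an extracted feature table to CSV
#'
#' One row per window: `animal_id`, `start_s`, `length_s`, `label`,
#' then the 44 feature columns with a stable header.
#'
#' @param features Data.frame from [extract_features()].
#' @param path Output file.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
}

#' Read a simulation config from YAML
#'
#' The file holds `n_animals`, `duration_s`, `sample_rate`, `seed` and
#' optionally an inline `regimes` list (defaulting to
#' [default_regimes()]).
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  regimes <- if (!is.null(raw$regimes)) {
    do.call(rbind, lapply(raw$regimes, as.data.frame,
                          stringsAsFactors = FALSE))
  } else default_regimes()
  sim_config(n_animals = raw$n_animals,
             duration_s = raw$duration_s,
             sample_rate = raw$sample_rate %||% 100,
             regimes = regimes,
             seed = raw$seed %||% 1L)
}
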