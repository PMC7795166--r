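#' Ethogram of calf postures and behaviours
#'
#' The fixed catalogue of states a window may be labelled with. Behaviours
#' follow the standard pre-weaned-calf ethogram used for collar-sensor
#' studies; postures are a separate two-state track over the same timeline.
#'
#' @return A list with character vectors `behaviours` and `postures`.
#' @export
ethogram <- function() {
  list(
    behaviours = c(
      "non-active lying", "active lying", "ruminating", "self-grooming",
      "nutritive suckling", "non-nutritive suckling", "locomotor play"
    ),
    postures = c("lying", "standing")
  )
}

#' Construct a 6-channel IMU series for one animal
#'
#' @param animal_id Identifier of the animal/recording file.
#' @param sample_rate Sampling rate in Hz.
#' @param ax,ay,az Accelerometer channels in g.
#' @param gx,gy,gz Gyroscope channels in degrees/s.
#' @param timestamps Optional vector of timestamps in seconds. Defaults to
#'   a uniform grid starting at 0. Must be strictly increasing and uniform
#'   at spacing `1/sample_rate`; non-uniform input is rejected, not
#'   resampled, because the downstream windowing assumes a fixed-rate
#'   sensor.
#'
#' @return An object of class `imu_series`.
#' @export
imu_series <- function(animal_id, sample_rate, ax, ay, az, gx, gy, gz,
                       timestamps = NULL) {
  n <- length(ax)
  lens <- c(length(ay), length(az), length(gx), length(gy), length(gz))
  if (any(lens != n)) {
    stop("all six channels must have equal length", call. = FALSE)
  }
  if (is.null(timestamps)) {
    timestamps <- seq_len(n - 1L)
    timestamps <- c(0, timestamps) / sample_rate
  } else {
    if (length(timestamps) != n) {
      stop("timestamps length must match channel length", call. = FALSE)
    }
    dt <- diff(timestamps)
    if (n > 1 && (any(dt <= 0) ||
                  max(abs(dt - 1 / sample_rate)) > 1e-6 / sample_rate)) {
      stop("timestamps must be strictly increasing and uniformly spaced at ",
           "1/sample_rate; resample the recording before import",
           call. = FALSE)
    }
  }
  structure(
    list(animal_id = animal_id, sample_rate = sample_rate,
         timestamps = as.numeric(timestamps),
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         gx = as.numeric(gx), gy = as.numeric(gy), gz = as.numeric(gz)),
    class = "imu_series"
  )
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> animal %s: %d samples at %g Hz (%.1f s)\n",
              x$animal_id, length(x$ax), x$sample_rate,
              length(x$ax) / x$sample_rate))
  invisible(x)
}

#' Construct a behaviour (or posture) label track
#'
#' Ordered, non-overlapping labelled intervals over one animal's recording.
#'
#' @param animal_id Identifier matching the sensor recording.
#' @param start_s,stop_s Interval bounds in seconds (stop > start).
#' @param behaviour Character vector of states; must belong to the
#'   ethogram unless `validate = FALSE`.
#' @param validate Check states against [ethogram()]. Default `TRUE`.
#'
#' @return An object of class `label_track`: a data.frame with columns
#'   `start_s`, `stop_s`, `behaviour` and attribute `animal_id`.
#' @export
label_track <- function(animal_id, start_s, stop_s, behaviour,
                        validate = TRUE) {
  if (!(length(start_s) == length(stop_s) &&
        length(stop_s) == length(behaviour))) {
    stop("start_s, stop_s and behaviour must have equal length",
         call. = FALSE)
  }
  o <- order(start_s)
  start_s <- as.numeric(start_s)[o]
  stop_s <- as.numeric(stop_s)[o]
  behaviour <- as.character(behaviour)[o]
  if (any(stop_s <= start_s)) {
    stop("every interval must satisfy stop_s > start_s", call. = FALSE)
  }
  if (length(start_s) > 1 &&
      any(start_s[-1] < stop_s[-length(stop_s)] - 1e-9)) {
    stop("intervals must not overlap", call. = FALSE)
  }
  if (validate) {
    known <- c(ethogram()$behaviours, ethogram()$postures)
    bad <- setdiff(unique(behaviour), known)
    if (length(bad)) {
      stop("unknown ethogram state(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- data.frame(start_s = start_s, stop_s = stop_s,
                    behaviour = behaviour, stringsAsFactors = FALSE)
  attr(out, "animal_id") <- animal_id
  class(out) <- c("label_track", "data.frame")
  out
}

#' Derive the posture track implied by a behaviour track
#'
#' Postures (lying/standing) and behaviours are two label tracks over
#' the same timeline; classifiers for the two are trained separately.
#' In the ethogram the mapping from behaviour to posture is
#' deterministic: suckling at the feeder and locomotor play happen
#' standing, all other behaviours lying. Adjacent intervals that map
#' to the same posture are merged.
#'
#' @param track A behaviour [label_track()].
#' @return A [label_track()] over `{lying, standing}`.
#' @export
posture_from_behaviour <- function(track) {
  stopifnot(inherits(track, "label_track"))
  standing <- c("nutritive suckling", "non-nutritive suckling",
                "locomotor play")
  post <- ifelse(track$behaviour %in% standing, "standing", "lying")
  new_run <- c(TRUE, post[-1] != post[-length(post)])
  grp <- cumsum(new_run)
  label_track(attr(track, "animal_id"),
              tapply(track$start_s, grp, min),
              tapply(track$stop_s, grp, max),
              post[new_run])
}

#' Per-sample Euclidean magnitude of a triaxial signal
#'
#' sqrt(x^2 + y^2 + z^2) per sample; removes the orientation dependence of
#' the raw axes, so downstream features are invariant to collar rotation.
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return Numeric vector of nonnegative magnitudes.
#' @export
magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z)) {
    stop("x, y and z must have equal length", call. = FALSE)
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Accelerometer and gyroscope magnitude streams of a series
#'
#' @param series An [imu_series()].
#' @return List with numeric vectors `accel` (g) and `gyro` (deg/s).
#' @export
series_magnitudes <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  list(accel = magnitude(series$ax, series$ay, series$az),
       gyro = magnitude(series$gx, series$gy, series$gz))
}

#' Shift a label track in time
#'
#' Corrects clock desynchronisation between the annotation source (video)
#' and the sensor by translating every interval by a constant offset.
#'
#' @param track A [label_track()].
#' @param offset_s Offset in seconds (positive shifts labels later).
#' @return The shifted `label_track`.
#' @export
apply_time_offset <- function(track, offset_s) {
  stopifnot(inherits(track, "label_track"))
  track$start_s <- track$start_s + offset_s
  track$stop_s <- track$stop_s + offset_s
  track
}

#' Discretise a recording into fixed-length overlapping windows
#'
#' Splits the magnitude streams of a series into windows of `window_s`
#' seconds with fractional overlap `overlap_frac` (default 50%: hop = half
#' the window). Window k covers samples `(k-1)*h + 1 ... (k-1)*h + w` with
#' `w = round(window_s * rate)` and `h = round(w * (1 - overlap_frac))`,
#' so the window count is `floor((N - w)/h) + 1` (0 when N < w).
#'
#' A window is labelled with state b when intervals of b cover strictly
#' more than half of the window's time span; otherwise it is unlabelled
#' (`NA`). Unlabelled windows are excluded from classifier training but
#' retained, e.g. as the non-play pool for quantification.
#'
#' @param series An [imu_series()].
#' @param track Optional [label_track()] used to label windows.
#' @param window_s Window length in seconds, in \[1, 10\].
#' @param overlap_frac Fractional overlap between consecutive windows.
#'
#' @return An object of class `window_set`: a list with
#'   \describe{
#'     \item{accel_mag, gyro_mag}{`w x K` matrices, one column per window.}
#'     \item{info}{data.frame with `animal_id`, `start_s`, `length_s`,
#'       `label` per window.}
#'     \item{sample_rate, window_s}{scalars.}
#'   }
#'   With K = 0 the matrices have zero columns (a short series is not an
#'   error).
#' @export
discretize <- function(series, track = NULL, window_s,
                       overlap_frac = 0.5) {
  stopifnot(inherits(series, "imu_series"))
  if (window_s < 1 || window_s > 10) {
    stop("window_s must lie in [1, 10] seconds", call. = FALSE)
  }
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must lie in [0, 1)", call. = FALSE)
  }
  rate <- series$sample_rate
  w <- as.integer(round(window_s * rate))
  h <- as.integer(round(w * (1 - overlap_frac)))
  if (h < 1L) stop("hop must be at least one sample", call. = FALSE)
  n <- length(series$ax)
  k <- if (n < w) 0L else as.integer((n - w) %/% h + 1L)
  mags <- series_magnitudes(series)
  starts <- (seq_len(k) - 1L) * h # 0-based sample offsets
  if (k > 0L) {
    idx <- outer(seq_len(w), starts, `+`)
    accel_mag <- matrix(mags$accel[idx], nrow = w)
    gyro_mag <- matrix(mags$gyro[idx], nrow = w)
  } else {
    accel_mag <- gyro_mag <- matrix(numeric(0), nrow = w, ncol = 0)
  }
  label <- rep(NA_character_, k)
  if (!is.null(track) && k > 0L) {
    label <- .label_windows(track, starts / rate, window_s)
  }
  info <- data.frame(
    animal_id = rep(series$animal_id, k),
    start_s = starts / rate,
    length_s = rep(window_s, k),
    label = label,
    stringsAsFactors = FALSE
  )
  structure(list(accel_mag = accel_mag, gyro_mag = gyro_mag, info = info,
                 sample_rate = rate, window_s = window_s),
            class = "window_set")
}

# Majority-coverage labelling: state b wins iff its intervals cover
# > 50% of the window span. Vectorised over windows via per-state
# cumulative coverage evaluated at window edges.
.label_windows <- function(track, win_start_s, window_s) {
  k <- length(win_start_s)
  win_stop_s <- win_start_s + window_s
  states <- unique(track$behaviour)
  best_cov <- numeric(k)
  best_state <- rep(NA_character_, k)
  for (st in states) {
    iv <- track[track$behaviour == st, , drop = FALSE]
    # covered(t) = total time of iv's union below t
    #            = sum over intervals of clamp(t - start, 0, stop - start);
    # intervals are disjoint so the sum is exact
    covered <- function(t) {
      m <- outer(t, iv$start_s, `-`)
      len <- iv$stop_s - iv$start_s
      m <- pmin(pmax(m, 0), rep(len, each = length(t)))
      rowSums(matrix(m, nrow = length(t)))
    }
    cov <- covered(win_stop_s) - covered(win_start_s)
    take <- cov > best_cov
    best_cov[take] <- cov[take]
    best_state[take] <- st
  }
  best_state[best_cov <= window_s / 2] <- NA_character_
  best_state
}

#' Combine window sets from several animals
#'
#' @param ... `window_set` objects with identical `window_s` and
#'   `sample_rate`.
#' @return A single `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  stopifnot(all(vapply(sets, inherits, TRUE, "window_set")))
  ws <- unique(vapply(sets, `[[`, 0, "window_s"))
  sr <- unique(vapply(sets, `[[`, 0, "sample_rate"))
  if (length(ws) != 1L || length(sr) != 1L) {
    stop("window sets must share window_s and sample_rate", call. = FALSE)
  }
  structure(list(
    accel_mag = do.call(cbind, lapply(sets, `[[`, "accel_mag")),
    gyro_mag = do.call(cbind, lapply(sets, `[[`, "gyro_mag")),
    info = do.call(rbind, lapply(sets, `[[`, "info")),
    sample_rate = sr, window_s = ws
  ), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s at %g Hz (%d labelled)\n",
              nrow(x$info), x$window_s, x$sample_rate,
              sum(!is.na(x$info$label))))
  invisible(x)
}

#' Down-sample a 100 Hz series by stride decimation
#'
#' Keeps every d-th sample starting from the first, with
#' d = 100 / target_hz. Only the frequencies whose stride divides 100
#' evenly are supported: 50, 20, 10 and 4 Hz (strides 2, 5, 10, 25). The
#' output is a subsequence of the input of length `ceiling(N / d)`.
#'
#' @param series An [imu_series()] sampled at 100 Hz.
#' @param target_hz One of 50, 20, 10, 4.
#' @return A decimated [imu_series()] at `target_hz`.
#' @export
downsample <- function(series, target_hz) {
  stopifnot(inherits(series, "imu_series"))
  if (series$sample_rate != 100) {
    stop("downsample expects a 100 Hz input series", call. = FALSE)
  }
  strides <- c(`50` = 2L, `20` = 5L, `10` = 10L, `4` = 25L)
  key <- as.character(target_hz)
  if (!key %in% names(strides)) {
    stop("target_hz must be one of 50, 20, 10, 4", call. = FALSE)
  }
  d <- strides[[key]]
  keep <- seq(1L, length(series$ax), by = d)
  imu_series(series$animal_id, target_hz,
             ax = series$ax[keep], ay = series$ay[keep],
             az = series$az[keep],
             gx = series$gx[keep], gy = series$gy[keep],
             gz = series$gz[keep],
             timestamps = NULL)
}
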