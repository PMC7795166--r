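#' Default per-behaviour signal and bout regimes
#'
#' One row per ethogram behaviour describing (a) how long its bouts last
#' and how much of the timeline it occupies, and (b) what the collar
#' signal looks like while it is happening. The signal model per bout is
#' a gravity baseline (accelerometer only) plus an optional sinusoid at
#' `osc_freq_hz`, additive Gaussian noise, and Poisson-placed
#' high-amplitude transients ("bursts"). Amplitudes are in g for the
#' accelerometer and deg/s for the gyroscope.
#'
#' The defaults encode the qualitative contrasts a collar sensor sees:
#' non-active lying is quiet; active lying is low-level aperiodic head
#' movement; ruminating is slow regular jaw cycling (~1.2 Hz); grooming
#' is mid-rate licking; suckling is fast teat-work (several Hz, fastest
#' when milk is flowing); locomotor play is rare, short and dominated by
#' high-amplitude bursts. Time fractions sum to 1 with locomotor play at
#' 0.0027 (0.27% of windows), the low prevalence regime the
#' quantification algorithm is designed for. They are deliberate design
#' choices for a synthetic benchmark, not estimates of real calf signal
#' statistics.
#'
#' @return A data.frame with one row per behaviour and columns
#'   `behaviour`, `prevalence`, `mean_bout_s`, `sd_bout_s`,
#'   `accel_amp_g`, `gyro_amp_dps`, `osc_freq_hz`, `burst_prob`,
#'   `accel_noise_g`, `gyro_noise_dps`.
#' @export
default_regimes <- function() {
  path <- system.file("extdata", "default_regimes.yaml",
                      package = "calfwatch")
  read_regimes_yaml(path)
}

#' Read a regimes table from YAML
#'
#' @param path Path to a YAML file: a list of per-behaviour records with
#'   the fields of [default_regimes()].
#' @return A regimes data.frame.
#' @export
read_regimes_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(raw$regimes, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  validate_regimes(out)
  out
}

validate_regimes <- function(regimes, sample_rate = 100) {
  need <- c("behaviour", "prevalence", "mean_bout_s", "sd_bout_s",
            "accel_amp_g", "gyro_amp_dps", "osc_freq_hz", "burst_prob",
            "accel_noise_g", "gyro_noise_dps")
  miss <- setdiff(need, names(regimes))
  if (length(miss)) {
    stop("regimes table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(regimes$accel_amp_g < 0) || any(regimes$gyro_amp_dps < 0)) {
    stop("base amplitudes must be nonnegative", call. = FALSE)
  }
  if (any(regimes$osc_freq_hz < 0) ||
      any(regimes$osc_freq_hz >= sample_rate / 2)) {
    stop("osc_freq_hz must lie in [0, Nyquist)", call. = FALSE)
  }
  if (any(regimes$mean_bout_s < 3)) {
    stop("mean_bout_s must be >= 3 s (bouts shorter than 3 s are not ",
         "part of the ethogram)", call. = FALSE)
  }
  invisible(regimes)
}

#' Simulation configuration for synthetic multi-animal IMU datasets
#'
#' @param n_animals Number of animals (one recording file each).
#' @param duration_s Recording duration per animal, seconds.
#' @param sample_rate Sensor rate in Hz (default 100).
#' @param regimes Regimes table, see [default_regimes()]. Prevalences
#'   must sum to 1 (checked to 1e-6).
#' @param seed Integer master seed; every random draw derives from it so
#'   identical configs give byte-identical output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_animals, duration_s, sample_rate = 100,
                       regimes = default_regimes(), seed = 1L) {
  validate_regimes(regimes, sample_rate)
  if (abs(sum(regimes$prevalence) - 1) > 1e-6) {
    stop("regime prevalences must sum to 1 (got ",
         format(sum(regimes$prevalence)), ")", call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  structure(list(n_animals = as.integer(n_animals),
                 duration_s = duration_s,
                 sample_rate = sample_rate,
                 regimes = regimes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Per-animal derived seed, kept inside 32-bit integer range.
.animal_seed <- function(seed, animal_index, salt = 0L) {
  (as.integer(seed) * 1009L + animal_index * 97L + salt) %% 2147483629L
}

#' Generate a behaviour-bout sequence for one animal
#'
#' A semi-Markov chain: the next state is drawn with probability
#' proportional to `prevalence / mean_bout_s` (rate-correction, so the
#' long-run *time* fraction in each state converges to its prevalence),
#' excluding self-transitions; bout durations come from a log-normal
#' matched to (`mean_bout_s`, `sd_bout_s`) and truncated at 3 s, the
#' minimum bout length in the ethogram. The final bout is clipped so the
#' intervals tile `[0, duration_s]` exactly.
#'
#' @param config A [sim_config()].
#' @param animal_id Animal identifier (also indexes the derived RNG
#'   stream: animal k of a config always gets the same track).
#' @return A [label_track()] tiling the recording span.
#' @export
generate_bout_sequence <- function(config, animal_id) {
  stopifnot(inherits(config, "sim_config"))
  reg <- config$regimes
  if (config$duration_s < 3) {
    stop("duration_s too short to place one minimal (3 s) bout",
         call. = FALSE)
  }
  idx <- if (is.numeric(animal_id)) as.integer(animal_id) else
    sum(utf8ToInt(as.character(animal_id)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.animal_seed(config$seed, idx, salt = 1L))

  # log-normal parameters matched by moments to (mean, sd)
  sdlog <- sqrt(log(1 + (reg$sd_bout_s / reg$mean_bout_s)^2))
  meanlog <- log(reg$mean_bout_s) - sdlog^2 / 2
  # actual mean bout length after truncation at 3 s:
  # E[X | X >= a] for a log-normal
  trunc_mean <- ifelse(
    sdlog > 0,
    exp(meanlog + sdlog^2 / 2) *
      stats::pnorm((meanlog + sdlog^2 - log(3)) / sdlog) /
      pmax(stats::pnorm((meanlog - log(3)) / sdlog), 1e-12),
    pmax(reg$mean_bout_s, 3))
  # target share of *visits* per state so that the share of *time*
  # matches the configured prevalence
  visit_p <- reg$prevalence / trunc_mean
  visit_p <- visit_p / sum(visit_p)
  rate_w <- .self_excluded_weights(visit_p)

  starts <- numeric(0); stops <- numeric(0); states <- character(0)
  t <- 0
  prev <- 0L
  nstate <- nrow(reg)
  while (t < config$duration_s) {
    w <- rate_w
    if (prev > 0L && nstate > 1L) w[prev] <- 0
    s <- sample.int(nstate, 1L, prob = w)
    len <- stats::rlnorm(1, meanlog[s], sdlog[s])
    tries <- 0L
    while (len < 3 && tries < 100L) {      # truncate at the 3 s minimum
      len <- stats::rlnorm(1, meanlog[s], sdlog[s]); tries <- tries + 1L
    }
    len <- max(len, 3)
    stop_t <- min(t + len, config$duration_s)
    starts <- c(starts, t); stops <- c(stops, stop_t)
    states <- c(states, reg$behaviour[s])
    t <- stop_t
    prev <- s
  }
  # merge adjacent same-state bouts (arises when only one state exists)
  if (length(states) > 1L) {
    new_run <- c(TRUE, states[-1] != states[-length(states)])
    grp <- cumsum(new_run)
    starts <- tapply(starts, grp, min)
    stops <- tapply(stops, grp, max)
    states <- states[new_run]
  }
  label_track(animal_id, starts, stops, states,
              validate = all(reg$behaviour %in%
                               c(ethogram()$behaviours,
                                 ethogram()$postures)))
}

#' Synthesise the 6-channel sensor signal for a labelled track
#'
#' Within each bout the signal follows that behaviour's regime:
#' \itemize{
#'   \item accelerometer: a 1 g gravity baseline on the z axis, plus a
#'     sinusoid of amplitude `accel_amp_g` at `osc_freq_hz` split across
#'     the x/y axes, plus Gaussian noise of sd `accel_noise_g` on each
#'     axis, plus transient bursts;
#'   \item gyroscope: the same structure without gravity, with
#'     `gyro_amp_dps` / `gyro_noise_dps`.
#' }
#' Bursts model the brief high-amplitude transients of locomotor play:
#' events arrive as a Poisson process at `burst_prob` per second within
#' the bout and each adds a ~0.3 s Gaussian-envelope pulse of 3x the
#' base amplitude (floor of 1 g / 60 deg/s so purely bursty regimes are
#' visible) on one axis.
#'
#' @param track A [label_track()] tiling the recording span.
#' @param config The [sim_config()] that produced it.
#' @return An [imu_series()] at `config$sample_rate`.
#' @export
synthesize_signal <- function(track, config) {
  stopifnot(inherits(track, "label_track"), inherits(config, "sim_config"))
  reg <- config$regimes
  missing_state <- setdiff(unique(track$behaviour), reg$behaviour)
  if (length(missing_state)) {
    stop("no signal regime defined for state(s): ",
         paste(missing_state, collapse = ", "), call. = FALSE)
  }
  rate <- config$sample_rate
  n <- as.integer(round((max(track$stop_s) - min(track$start_s)) * rate))
  tt <- (seq_len(n) - 1L) / rate + min(track$start_s)

  aid <- attr(track, "animal_id")
  idx <- if (is.numeric(aid)) as.integer(aid) else
    sum(utf8ToInt(as.character(aid)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.animal_seed(config$seed, idx, salt = 2L))

  # per-sample regime parameter envelopes via rep() over bout lengths
  ri <- match(track$behaviour, reg$behaviour)
  bnd <- pmin(pmax(round((track$stop_s - min(track$start_s)) * rate), 0), n)
  lens <- diff(c(0L, as.integer(bnd)))
  if (sum(lens) != n) lens[length(lens)] <- lens[length(lens)] + n - sum(lens)
  # per-bout movement intensity: animals do not repeat a behaviour at a
  # fixed loudness, so every bout scales its regime amplitudes and noise
  # by a log-normal factor (sd 0.3 on the log scale); this gives
  # neighbouring behaviours honestly overlapping feature distributions
  intensity <- stats::rlnorm(nrow(track), 0, 0.3)
  env <- function(v) rep(v[ri], times = lens)
  ienv <- rep(intensity, times = lens)
  a_amp <- env(reg$accel_amp_g) * ienv
  g_amp <- env(reg$gyro_amp_dps) * ienv
  freq <- env(reg$osc_freq_hz)
  a_sd <- env(reg$accel_noise_g) * ienv
  g_sd <- env(reg$gyro_noise_dps) * ienv

  # per-bout random phase so windows are not phase-locked
  phase <- rep(stats::runif(nrow(track), 0, 2 * pi), times = lens)
  osc <- sin(2 * pi * freq * tt + phase)

  # part of the accel oscillation rides along gravity and the gyro
  # oscillation rides on a positive baseline, so the *magnitude*
  # streams oscillate at the regime frequency itself rather than at
  # its rectified double
  ax <- 0.35 * a_amp * osc + a_sd * stats::rnorm(n)
  ay <- a_sd * stats::rnorm(n)
  az <- 1 + 0.35 * a_amp * osc + a_sd * stats::rnorm(n)  # gravity ~1 g
  gx <- g_amp * (0.6 + 0.4 * osc) + g_sd * stats::rnorm(n)
  gy <- g_sd * stats::rnorm(n)
  gz <- g_sd * stats::rnorm(n)

  # Poisson bursts per bout
  bursty <- which(reg$burst_prob[ri] > 0 & lens > 0)
  if (length(bursty)) {
    half <- as.integer(round(0.15 * rate))          # ~0.3 s pulse
    pulse <- exp(-0.5 * ((-half:half) / (0.05 * rate))^2)
    offsets <- cumsum(c(0L, lens))[seq_along(lens)]
    for (b in bursty) {
      dur <- lens[b] / rate
      k <- stats::rpois(1, reg$burst_prob[ri[b]] * dur)
      if (k == 0) next
      centers <- offsets[b] + sample.int(lens[b], k, replace = TRUE)
      amp_a <- 3 * max(reg$accel_amp_g[ri[b]], 1) * intensity[b]
      amp_g <- 3 * max(reg$gyro_amp_dps[ri[b]], 60) * intensity[b]
      for (c0 in centers) {
        lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
        pw <- pulse[(lo - (c0 - half) + 1L):(hi - (c0 - half) + 1L)]
        sgn <- sample(c(-1, 1), 1)
        ax[lo:hi] <- ax[lo:hi] + sgn * amp_a * pw
        gy[lo:hi] <- gy[lo:hi] + sgn * amp_g * pw
      }
    }
  }
  imu_series(aid, rate, ax, ay, az, gx, gy, gz)
}

#' Simulate a labelled multi-animal IMU dataset
#'
#' @param config A [sim_config()].
#' @return A list with elements `tracks` (list of [label_track()]) and
#'   `series` (list of [imu_series()]), one per animal, named
#'   `animal_1 ... animal_n` (ids are the integers 1..n).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tracks <- lapply(seq_len(config$n_animals), function(i) {
    generate_bout_sequence(config, i)
  })
  series <- lapply(tracks, synthesize_signal, config = config)
  names(tracks) <- names(series) <- paste0("animal_", seq_along(tracks))
  list(tracks = tracks, series = series)
}

# Sampling weights v for a chain that forbids self-transitions
# (q_{i->j} = v_j / (1 - v_i), j != i). Its stationary visit
# distribution is pi_j  proportional to  v_j (1 - v_j); invert that so the
# realised visit shares equal the target p: v_j = (1 - sqrt(1 - 4 L p_j))/2
# with L chosen so the v_j sum to 1. When no solution exists (fewer
# than 3 states, or one state demanded in more than half of all
# visits) the uncorrected weights are returned.
.self_excluded_weights <- function(p) {
  if (length(p) < 3L) return(p)
  vfun <- function(lam) (1 - sqrt(pmax(1 - 4 * lam * p, 0))) / 2
  lam_max <- 1 / (4 * max(p))
  if (sum(vfun(lam_max)) < 1) return(p)
  lam <- stats::uniroot(function(l) sum(vfun(l)) - 1,
                        lower = 1e-12, upper = lam_max,
                        tol = 1e-14)$root
  vfun(lam)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
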