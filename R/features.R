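#' The 44-feature characteristic catalogue
#'
#' Features are computed on the acceleration-magnitude and
#' gyroscope-magnitude streams of each window, for both the raw stream
#' and its first difference, in the time and frequency domains. Per
#' stream (accel/gyro x raw/difference = 4 streams) the 11 statistics
#' are:
#' time domain: mean, minimum, maximum, kurtosis, zero-crossing count,
#' signal area; frequency domain (one-sided periodogram, zero-frequency
#' bin excluded): spectral entropy, spectrum minimum, spectrum first
#' quartile, spectrum mean-crossing count, spectrum area. 4 x 11 = 44.
#'
#' Extraction is name-keyed, so a reordered catalogue yields the same
#' values under the same names.
#'
#' @return A data.frame with 44 rows and columns `name`, `modality`
#'   (accel/gyro), `stream` (raw/difference), `domain` (time/frequency),
#'   `statistic`.
#' @export
feature_catalogue <- function() {
  stats_time <- c("mean", "min", "max", "kurtosis", "zero_crossings",
                  "signal_area")
  stats_freq <- c("spectral_entropy", "spec_min", "spec_q1",
                  "spec_mean_crossings", "spec_area")
  grid <- expand.grid(statistic = c(stats_time, stats_freq),
                      stream = c("raw", "difference"),
                      modality = c("accel", "gyro"),
                      stringsAsFactors = FALSE)
  grid$domain <- ifelse(grid$statistic %in% stats_time, "time",
                        "frequency")
  grid$name <- paste(grid$modality,
                     ifelse(grid$stream == "raw", "raw", "diff"),
                     grid$statistic, sep = "_")
  out <- grid[, c("name", "modality", "stream", "domain", "statistic")]
  validate_catalogue(out)
  out
}

#' Read a feature catalogue from YAML
#'
#' @param path YAML file holding a list `features` of records with the
#'   columns of [feature_catalogue()].
#' @return A validated catalogue data.frame.
#' @export
read_catalogue_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(raw$features, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  validate_catalogue(out)
  out
}

validate_catalogue <- function(cat) {
  if (nrow(cat) != 44L) {
    stop("feature catalogue must have exactly 44 entries (got ",
         nrow(cat), ")", call. = FALSE)
  }
  if (anyDuplicated(cat$name)) {
    stop("feature names must be unique", call. = FALSE)
  }
  tab <- table(cat$modality)
  if (!all(sort(names(tab)) == c("accel", "gyro")) || !all(tab == 22L)) {
    stop("catalogue must hold 22 accel and 22 gyro features",
         call. = FALSE)
  }
  invisible(cat)
}

#' First difference of a signal
#'
#' @param signal Numeric vector, length >= 2.
#' @return Vector of consecutive differences, length n - 1.
#' @export
first_difference <- function(signal) {
  if (length(signal) < 2L) {
    stop("first_difference needs at least 2 samples", call. = FALSE)
  }
  diff(signal)
}

#' Mean-crossing count of a signal
#'
#' Number of sign changes of `signal - mean(signal)` between consecutive
#' samples (the classic "zero crossings" activity feature; crossing the
#' mean rather than literal zero makes it offset-invariant, which
#' matters for the gravity-offset accelerometer magnitude).
#'
#' @param signal Numeric vector, length >= 2.
#' @return Integer count in `0 .. length(signal) - 1`.
#' @export
zero_crossings <- function(signal) {
  if (length(signal) < 2L) {
    stop("zero_crossings needs at least 2 samples", call. = FALSE)
  }
  b <- (signal - mean(signal)) > 0
  sum(b[-1] != b[-length(b)])
}

#' Rectified signal area
#'
#' Rectangular integration of |signal| over time: `sum(|s|) / rate`,
#' i.e. the area under the rectified signal in (units x seconds).
#'
#' @param signal Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @return Nonnegative scalar.
#' @export
signal_area <- function(signal, sample_rate) {
  sum(abs(signal)) / sample_rate
}

#' Normalised spectral entropy
#'
#' Shannon entropy of the unit-normalised one-sided periodogram
#' (rectangular taper, zero-frequency bin excluded), divided by the log
#' of the number of bins: 1 for a flat (white) spectrum, near 0 for a
#' single-bin (pure tone) spectrum. A zero-power (constant) signal is
#' defined to have entropy 0.
#'
#' @param signal Numeric vector, length >= 4.
#' @param sample_rate Sampling rate in Hz (retained for interface
#'   symmetry; entropy itself is rate-free).
#' @return Scalar in \[0, 1\].
#' @export
spectral_entropy <- function(signal, sample_rate = 100) {
  n <- length(signal)
  if (n < 4L) {
    stop("spectral_entropy needs at least 4 samples", call. = FALSE)
  }
  p <- .periodogram(matrix(signal, ncol = 1))[, 1]
  tot <- sum(p)
  if (tot <= .spec_floor(signal)) return(0)
  q <- p / tot
  q <- q[q > 0]
  if (length(q) < 2L) return(0)
  -sum(q * log(q)) / log(length(p))
}

# Numerical floor below which a spectrum is treated as zero-power
# (guards against fft round-off on constant signals).
.spec_floor <- function(signal) 1e-18 * max(1, mean(signal)^2)

# One-sided periodogram columns of M (w x K), DC bin excluded:
# P_k = |X_k|^2 / w for k = 1 .. floor(w/2).
.periodogram <- function(M) {
  w <- nrow(M)
  X <- stats::mvfft(M)
  kmax <- w %/% 2L
  (Mod(X[2:(kmax + 1L), , drop = FALSE])^2) / w
}

# Columnwise sort via a single global order (fast path for quartiles).
.col_sorted <- function(M) {
  matrix(M[order(col(M), M)], nrow = nrow(M))
}

# 11 statistics for every column of a w x K stream matrix.
# Returns a K x 11 matrix with the statistic names of the catalogue.
# Large inputs are processed in column blocks to keep the intermediate
# matrices cache- and allocator-friendly.
.col_features <- function(M, sample_rate, block = 8192L) {
  w <- nrow(M); k <- ncol(M)
  stats_names <- c("mean", "min", "max", "kurtosis", "zero_crossings",
                   "signal_area", "spectral_entropy", "spec_min",
                   "spec_q1", "spec_mean_crossings", "spec_area")
  if (k == 0L) {
    return(matrix(numeric(0), 0, 11,
                  dimnames = list(NULL, stats_names)))
  }
  if (w < 4L) {
    stop("windows must hold at least 4 samples per stream ",
         "(spectral features undefined below that)", call. = FALSE)
  }
  if (k > block) {
    out <- matrix(NA_real_, k, 11, dimnames = list(NULL, stats_names))
    for (s in seq(1L, k, by = block)) {
      e <- min(s + block - 1L, k)
      out[s:e, ] <- .col_features(M[, s:e, drop = FALSE], sample_rate,
                                  block = block)
    }
    return(out)
  }
  cm <- colMeans(M)
  Mc <- M - rep(cm, each = w)
  Mc2 <- Mc * Mc
  m2 <- colMeans(Mc2)
  m4 <- colMeans(Mc2 * Mc2)
  degen <- m2 <= 1e-24 * pmax(1, cm^2)
  kurt <- m4 / (m2 * m2 + degen)  # degen adds 1 to avoid 0/0
  kurt[degen] <- 0
  pos <- Mc > 0
  zc <- colSums(pos[-1L, , drop = FALSE] != pos[-w, , drop = FALSE])
  # columnwise min/max by repeated halving (log2(w) full-matrix pmin/pmax
  # passes instead of a per-row loop)
  Lo <- Hi <- M
  while (nrow(Lo) > 1L) {
    n1 <- nrow(Lo); half <- n1 %/% 2L
    top <- seq_len(half)
    Lo2 <- pmin(Lo[top, , drop = FALSE], Lo[half + top, , drop = FALSE])
    Hi2 <- pmax(Hi[top, , drop = FALSE], Hi[half + top, , drop = FALSE])
    if (n1 %% 2L) {
      Lo2[1L, ] <- pmin(Lo2[1L, ], Lo[n1, ])
      Hi2[1L, ] <- pmax(Hi2[1L, ], Hi[n1, ])
    }
    Lo <- Lo2; Hi <- Hi2
  }
  colmin <- as.numeric(Lo); colmax <- as.numeric(Hi)
  area <- colSums(abs(M)) / sample_rate

  P <- .periodogram(M)
  nb <- nrow(P)
  ptot <- colSums(P)
  pdegen <- ptot <= 1e-18 * pmax(1, cm^2)
  Q <- P / rep(ptot + pdegen, each = nb)
  Ql <- Q * log(Q)
  Ql[Q <= 0] <- 0
  sent <- -colSums(Ql) / log(max(nb, 2L))
  sent[pdegen | nb < 2L] <- 0
  ppos <- (P - rep(colMeans(P), each = nb)) > 0
  pzc <- if (nb >= 2L) {
    colSums(ppos[-1L, , drop = FALSE] != ppos[-nb, , drop = FALSE])
  } else rep(0, k)
  Ps <- .col_sorted(P)
  # first quartile, linear interpolation between order statistics
  hq <- (nb - 1) * 0.25 + 1
  lo <- floor(hq); frac <- hq - lo
  q1 <- Ps[lo, ] * (1 - frac) +
    (if (lo < nb) Ps[lo + 1L, ] else Ps[lo, ]) * frac
  sarea <- ptot * sample_rate / w  # integral over Hz of the periodogram

  out <- cbind(mean = cm, min = colmin, max = colmax, kurtosis = kurt,
               zero_crossings = zc, signal_area = area,
               spectral_entropy = sent, spec_min = Ps[1L, ],
               spec_q1 = q1, spec_mean_crossings = pzc,
               spec_area = sarea)
  out[, stats_names, drop = FALSE]
}

#' Extract the 44-feature vector for every window of a window set
#'
#' @param windows A `window_set` from [discretize()] or
#'   [bind_window_sets()] with at least 4 samples per window.
#' @param catalogue A feature catalogue (default [feature_catalogue()]).
#' @return A data.frame: the window `info` columns (`animal_id`,
#'   `start_s`, `length_s`, `label`) followed by one named column per
#'   catalogue feature, rows aligned with the windows.
#' @export
extract_features <- function(windows, catalogue = feature_catalogue()) {
  stopifnot(inherits(windows, "window_set"))
  validate_catalogue(catalogue)
  rate <- windows$sample_rate
  per_stream <- list(
    accel_raw = .col_features(windows$accel_mag, rate),
    accel_diff = .col_features(.diff_matrix(windows$accel_mag), rate),
    gyro_raw = .col_features(windows$gyro_mag, rate),
    gyro_diff = .col_features(.diff_matrix(windows$gyro_mag), rate)
  )
  k <- nrow(windows$info)
  feats <- matrix(NA_real_, k, nrow(catalogue),
                  dimnames = list(NULL, catalogue$name))
  for (i in seq_len(nrow(catalogue))) {
    stream_key <- paste0(catalogue$modality[i], "_",
                         ifelse(catalogue$stream[i] == "raw",
                                "raw", "diff"))
    feats[, i] <- per_stream[[stream_key]][, catalogue$statistic[i]]
  }
  cbind(windows$info, as.data.frame(feats))
}

.diff_matrix <- function(M) {
  w <- nrow(M)
  if (w < 2L) stop("difference stream needs >= 2 samples", call. = FALSE)
  M[-1L, , drop = FALSE] - M[-w, , drop = FALSE]
}

#' Names of the feature columns in an extracted feature table
#'
#' @param features A data.frame from [extract_features()].
#' @return Character vector of the 44 feature column names.
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("animal_id", "start_s", "length_s", "label"))
}
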