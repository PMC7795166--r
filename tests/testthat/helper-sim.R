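# Shared fixtures: regime tables and tiny configs built in code.

# Single-state regime table (prevalence 1) for a named behaviour.
one_state_regimes <- function(behaviour = "non-active lying",
                              accel_amp_g = 0, gyro_amp_dps = 0,
                              osc_freq_hz = 0, burst_prob = 0,
                              accel_noise_g = 0, gyro_noise_dps = 0,
                              mean_bout_s = 60, sd_bout_s = 10) {
  data.frame(behaviour = behaviour, prevalence = 1,
             mean_bout_s = mean_bout_s, sd_bout_s = sd_bout_s,
             accel_amp_g = accel_amp_g, gyro_amp_dps = gyro_amp_dps,
             osc_freq_hz = osc_freq_hz, burst_prob = burst_prob,
             accel_noise_g = accel_noise_g,
             gyro_noise_dps = gyro_noise_dps,
             stringsAsFactors = FALSE)
}

# Pull one behaviour's row from the shipped defaults and make it the
# only state.
solo_regime <- function(behaviour) {
  r <- default_regimes()
  r <- r[r$behaviour == behaviour, , drop = FALSE]
  r$prevalence <- 1
  r
}

# A constant-signal series: accel magnitude 1 g (gravity on z), gyro 0.
constant_series <- function(n = 400, sample_rate = 100, animal_id = "c") {
  z <- rep(0, n)
  imu_series(animal_id, sample_rate, ax = z, ay = z, az = rep(1, n),
             gx = z, gy = z, gz = z)
}

# A deterministic toy series whose channels are arbitrary smooth signals.
toy_series <- function(n = 1200, sample_rate = 100, animal_id = "t") {
  tt <- (seq_len(n) - 1) / sample_rate
  imu_series(animal_id, sample_rate,
             ax = sin(2 * pi * 1.5 * tt), ay = 0.3 * cos(2 * pi * 2 * tt),
             az = 1 + 0.1 * sin(2 * pi * 0.5 * tt),
             gx = 20 * sin(2 * pi * 3 * tt), gy = rep(2, n),
             gz = 5 * cos(2 * pi * 1 * tt))
}

# Feature table with given per-(file, behaviour) counts; columns mimic
# an extract_features() output with two dummy feature columns.
counts_table <- function(counts) {
  # counts: data.frame(animal_id, label, n)
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    data.frame(animal_id = counts$animal_id[i],
               start_s = seq_len(n), length_s = 3,
               label = counts$label[i],
               f1 = stats::runif(n), f2 = stats::runif(n),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

# Two/three-class Gaussian feature sets for classifier tests.
gaussian_classes <- function(n_per = 100, centers = c(0, 3, 6),
                             p = 4, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(cc) {
    matrix(stats::rnorm(n_per * p, mean = cc, sd = sd), n_per, p)
  }))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = as.data.frame(X),
       y = factor(rep(paste0("class", seq_along(centers)),
                      each = n_per)))
}
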