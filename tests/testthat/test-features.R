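test_that("the catalogue holds 44 uniquely named, evenly split features", {
  cat44 <- feature_catalogue()
  expect_equal(nrow(cat44), 44L)
  expect_equal(anyDuplicated(cat44$name), 0L)
  expect_equal(as.vector(table(cat44$modality)), c(22L, 22L))
  bad <- cat44[-1, ]
  expect_error(validate_catalogue(bad), "44")
  dup <- cat44; dup$name[2] <- dup$name[1]
  expect_error(validate_catalogue(dup), "unique")
})

test_that("the shipped catalogue YAML matches the in-code catalogue", {
  path <- system.file("extdata", "feature_catalogue.yaml",
                      package = "calfwatch")
  expect_equal(read_catalogue_yaml(path), feature_catalogue(),
               ignore_attr = TRUE)
})

test_that("first_difference matches its definition", {
  expect_equal(first_difference(c(1, 1, 1)), c(0, 0))
  expect_equal(first_difference(c(0, 1, 3)), c(1, 2))
  ramp <- seq(0, 10, by = 0.5)
  expect_equal(first_difference(ramp), rep(0.5, length(ramp) - 1))
  expect_error(first_difference(3), "2 samples")
})

test_that("zero_crossings counts mean-crossing sign changes", {
  expect_equal(zero_crossings(rep(5, 10)), 0L)
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3L)
  tt <- seq(0, 5 - 1e-9, by = 1 / 200)   # 5 full cycles of a 1 Hz sine
  expect_equal(zero_crossings(sin(2 * pi * tt + 0.3)), 10L)
})

test_that("signal_area integrates the rectified signal over time", {
  expect_equal(signal_area(rep(1, 300), 100), 3)
  expect_equal(signal_area(rep(0, 50), 100), 0)
  expect_equal(signal_area(rep(2, 4), 4), 2)
  expect_equal(signal_area(c(-1, 1, -1, 1), 4), 1)
})

test_that("spectral entropy separates tones, noise and silence", {
  n <- 256
  tt <- (seq_len(n) - 1) / 100
  tone <- sin(2 * pi * (100 * 8 / n) * tt)   # exactly bin 8
  expect_lt(spectral_entropy(tone, 100), 0.2)
  expect_equal(spectral_entropy(rep(3, n), 100), 0)
  ent <- vapply(1:5, function(s) {
    set.seed(s); spectral_entropy(rnorm(1024), 100)
  }, 0)
  expect_true(all(ent > 0.9))
  expect_error(spectral_entropy(1:3, 100), "4 samples")
})

test_that("constant windows produce the degenerate-case feature values", {
  ws <- discretize(constant_series(400), NULL, 3)
  f <- extract_features(ws)
  expect_equal(f$accel_raw_mean, rep(1, nrow(f)))
  expect_equal(f$accel_raw_min, rep(1, nrow(f)))
  expect_equal(f$accel_raw_max, rep(1, nrow(f)))
  expect_equal(f$accel_raw_kurtosis, rep(0, nrow(f)))      # flagged 0
  expect_equal(f$accel_raw_zero_crossings, rep(0, nrow(f)))
  expect_equal(f$accel_raw_spectral_entropy, rep(0, nrow(f)))
  expect_equal(f$accel_raw_signal_area, rep(3, nrow(f)))
  expect_equal(f$accel_diff_mean, rep(0, nrow(f)))
  expect_equal(f$accel_diff_signal_area, rep(0, nrow(f)))
  expect_equal(f$gyro_raw_mean, rep(0, nrow(f)))
})

test_that("a periodic gyro window has lower spectral entropy than noise", {
  cfg <- sim_config(1, 30, regimes = solo_regime("ruminating"), seed = 8)
  s1 <- simulate_dataset(cfg)$series[[1]]
  f1 <- extract_features(discretize(s1, NULL, 3))
  cfg2 <- sim_config(1, 30,
                     regimes = one_state_regimes(gyro_noise_dps = 10),
                     seed = 8)
  s2 <- simulate_dataset(cfg2)$series[[1]]
  f2 <- extract_features(discretize(s2, NULL, 3))
  expect_lt(mean(f1$gyro_raw_spectral_entropy),
            mean(f2$gyro_raw_spectral_entropy))
})

test_that("extraction is name-keyed: a reordered catalogue agrees", {
  ws <- discretize(toy_series(), NULL, 3)
  cat44 <- feature_catalogue()
  set.seed(1)
  shuffled <- cat44[sample.int(nrow(cat44)), ]
  f1 <- extract_features(ws, cat44)
  f2 <- extract_features(ws, shuffled)
  for (nm in cat44$name) expect_equal(f2[[nm]], f1[[nm]])
})

test_that("features are invariant to axis permutation and sign flips", {
  s <- toy_series()
  sp <- imu_series("t", 100, ax = -s$ay, ay = s$az, az = s$ax,
                   gx = s$gz, gy = -s$gx, gz = s$gy)
  f1 <- extract_features(discretize(s, NULL, 3))
  f2 <- extract_features(discretize(sp, NULL, 3))
  for (nm in feature_names(f1)) expect_equal(f2[[nm]], f1[[nm]])
})

test_that("amplitude features scale with gain; shape features do not", {
  s <- toy_series()
  g <- 2.5
  sg <- imu_series("t", 100, ax = g * s$ax, ay = g * s$ay,
                   az = g * s$az, gx = g * s$gx, gy = g * s$gy,
                   gz = g * s$gz)
  f1 <- extract_features(discretize(s, NULL, 3))
  f2 <- extract_features(discretize(sg, NULL, 3))
  for (nm in grep("_(raw|diff)_(mean|min|max|signal_area)$",
                  feature_names(f1), value = TRUE)) {
    expect_equal(f2[[nm]], g * f1[[nm]], tolerance = 1e-10)
  }
  for (nm in grep("_spec_area$", feature_names(f1), value = TRUE)) {
    expect_equal(f2[[nm]], g^2 * f1[[nm]], tolerance = 1e-10)
  }
  for (nm in grep("_(kurtosis|zero_crossings|spectral_entropy)$",
                  feature_names(f1), value = TRUE)) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-10)
  }
})
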