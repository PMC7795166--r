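# Small labelled play/non-play feature pools (Gaussian features; the
# full signal pipeline is exercised in the acceptance suite).
play_pool <- function(n_pos, n_neg, sep = 4, seed = 1, files = 3) {
  set.seed(seed)
  n <- n_pos + n_neg
  lab <- c(rep("locomotor play", n_pos), rep(NA_character_, n_neg))
  mu <- ifelse(is.na(lab), 0, sep)
  d <- data.frame(animal_id = sample(paste0("f", seq_len(files)), n,
                                     replace = TRUE),
                  start_s = seq_len(n), length_s = 3, label = lab,
                  f1 = rnorm(n, mu, 1), f2 = rnorm(n, mu / 2, 1),
                  f3 = rnorm(n), f4 = rnorm(n),
                  stringsAsFactors = FALSE)
  d[sample.int(n), ]
}

test_that("adjust_prevalence implements the corrected estimate", {
  expect_equal(adjust_prevalence(0.5, 1, 0), 0.5)
  expect_equal(adjust_prevalence(0.001, 0.8, 0.001), 0)
  expect_equal(adjust_prevalence(0.0032, 0.8, 0.001),
               (0.0032 - 0.001) / 0.799)
  expect_equal(adjust_prevalence(0.0005, 0.9, 0.001), 0)   # clipped at 0
  expect_equal(adjust_prevalence(0.99, 0.7, 0.2), 1)       # clipped at 1
  expect_error(adjust_prevalence(0.5, 0.3, 0.3), "uninformative")
  expect_error(adjust_prevalence(0.5, 0.2, 0.4), "uninformative")
})

test_that("forward corruption then adjustment recovers prevalence", {
  set.seed(21)
  for (i in 1:200) {
    tpr <- runif(1, 0.55, 1); fpr <- runif(1, 0, 0.45)
    if (tpr <= fpr) next
    p <- runif(1)
    p0 <- p * tpr + (1 - p) * fpr
    expect_equal(adjust_prevalence(p0, tpr, fpr), p,
                 tolerance = 1e-12)
  }
})

test_that("the adjusted prevalence is monotone in the raw estimate", {
  p0 <- seq(0.1, 0.9, by = 0.1)
  ps <- adjust_prevalence(p0, 0.85, 0.05)
  expect_true(all(diff(ps) > 0))
})

test_that("overestimation accounting matches its definition", {
  o <- overestimation(195, 232)
  expect_equal(o$absolute, 37)
  expect_equal(o$percent, 100 * 37 / 195)
  expect_equal(overestimation(10, 10), list(absolute = 0, percent = 0,
                                            infinite = FALSE))
  u <- overestimation(200, 150)
  expect_equal(u$absolute, -50)
  expect_equal(u$percent, -25)
  z <- overestimation(0, 5)
  expect_true(z$infinite)
  expect_equal(z$percent, Inf)
  expect_equal(overestimation(0, 0)$percent, 0)
  expect_error(overestimation(-1, 5), ">= 0")
})

test_that("estimate_rates pools fold counts consistently", {
  d <- play_pool(40, 400, seed = 5)
  y <- binary_labels(d$label)
  cond <- training_condition(30, 300, seed = 9)
  r <- estimate_rates(d[, c("f1", "f2", "f3", "f4")], y, cond,
                      params = ensemble_params(n_learners = 5))
  expect_equal(unname(r$counts["tp"] + r$counts["fn"]), 30)
  expect_equal(unname(r$counts["fp"] + r$counts["tn"]), 300)
  expect_equal(r$tpr,
               unname(r$counts["tp"] / (r$counts["tp"] + r$counts["fn"])))
  expect_equal(r$fpr,
               unname(r$counts["fp"] / (r$counts["fp"] + r$counts["tn"])))
  # well-separated classes: near-oracle rates
  expect_gte(r$tpr, 0.85)
  expect_lt(r$fpr, 0.05)
  expect_error(estimate_rates(d[, 5:8], y, training_condition(100, 300)),
               "positives")
})

test_that("the condition sweep returns the tpr - fpr argmax", {
  d <- play_pool(60, 600, seed = 6)
  y <- binary_labels(d$label)
  sw <- sweep_conditions(d[, c("f1", "f2", "f3", "f4")], y,
                         p_grid = c(10, 25, 40), np = 400, seed = 3,
                         params = ensemble_params(n_learners = 5))
  best_val <- sw$best_rates$tpr - sw$best_rates$fpr
  expect_true(all(best_val >= sw$sweep$tpr_minus_fpr))
  # on a perfectly separable pool several conditions tie at 1;
  # the tie breaks towards the smallest p
  d2 <- play_pool(60, 600, sep = 30, seed = 7)
  y2 <- binary_labels(d2$label)
  sw2 <- sweep_conditions(d2[, c("f1", "f2", "f3", "f4")], y2,
                          p_grid = c(10, 25, 40), np = 400, seed = 3,
                          params = ensemble_params(n_learners = 5))
  expect_equal(max(sw2$sweep$tpr_minus_fpr), 1)
  expect_equal(sw2$best$p,
               min(sw2$sweep$p[sw2$sweep$tpr_minus_fpr == 1]))
})

test_that("quantify reports adjusted counts and per-file accounting", {
  train <- play_pool(60, 2000, seed = 8)
  test <- play_pool(25, 3000, seed = 9, files = 4)
  res <- quantify(train, test, p_grid = c(20, 40), np = 1000, seed = 2,
                  params = ensemble_params(n_learners = 5))
  expect_s3_class(res, "quantification_result")
  expect_equal(res$n_test, nrow(test))
  expect_equal(res$observed_count, 25)
  expect_equal(res$p0_prime, res$raw_count / res$n_test)
  expect_equal(res$adjusted_count,
               as.integer(round(res$p_prime * res$n_test)))
  # per-file accounting adds up
  pf <- res$per_file
  expect_equal(sum(pf$observed_count), res$observed_count)
  expect_equal(sum(pf$n), res$n_test)
  expect_equal(sum(pf$over),
               sum(pf$adjusted_count) - sum(pf$observed_count))
  # a separable pool recovers the truth closely
  expect_lt(abs(res$adjusted_count - 25), 15)
})

test_that("oracle-rate adjusted counts are unbiased and beat raw counts", {
  # binomial test-set simulation with known rates
  tpr <- 0.85; fpr <- 0.01; n <- 20000
  for (p in c(0.001, 0.0027, 0.01, 0.05)) {
    set.seed(round(1e4 * p) + 17)
    npos <- round(p * n)
    reps <- 200
    p_adj <- p_raw <- numeric(reps)
    for (i in seq_len(reps)) {
      pos_hits <- rbinom(1, npos, tpr)
      neg_hits <- rbinom(1, n - npos, fpr)
      p_raw[i] <- (pos_hits + neg_hits) / n
      p_adj[i] <- adjust_prevalence(p_raw[i], tpr, fpr)
    }
    se <- sd(p_adj) / sqrt(reps)
    expect_lt(abs(mean(p_adj) - npos / n), 3 * se + 1e-6)
    # dominance in mean absolute error whenever fpr > 0
    expect_lt(mean(abs(p_adj - npos / n)), mean(abs(p_raw - npos / n)))
  }
})
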