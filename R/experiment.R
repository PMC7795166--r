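#' Window features for a whole simulated dataset
#'
#' Convenience driver: simulate every animal of a config, discretise
#' with 50% overlap and extract the 44 features, animal by animal (to
#' bound memory), returning one stacked feature table.
#'
#' @param config A [sim_config()].
#' @param window_s Window length in seconds (default 3).
#' @return A feature data.frame as from [extract_features()].
#' @export
simulate_features <- function(config, window_s = 3) {
  stopifnot(inherits(config, "sim_config"))
  parts <- vector("list", config$n_animals)
  for (i in seq_len(config$n_animals)) {
    track <- generate_bout_sequence(config, i)
    series <- synthesize_signal(track, config)
    parts[[i]] <- extract_features(discretize(series, track, window_s))
  }
  do.call(rbind, parts)
}

#' Replicated adjusted-count vs classify-and-count experiment
#'
#' Deployment-style evaluation of the adjusted-count quantifier on
#' synthetic data at low play prevalence. One training dataset is
#' simulated and the tpr - fpr-maximising training condition selected
#' by [sweep_conditions()]; the binary ensemble is retrained on that
#' condition's draw. Then `n_replicates` independent test datasets of
#' the same size are simulated, and for each the raw classify-and-count
#' estimate and the adjusted count are compared with the observed play
#' windows.
#'
#' @param n_replicates Number of independent test datasets.
#' @param n_animals,duration_s Size of each dataset (train and test);
#'   defaults 7 animals x 4 h at 100 Hz, about 67,000 3-s windows.
#' @param window_s Window length (default 3 s).
#' @param regimes Regime table (default [default_regimes()], play
#'   prevalence 0.27%).
#' @param p_grid,np Training-condition grid; p values exceeding the
#'   positives available in the training pool are dropped.
#' @param params [ensemble_params()] for every fit.
#' @param seed Master seed.
#' @return List with `condition`, `tpr`, `fpr`, `sweep`,
#'   `n_train_positives` and `replicates`, a data.frame with one row
#'   per test replicate: `n_windows`, `observed`, `raw_count`,
#'   `adjusted_count`, `raw_err_pct`, `adj_err_pct` (signed relative
#'   errors in percent of the observed count).
#' @export
quantification_experiment <- function(n_replicates = 20L,
                                      n_animals = 7L,
                                      duration_s = 4 * 3600,
                                      window_s = 3,
                                      regimes = default_regimes(),
                                      p_grid = seq(10L, 190L, by = 10L),
                                      np = 10000L,
                                      params = ensemble_params(),
                                      seed = 1L) {
  seed <- as.integer(seed)
  train_cfg <- sim_config(n_animals, duration_s, regimes = regimes,
                          seed = (seed * 2L + 1L) %% 2147483629L)
  train <- simulate_features(train_cfg, window_s)
  fcols <- feature_names(train)
  ytr <- binary_labels(train$label)
  pos_lev <- levels(ytr)[2]
  n_pos <- sum(ytr == pos_lev)
  grid <- p_grid[p_grid <= n_pos]
  if (!length(grid)) {
    stop("training pool holds only ", n_pos, " positives; the whole ",
         "condition grid is infeasible", call. = FALSE)
  }
  sw <- sweep_conditions(train[, fcols], ytr, p_grid = grid, np = np,
                         seed = seed, params = params)
  cond <- sw$best
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cond$seed)
  take <- c(sample(which(ytr == pos_lev), cond$p),
            sample(which(ytr != pos_lev), cond$np))
  model <- train_ensemble(train[take, fcols], droplevels(ytr[take]),
                          params)
  tpr <- sw$best_rates$tpr; fpr <- sw$best_rates$fpr

  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    test_cfg <- sim_config(n_animals, duration_s, regimes = regimes,
                           seed = (seed * 1000L + 7L * r) %% 2147483629L)
    test <- simulate_features(test_cfg, window_s)
    yte <- binary_labels(test$label)
    pred <- predict(model, test[, fcols])
    n_w <- nrow(test)
    raw <- sum(pred == pos_lev)
    adj <- round(adjust_prevalence(raw / n_w, tpr, fpr) * n_w)
    obs <- sum(yte == pos_lev)
    reps[[r]] <- data.frame(
      replicate = r, n_windows = n_w, observed = obs, raw_count = raw,
      adjusted_count = adj,
      raw_err_pct = 100 * (raw - obs) / obs,
      adj_err_pct = 100 * (adj - obs) / obs)
  }
  list(condition = cond, tpr = tpr, fpr = fpr, sweep = sw$sweep,
       n_train_positives = n_pos,
       replicates = do.call(rbind, reps))
}
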