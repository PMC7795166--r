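#' Sampling-frequency degradation study
#'
#' Quantifies how much classification performance is lost when the
#' 100 Hz recordings are decimated to 50, 20, 10 and 4 Hz. For each
#' frequency the full pipeline is re-run from the raw series:
#' [downsample()], [discretize()], [extract_features()],
#' [balance_classes()] (rebalanced per frequency) and a k-fold
#' [cross_validate()]. The per-class decrease for metric m of class b is
#' reported relative to the 100 Hz value,
#' `100 * (m_100(b) - m_f(b)) / m_100(b)` (or as the absolute
#' percentage-point difference `100 * (m_100(b) - m_f(b))` with
#' `relative = FALSE`); a class whose 100 Hz metric is 0 gets `NA`.
#'
#' @param series_list List of 100 Hz [imu_series()] objects.
#' @param track_list Matching list of [label_track()] objects.
#' @param window_s Window length in seconds.
#' @param target_hz Frequencies to evaluate (subset of 50/20/10/4).
#' @param params [ensemble_params()] for every fit.
#' @param s_min Balancing budget (see [balance_classes()]).
#' @param k CV folds.
#' @param seed Seed for balancing and fold construction.
#' @param relative Relative (default) or absolute decrease.
#' @return A list with `decreases` (long data.frame: `target_hz`,
#'   `class`, `metric`, `value_100`, `value_target`, `decrease`) and
#'   `reports` (the fold-averaged `performance_report` per frequency,
#'   including `hz100`).
#' @export
frequency_study <- function(series_list, track_list, window_s = 3,
                            target_hz = c(50, 20, 10, 4),
                            params = ensemble_params(), s_min = "auto",
                            k = 5L, seed = 1L, relative = TRUE) {
  stopifnot(length(series_list) == length(track_list))
  run_at <- function(slist) {
    ws <- bind_window_sets(mapply(discretize, slist, track_list,
                                  MoreArgs = list(window_s = window_s),
                                  SIMPLIFY = FALSE))
    feats <- extract_features(ws)
    bal <- balance_classes(feats, s_min = s_min, seed = seed)
    cv <- cross_validate(bal[, feature_names(bal)], bal$label, k = k,
                         params = params, seed = seed)
    cv$report
  }
  reports <- list(hz100 = run_at(series_list))
  for (hz in target_hz) {
    reports[[paste0("hz", hz)]] <-
      run_at(lapply(series_list, downsample, target_hz = hz))
  }
  metric_cols <- c("accuracy", "specificity", "recall", "precision",
                   "f_score")
  base <- reports$hz100$per_class
  rows <- list()
  for (hz in target_hz) {
    cur <- reports[[paste0("hz", hz)]]$per_class
    stopifnot(identical(cur$class, base$class))
    for (mcol in metric_cols) {
      dec <- if (relative) {
        ifelse(base[[mcol]] == 0, NA_real_,
               100 * (base[[mcol]] - cur[[mcol]]) / base[[mcol]])
      } else {
        100 * (base[[mcol]] - cur[[mcol]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target_hz = hz, class = base$class, metric = mcol,
        value_100 = base[[mcol]], value_target = cur[[mcol]],
        decrease = dec, stringsAsFactors = FALSE)
    }
  }
  list(decreases = do.call(rbind, rows), reports = reports)
}
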