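#' Collapse behaviour labels to a positive/negative pair
#'
#' Every window not labelled with the positive behaviour -- including
#' unlabelled windows -- counts as negative, mirroring a deployment
#' setting where only the rare target behaviour is exhaustively
#' annotated.
#'
#' @param labels Character vector of window labels (may contain `NA`).
#' @param positive The positive class (default `"locomotor play"`).
#' @return Factor with levels `c("non-play", "play")` (generically
#'   `c("negative", "positive")` for other targets).
#' @export
binary_labels <- function(labels, positive = "locomotor play") {
  lev <- if (positive == "locomotor play") c("non-play", "play") else
    c("negative", "positive")
  out <- ifelse(!is.na(labels) & labels == positive, lev[2], lev[1])
  factor(out, levels = lev)
}

#' A quantification training condition
#'
#' @param p Number of positive instances drawn for training.
#' @param np Number of negative instances drawn (default 10000).
#' @param seed Seed for the draw.
#' @return An object of class `training_condition`.
#' @export
training_condition <- function(p, np = 10000L, seed = 1L) {
  stopifnot(p >= 1, np >= p)
  structure(list(p = as.integer(p), np = as.integer(np),
                 seed = as.integer(seed)),
            class = "training_condition")
}

#' Estimate tpr and fpr of the binary classifier under a condition
#'
#' Draws `condition$p` positives and `condition$np` negatives from the
#' training pool under the condition's seed, then runs a k-fold
#' cross-validation of the boosted binary ensemble on the draw. Rates
#' are pooled over the held-out folds:
#' `tpr = tp / (tp + fn)`, `fpr = fp / (tn + fp)`.
#'
#' @param features Numeric feature data.frame/matrix of the training
#'   pool.
#' @param labels Binary factor (second level = positive), as from
#'   [binary_labels()].
#' @param condition A [training_condition()].
#' @param k CV folds (default 5).
#' @param params [ensemble_params()].
#' @return An object of class `rate_estimates`: list with `tpr`, `fpr`,
#'   `fold_rates` (per-fold data.frame), `counts` (pooled tp/fp/tn/fn),
#'   `condition`.
#' @export
estimate_rates <- function(features, labels, condition, k = 5L,
                           params = ensemble_params()) {
  stopifnot(inherits(condition, "training_condition"))
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  pos_lev <- levels(labels)[2]
  pos_idx <- which(labels == pos_lev)
  neg_idx <- which(labels != pos_lev)
  if (length(pos_idx) < condition$p) {
    stop("training pool holds ", length(pos_idx), " positives; ",
         "condition requires p = ", condition$p, call. = FALSE)
  }
  if (length(neg_idx) < condition$np) {
    stop("training pool holds ", length(neg_idx), " negatives; ",
         "condition requires np = ", condition$np, call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(condition$seed)
  take <- c(sample(pos_idx, condition$p),
            sample(neg_idx, condition$np))
  X <- as.data.frame(features)[take, , drop = FALSE]
  y <- droplevels(labels[take])
  fold <- .stratified_folds(y, k, condition$seed)
  tp <- fp <- tn <- fn <- 0
  fold_rates <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_ensemble(X[tr, , drop = FALSE], y[tr], params)
    pred <- predict(model, X[!tr, , drop = FALSE])
    truth_pos <- y[!tr] == pos_lev
    pred_pos <- pred == pos_lev
    ftp <- sum(truth_pos & pred_pos); ffn <- sum(truth_pos & !pred_pos)
    ffp <- sum(!truth_pos & pred_pos); ftn <- sum(!truth_pos & !pred_pos)
    tp <- tp + ftp; fn <- fn + ffn; fp <- fp + ffp; tn <- tn + ftn
    fold_rates[[f]] <- data.frame(
      fold = f,
      tpr = if (ftp + ffn > 0) ftp / (ftp + ffn) else NA_real_,
      fpr = if (ftn + ffp > 0) ffp / (ftn + ffp) else NA_real_)
  }
  structure(list(tpr = tp / (tp + fn), fpr = fp / (tn + fp),
                 fold_rates = do.call(rbind, fold_rates),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 condition = condition),
            class = "rate_estimates")
}

#' Adjusted-count prevalence correction
#'
#' Corrects the raw classify-and-count prevalence estimate `p0_prime`
#' of a binary classifier with true-positive rate `tpr` and
#' false-positive rate `fpr`:
#' `p' = (p0' - fpr) / (tpr - fpr)`, clipped to \[0, 1\]. A classifier
#' with `tpr <= fpr` carries no information about prevalence and is
#' rejected.
#'
#' @param p0_prime Raw predicted-positive fraction in \[0, 1\].
#' @param tpr,fpr Classifier rates, `tpr > fpr`.
#' @return The adjusted prevalence in \[0, 1\].
#' @export
adjust_prevalence <- function(p0_prime, tpr, fpr) {
  if (any(tpr <= fpr)) {
    stop("uninformative classifier: tpr <= fpr, the adjusted-count ",
         "correction is undefined", call. = FALSE)
  }
  pmin(pmax((p0_prime - fpr) / (tpr - fpr), 0), 1)
}

#' Sweep training conditions and select the tpr - fpr maximiser
#'
#' Evaluates [estimate_rates()] for every p in `p_grid` (each condition
#' draws its own positives and `np` negatives under a seed derived from
#' `seed` and p) and returns the condition maximising `tpr - fpr`. Ties
#' are broken towards the smaller p (the cheaper labelling effort).
#'
#' @param features,labels Training pool, as in [estimate_rates()].
#' @param p_grid Positive-count grid (default `seq(10, 190, by = 10)`).
#' @param np Negatives per condition (default 10000).
#' @param seed Master seed.
#' @param k CV folds.
#' @param params [ensemble_params()].
#' @return List with `best` (a [training_condition()]), `best_rates`
#'   (its `rate_estimates`) and `sweep` (data.frame of p, tpr, fpr,
#'   tpr_minus_fpr for every grid row).
#' @export
sweep_conditions <- function(features, labels,
                             p_grid = seq(10L, 190L, by = 10L),
                             np = 10000L, seed = 1L, k = 5L,
                             params = ensemble_params()) {
  if (!length(p_grid)) stop("empty condition grid", call. = FALSE)
  rows <- list(); rates <- list()
  for (p in p_grid) {
    cond <- training_condition(
      p, np, seed = (as.integer(seed) * 131L + as.integer(p)) %% 2147483629L)
    r <- estimate_rates(features, labels, cond, k = k, params = params)
    rates[[as.character(p)]] <- r
    rows[[length(rows) + 1L]] <- data.frame(
      p = p, np = np, tpr = r$tpr, fpr = r$fpr,
      tpr_minus_fpr = r$tpr - r$fpr)
  }
  sweep <- do.call(rbind, rows)
  best_i <- which(sweep$tpr_minus_fpr == max(sweep$tpr_minus_fpr))
  best_i <- best_i[which.min(sweep$p[best_i])]       # tie -> smaller p
  best_rates <- rates[[as.character(sweep$p[best_i])]]
  list(best = best_rates$condition, best_rates = best_rates,
       sweep = sweep)
}

#' Over/underestimation of a count
#'
#' @param observed Observed (true) count, >= 0.
#' @param predicted Predicted count.
#' @return List with `absolute` (predicted - observed), `percent`
#'   (100 * absolute / observed; `Inf` with `infinite = TRUE` when
#'   observed = 0 and predicted > 0) and `infinite` flag.
#' @export
overestimation <- function(observed, predicted) {
  if (observed < 0) stop("observed count must be >= 0", call. = FALSE)
  absolute <- predicted - observed
  if (observed == 0) {
    if (predicted == 0) {
      return(list(absolute = 0, percent = 0, infinite = FALSE))
    }
    return(list(absolute = absolute, percent = Inf, infinite = TRUE))
  }
  list(absolute = absolute, percent = 100 * absolute / observed,
       infinite = FALSE)
}

#' Adjusted-count quantification of a rare behaviour
#'
#' The full deployment procedure: sweep training conditions on the
#' labelled training pool to select the tpr - fpr maximiser, retrain
#' the binary ensemble on the selected condition's draw, count
#' predicted positives on the test pool, and correct the raw
#' classify-and-count estimate with [adjust_prevalence()]. When the
#' test pool carries labels, observed counts and over/underestimation
#' are reported overall and per file.
#'
#' @param train_features Data.frame from [extract_features()] (training
#'   pool): feature columns plus `label` and `animal_id`.
#' @param test_features Same layout for the test pool; `label` may be
#'   absent or all-`NA`.
#' @param positive Positive behaviour (default `"locomotor play"`).
#' @param p_grid,np,seed,k,params Passed to [sweep_conditions()].
#' @return An object of class `quantification_result`: list with
#'   `n_test`, `raw_count`, `p0_prime`, `condition`, `tpr`, `fpr`,
#'   `p_prime`, `adjusted_count`, `sweep`, and -- when test labels
#'   exist -- `observed_count`, `overestimation`, `per_file`.
#' @export
quantify <- function(train_features, test_features,
                     positive = "locomotor play",
                     p_grid = seq(10L, 190L, by = 10L), np = 10000L,
                     seed = 1L, k = 5L, params = ensemble_params()) {
  fcols <- feature_names(train_features)
  ytr <- binary_labels(train_features$label, positive)
  pos_lev <- levels(ytr)[2]
  sw <- sweep_conditions(train_features[, fcols], ytr,
                         p_grid = p_grid, np = np, seed = seed, k = k,
                         params = params)
  cond <- sw$best
  # retrain on the selected condition's own draw
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cond$seed)
  pos_idx <- which(ytr == pos_lev)
  neg_idx <- which(ytr != pos_lev)
  take <- c(sample(pos_idx, cond$p), sample(neg_idx, cond$np))
  model <- train_ensemble(train_features[take, fcols],
                          droplevels(ytr[take]), params)

  Xte <- test_features[, fcols]
  pred <- predict(model, Xte)
  n_test <- nrow(Xte)
  raw_count <- sum(pred == pos_lev)
  p0 <- raw_count / n_test
  tpr <- sw$best_rates$tpr; fpr <- sw$best_rates$fpr
  p_prime <- adjust_prevalence(p0, tpr, fpr)
  out <- list(n_test = n_test, raw_count = raw_count, p0_prime = p0,
              condition = cond, tpr = tpr, fpr = fpr,
              p_prime = p_prime,
              adjusted_count = as.integer(round(p_prime * n_test)),
              sweep = sw$sweep, model = model)
  has_labels <- "label" %in% names(test_features) &&
    any(!is.na(test_features$label))
  if (has_labels) {
    yte <- binary_labels(test_features$label, positive)
    out$observed_count <- sum(yte == pos_lev)
    out$overestimation <- overestimation(out$observed_count,
                                         out$adjusted_count)
    files <- as.character(test_features$animal_id)
    per <- lapply(sort(unique(files)), function(f) {
      in_f <- files == f
      n_f <- sum(in_f)
      raw_f <- sum(pred[in_f] == pos_lev)
      adj_f <- round(adjust_prevalence(raw_f / n_f, tpr, fpr) * n_f)
      obs_f <- sum(yte[in_f] == pos_lev)
      data.frame(animal_id = f, n = n_f, raw_count = raw_f,
                 adjusted_count = adj_f, observed_count = obs_f,
                 over = adj_f - obs_f, stringsAsFactors = FALSE)
    })
    out$per_file <- do.call(rbind, per)
  }
  structure(out, class = "quantification_result")
}

#' @export
print.quantification_result <- function(x, ...) {
  cat(sprintf(
    "<quantification_result> n_test = %d\n  raw (classify-and-count): %d  adjusted: %d\n",
    x$n_test, x$raw_count, x$adjusted_count))
  cat(sprintf("  condition p = %d, np = %d; tpr = %.4f, fpr = %.5f\n",
              x$condition$p, x$condition$np, x$tpr, x$fpr))
  if (!is.null(x$observed_count)) {
    cat(sprintf("  observed: %d; overestimation %d (%.2f%%)\n",
                x$observed_count, x$overestimation$absolute,
                x$overestimation$percent))
  }
  invisible(x)
}
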