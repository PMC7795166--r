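#' Boosted-ensemble hyper-parameters
#'
#' Parameters of the SAMME AdaBoost ensemble of depth-limited CART
#' trees. The base learner keeps a minimum leaf size of 5; tree
#' complexity is capped through `max_splits` (mapped to the deepest
#' binary tree whose split count cannot exceed it,
#' `maxdepth = floor(log2(max_splits + 1))`).
#'
#' @param n_learners Number of boosting rounds (default 100).
#' @param min_leaf_size Minimum observations per leaf (default 5).
#' @param max_splits Cap on splits per tree (default 20).
#' @param learning_rate Shrinkage on the per-round learner weight
#'   (default 1).
#' @param seed Integer seed (training itself is deterministic; the seed
#'   is recorded and used by callers for fold construction).
#' @return An object of class `ensemble_params`.
#' @export
ensemble_params <- function(n_learners = 100L, min_leaf_size = 5L,
                            max_splits = 20L, learning_rate = 1,
                            seed = 1L) {
  stopifnot(n_learners >= 1, min_leaf_size >= 1, max_splits >= 1,
            learning_rate > 0)
  structure(list(n_learners = as.integer(n_learners),
                 min_leaf_size = as.integer(min_leaf_size),
                 max_splits = as.integer(max_splits),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "ensemble_params")
}

#' Train a SAMME AdaBoost ensemble of CART trees
#'
#' Multi-class AdaBoost (SAMME): each round fits a weighted
#' classification tree, computes its weighted error e, receives voting
#' weight `alpha = learning_rate * (log((1 - e)/e) + log(K - 1))`, and
#' re-weights misclassified samples by `exp(alpha)`. Rounds with
#' `e >= 1 - 1/K` are discarded and boosting stops; a perfect round
#' (e = 0) gets a large capped alpha and stops boosting early.
#'
#' @param features Numeric data.frame or matrix (samples x features),
#'   no missing values.
#' @param labels Vector/factor of class labels; at least 2 classes.
#' @param params An [ensemble_params()].
#' @return An object of class `ada_ensemble` with elements `trees`,
#'   `alphas`, `classes`, `params`.
#' @export
train_ensemble <- function(features, labels, params = ensemble_params()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("training needs at least 2 classes", call. = FALSE)
  }
  X <- as.data.frame(features)
  if (anyNA(X)) stop("missing feature values are not allowed",
                     call. = FALSE)
  n <- nrow(X); K <- nlevels(labels)
  maxdepth <- max(1L, as.integer(floor(log2(params$max_splits + 1))))
  ctrl <- rpart::rpart.control(minbucket = params$min_leaf_size,
                               minsplit = 2L * params$min_leaf_size,
                               maxdepth = maxdepth, cp = 0, xval = 0,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  d <- X
  d$.y <- labels
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(params$n_learners)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, X, type = "class")
    miss <- pred != labels
    e <- sum(w[miss])
    if (e >= 1 - 1 / K) {
      if (length(trees) == 0L) {
        # degenerate data: keep the single weak tree with tiny weight
        trees[[1]] <- fit; alphas <- 1e-3
      }
      break
    }
    alpha <- if (e <= 0) {
      log(1e10) + log(K - 1)             # perfect learner, capped
    } else {
      log((1 - e) / e) + log(K - 1)
    }
    alpha <- params$learning_rate * alpha
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (e <= 0) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas,
                 classes = levels(labels), params = params),
            class = "ada_ensemble")
}

#' Predict classes (and per-class scores) from a trained ensemble
#'
#' @param object An `ada_ensemble` from [train_ensemble()].
#' @param newdata Feature data.frame/matrix with the training columns.
#' @param type `"class"` for labels, `"score"` for the matrix of
#'   normalised alpha-weighted vote shares per class.
#' @param ... Unused.
#' @return Factor of predicted classes, or a samples x classes score
#'   matrix.
#' @export
predict.ada_ensemble <- function(object, newdata, type = c("class",
                                                           "score"),
                                 ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata)
  votes <- matrix(0, nrow(X), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in seq_along(object$trees)) {
    p <- predict(object$trees[[m]], X, type = "class")
    votes[cbind(seq_len(nrow(X)), as.integer(p))] <-
      votes[cbind(seq_len(nrow(X)), as.integer(p))] + object$alphas[m]
  }
  if (type == "score") {
    return(votes / pmax(rowSums(votes), .Machine$double.eps))
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred Vectors of class labels (coerced to a common
#'   factor level set).
#' @param classes Optional explicit class ordering.
#' @return Square integer matrix (rows = truth, cols = prediction) of
#'   class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(truth), as.character(pred))))
  }
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  structure(unclass(cm), class = "confusion_matrix")
}

#' Confusion-derived performance report
#'
#' One-vs-rest metrics per class plus overall accuracy, unweighted macro
#' averages and Cohen's kappa. For class c with one-vs-rest counts
#' tp/fp/tn/fn: recall = tp/(tp+fn), precision = tp/(tp+fp),
#' specificity = tn/(tn+fp), accuracy = (tp+tn)/total and
#' F = 2PR/(P+R). Kappa = (p_o - p_e)/(1 - p_e) with the expected
#' agreement p_e from the product of row and column marginals. Any
#' zero-denominator rate is reported as 0 and the affected
#' (class, metric) pairs are listed in the `undefined` field.
#'
#' @param cm A square counts matrix (truth in rows), e.g. from
#'   [confusion_matrix()].
#' @return An object of class `performance_report`: list with
#'   `per_class` (data.frame), `overall_accuracy`, `macro` (named
#'   vector), `kappa`, `undefined`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) != ncol(cm) || nrow(cm) < 1L) {
    stop("confusion matrix must be square and nonempty", call. = FALSE)
  }
  if (any(cm < 0)) stop("confusion counts must be nonnegative",
                        call. = FALSE)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class_", seq_len(nrow(cm)))
  total <- sum(cm)
  undefined <- character(0)
  safe_div <- function(num, den, cls, metric) {
    if (den == 0) {
      undefined <<- c(undefined, paste0(cls, ":", metric))
      return(0)
    }
    num / den
  }
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    rec <- safe_div(tp, tp + fn, classes[i], "recall")
    pre <- safe_div(tp, tp + fp, classes[i], "precision")
    spe <- safe_div(tn, tn + fp, classes[i], "specificity")
    acc <- safe_div(tp + tn, total, classes[i], "accuracy")
    f1 <- if (pre + rec == 0) {
      undefined <<- c(undefined, paste0(classes[i], ":f_score"))
      0
    } else 2 * pre * rec / (pre + rec)
    data.frame(class = classes[i], accuracy = acc, specificity = spe,
               recall = rec, precision = pre, f_score = f1,
               support = tp + fn, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  macro <- colMeans(per[, c("accuracy", "specificity", "recall",
                            "precision", "f_score")])
  structure(list(per_class = per,
                 overall_accuracy = p_o,
                 macro = macro,
                 kappa = kappa,
                 undefined = unique(undefined)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Overall accuracy %.4f, Cohen's kappa %.4f\n",
              x$overall_accuracy, x$kappa))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

# Stratified k-fold assignment: within each class, samples are permuted
# under the seed and dealt round-robin into folds.
.stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer than k = ", k, " samples",
           call. = FALSE)
    }
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  fold
}

#' k-fold cross-validated evaluation of the boosted ensemble
#'
#' Folds are stratified by class under the seed; each sample is tested
#' exactly once. The returned report averages the per-fold metric
#' values (overall accuracy, kappa, per-class and macro rates); the
#' pooled confusion matrix over all held-out predictions is returned
#' alongside.
#'
#' @param features Numeric feature data.frame/matrix.
#' @param labels Class labels (every class needs >= k samples).
#' @param k Number of folds (default 5).
#' @param params [ensemble_params()].
#' @param seed Seed for fold construction.
#' @return List with `report` (fold-averaged `performance_report`),
#'   `pooled_confusion`, `fold_reports`.
#' @export
cross_validate <- function(features, labels, k = 5L,
                           params = ensemble_params(), seed = 1L) {
  labels <- factor(labels)
  X <- as.data.frame(features)
  fold <- .stratified_folds(labels, k, seed)
  preds <- factor(rep(NA_character_, length(labels)),
                  levels = levels(labels))
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_ensemble(X[tr, , drop = FALSE], labels[tr], params)
    p <- predict(model, X[!tr, , drop = FALSE])
    preds[!tr] <- factor(as.character(p), levels = levels(labels))
    fold_reports[[f]] <- metrics_from_confusion(
      confusion_matrix(labels[!tr], p, classes = levels(labels)))
  }
  pooled <- confusion_matrix(labels, preds, classes = levels(labels))
  list(report = .average_reports(fold_reports),
       pooled_confusion = pooled,
       fold_reports = fold_reports)
}

.average_reports <- function(reports) {
  per <- reports[[1]]$per_class
  metric_cols <- c("accuracy", "specificity", "recall", "precision",
                   "f_score")
  for (mcol in metric_cols) {
    per[[mcol]] <- rowMeans(vapply(reports,
                                   function(r) r$per_class[[mcol]],
                                   numeric(nrow(per))))
  }
  per$support <- rowSums(vapply(reports,
                                function(r) r$per_class$support,
                                numeric(nrow(per))))
  macro <- colMeans(do.call(rbind, lapply(reports, `[[`, "macro")))
  structure(list(
    per_class = per,
    overall_accuracy = mean(vapply(reports, `[[`, 0,
                                   "overall_accuracy")),
    macro = macro,
    kappa = mean(vapply(reports, `[[`, 0, "kappa")),
    undefined = unique(unlist(lapply(reports, `[[`, "undefined")))
  ), class = "performance_report")
}
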