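#' ReliefF feature ranking
#'
#' Multi-class ReliefF: each feature is scored by its ability to
#' separate near hits from near misses. Features are min-max scaled to
#' \[0, 1\]; for each anchor sample the k nearest same-class neighbours
#' (hits) and, per other class C, the k nearest neighbours in C
#' (misses) are found under Manhattan distance. The weight update
#' subtracts the mean per-feature difference to hits and adds the
#' prior-weighted mean difference to misses, so weights lie in
#' \[-1, 1\]; a feature carrying no class information scores near 0 and
#' a constant feature scores exactly 0.
#'
#' @param features Numeric data.frame/matrix (samples x features).
#' @param labels Class labels; >= 2 classes, each with >= 2 samples.
#' @param k_neighbors Neighbours per class (default 10; clipped to the
#'   available class sizes).
#' @param n_anchors Number of anchor samples; the default `NULL` uses
#'   every sample, which makes the ranking deterministic without a
#'   seed. If fewer, anchors are drawn under `seed`.
#' @param seed Seed for anchor sampling (only used when
#'   `n_anchors < n`).
#' @return A data.frame `(feature, weight, rank)` ordered by descending
#'   weight.
#' @export
relieff_rank <- function(features, labels, k_neighbors = 10L,
                         n_anchors = NULL, seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  n <- nrow(X); p <- ncol(X)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("relieff_rank needs at least 2 classes", call. = FALSE)
  }
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  scale_span <- ifelse(span > 0, span, 1)
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, scale_span, "/")
  Xs[, span == 0] <- 0                    # constant features: weight 0

  priors <- table(labels) / n
  anchors <- seq_len(n)
  if (!is.null(n_anchors) && n_anchors < n) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    anchors <- sort(sample.int(n, n_anchors))
  }
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  W <- numeric(p)
  m <- length(anchors)
  for (a in anchors) {
    cls_a <- labels[a]
    for (cl in classes) {
      pool <- which(labels == cl)
      pool <- pool[pool != a]
      if (!length(pool)) next
      k <- min(k_neighbors, length(pool))
      nn <- pool[order(D[a, pool])[seq_len(k)]]
      dmean <- colMeans(abs(Xs[nn, , drop = FALSE] -
                              rep(Xs[a, ], each = k)))
      if (cl == cls_a) {
        W <- W - dmean / m
      } else {
        W <- W + (priors[[cl]] / (1 - priors[[cls_a]])) * dmean / m
      }
    }
  }
  out <- data.frame(feature = colnames(X) %||% paste0("f", seq_len(p)),
                    weight = W, stringsAsFactors = FALSE)
  out <- out[order(-out$weight), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
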