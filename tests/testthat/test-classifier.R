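test_that("the boosted ensemble separates well-separated Gaussians", {
  gc2 <- gaussian_classes(n_per = 100, centers = c(0, 3), seed = 2)
  model <- train_ensemble(gc2$X, gc2$y,
                          ensemble_params(n_learners = 20, seed = 1))
  acc <- mean(predict(model, gc2$X) == gc2$y)
  expect_gte(acc, 0.99)
  # determinism
  model2 <- train_ensemble(gc2$X, gc2$y,
                           ensemble_params(n_learners = 20, seed = 1))
  expect_identical(predict(model2, gc2$X), predict(model, gc2$X))
  expect_error(train_ensemble(gc2$X, rep("a", 200)), "2 classes")
  expect_error(train_ensemble(cbind(gc2$X, bad = NA), gc2$y), "missing")
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  gc2 <- gaussian_classes(n_per = 100, centers = c(0, 3), seed = 3)
  accs <- vapply(1:3, function(i) {
    set.seed(40 + i)
    y_perm <- sample(gc2$y)
    cross_validate(gc2$X, y_perm, k = 5,
                   params = ensemble_params(n_learners = 10),
                   seed = 5)$report$overall_accuracy
  }, 0)
  # 2 classes: chance 0.5; 3 s.e. of the 3-permutation mean ~ 0.06,
  # plus slack for fold-level dependence
  expect_lt(abs(mean(accs) - 0.5), 0.11)
})

test_that("stratified folds partition every class across k folds", {
  y <- factor(rep(c("a", "b", "c"), times = c(30, 25, 10)))
  fold <- calfwatch:::.stratified_folds(y, 5, seed = 1)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), length(y))
  for (cl in levels(y)) {
    expect_true(all(table(fold[y == cl]) >= 2))
  }
  expect_error(calfwatch:::.stratified_folds(factor(rep(c("a", "b"),
                                                        c(30, 3))),
                                             5, 1),
               "fewer than k")
})

test_that("a perfectly separable 3-class set scores accuracy and kappa 1", {
  gc3 <- gaussian_classes(n_per = 40, centers = c(0, 5, 10), sd = 0.3,
                          seed = 4)
  cv <- cross_validate(gc3$X, gc3$y, k = 5,
                       params = ensemble_params(n_learners = 10),
                       seed = 2)
  expect_equal(cv$report$overall_accuracy, 1)
  expect_equal(cv$report$kappa, 1)
  expect_true(all(diag(unclass(cv$pooled_confusion)) == 40))
})

test_that("confusion metrics match hand arithmetic on the 2x2 case", {
  cm <- matrix(c(45, 5, 5, 45), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  r <- metrics_from_confusion(cm)
  expect_equal(r$overall_accuracy, 0.9)
  expect_equal(r$per_class$recall, c(0.9, 0.9))
  expect_equal(r$per_class$precision, c(0.9, 0.9))
  expect_equal(r$per_class$specificity, c(0.9, 0.9))
  expect_equal(r$kappa, 0.8)   # p_o = 0.9, p_e = 0.5
})

test_that("kappa is 1 iff the confusion matrix is diagonal", {
  d <- diag(c(10, 20, 30))
  r <- metrics_from_confusion(d)
  expect_equal(r$kappa, 1)
  expect_true(all(r$per_class$recall == 1))
  expect_true(all(r$per_class$f_score == 1))
  nd <- d; nd[1, 2] <- 1
  expect_lt(metrics_from_confusion(nd)$kappa, 1)
})

test_that("zero-denominator rates are reported as 0 and flagged", {
  cm <- matrix(c(10, 0, 5, 0), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  r <- metrics_from_confusion(cm)   # nothing predicted as b
  expect_equal(r$per_class$precision[2], 0)
  expect_true("b:precision" %in% r$undefined)
})

test_that("metrics agree with a per-sample brute-force recount", {
  set.seed(31)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 6), k, k,
                 dimnames = list(paste0("c", 1:k), paste0("c", 1:k)))
    if (sum(cm) == 0) next
    r <- metrics_from_confusion(cm)
    truth <- rep(rep(rownames(cm), k), times = as.vector(cm))
    pred <- rep(rep(colnames(cm), each = k), times = as.vector(cm))
    expect_equal(r$overall_accuracy, mean(truth == pred))
    for (ci in seq_len(k)) {
      cl <- rownames(cm)[ci]
      tp <- sum(truth == cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      fp <- sum(truth != cl & pred == cl)
      tn <- sum(truth != cl & pred != cl)
      if (tp + fn > 0) expect_equal(r$per_class$recall[ci], tp / (tp + fn))
      if (tp + fp > 0) expect_equal(r$per_class$precision[ci], tp / (tp + fp))
      if (tn + fp > 0) expect_equal(r$per_class$specificity[ci], tn / (tn + fp))
    }
    # macro metrics are plain unweighted means of the per-class columns
    expect_equal(unname(r$macro["recall"]), mean(r$per_class$recall))
    expect_equal(unname(r$macro["f_score"]), mean(r$per_class$f_score))
  }
})

test_that("CV folds test each sample exactly once", {
  gc2 <- gaussian_classes(n_per = 30, centers = c(0, 4), seed = 6)
  fold <- calfwatch:::.stratified_folds(gc2$y, 5, seed = 3)
  tested <- unlist(lapply(1:5, function(f) which(fold == f)))
  expect_setequal(tested, seq_along(gc2$y))
  expect_equal(length(tested), length(unique(tested)))
})
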