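test_that("stratified_kfold balances classes and is deterministic", {
  lab <- rep(c("a", "b"), each = 10)
  f <- stratified_kfold(lab, 10, seed = 1)
  for (k in 1:10) {
    expect_equal(sum(f == k & lab == "a"), 1)
    expect_equal(sum(f == k & lab == "b"), 1)
  }
  # OASIS-like multiset: the 2-member class lands in 2 distinct folds
  lab2 <- rep(c("none", "verymild", "mild", "moderate"),
              c(336, 70, 28, 2))
  f2 <- stratified_kfold(lab2, 10, seed = 3)
  expect_equal(length(unique(f2[lab2 == "moderate"])), 2)
  # every fold within one sample of the even split, per class
  for (cl in unique(lab2)) {
    counts <- tabulate(f2[lab2 == cl], 10)
    expect_lte(diff(range(counts)), 1)
  }
  expect_identical(stratified_kfold(lab2, 10, seed = 3), f2)
  expect_false(identical(stratified_kfold(lab2, 10, seed = 4), f2))
  expect_error(stratified_kfold(lab, 25), "exceed")
})

test_that("normalize_fit_apply learns only from the training fold", {
  set.seed(5)
  train <- matrix(rnorm(40, mean = 3, sd = 2), 10, 4)
  train[, 4] <- 7                   # degenerate constant feature
  test <- matrix(rnorm(20, mean = 5, sd = 1), 5, 4)
  nz <- normalize_fit_apply(train, test)
  expect_equal(colMeans(nz$train[, 1:3]), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(nz$train[, 1:3], 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(nz$train[, 4], rep(0, 10))
  # test-fold statistics are generally not (0, 1) under distribution shift
  expect_gt(abs(mean(nz$other[, 1])), 0.1)
  # transform must not depend on the held-out data
  nz2 <- normalize_fit_apply(train, matrix(rnorm(20), 5, 4))
  expect_identical(nz$center, nz2$center)
  expect_identical(nz$scale, nz2$scale)
})

test_that("weighted_accuracy matches a brute-force one-vs-rest oracle", {
  oracle <- function(cm) {
    tot <- sum(cm); C <- nrow(cm); acc <- numeric(C); w <- numeric(C)
    for (c in seq_len(C)) {
      tp <- 0; fp <- 0; tn <- 0; fn <- 0
      for (i in seq_len(C)) for (j in seq_len(C)) {
        if (i == c && j == c) tp <- tp + cm[i, j]
        else if (i == c) fn <- fn + cm[i, j]
        else if (j == c) fp <- fp + cm[i, j]
        else tn <- tn + cm[i, j]
      }
      acc[c] <- (tp + tn) / (tp + fp + tn + fn)
      w[c] <- sum(cm[c, ]) / tot
    }
    sum(acc * w)
  }
  expect_equal(weighted_accuracy(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 0.75)
  expect_equal(weighted_accuracy(diag(c(5, 2, 9))), 1)
  cm3 <- matrix(c(5, 0, 0, 0, 5, 0, 5, 0, 0), 3, byrow = TRUE)
  expect_equal(weighted_accuracy(cm3, rep(1 / 3, 3)),
               mean(c(10 / 15, 15 / 15, 10 / 15)))
  set.seed(99)
  for (i in 1:1000) {
    C <- sample(2:5, 1)
    cm <- matrix(rpois(C * C, 3), C, C)
    if (sum(cm) == 0) cm[1, 1] <- 1
    expect_equal(weighted_accuracy(cm), oracle(cm), tolerance = 1e-12)
  }
  expect_error(weighted_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("grid_search picks the separating configuration", {
  g1 <- data.frame(k = 3, distance = "euclidean", stringsAsFactors = FALSE)
  set.seed(2)
  x <- matrix(rnorm(60), 30, 2)
  y <- factor(rep(c("a", "b"), 15))
  gs <- grid_search("kNN", g1, x, y, seed = 1)
  expect_equal(gs$params$k, 3)

  # linearly separable data: k = 1 wins over the degenerate k = n_train
  x2 <- rbind(matrix(rnorm(40, -4), 20, 2), matrix(rnorm(40, 4), 20, 2))
  y2 <- factor(rep(c("a", "b"), each = 20))
  g2 <- data.frame(k = c(40, 1), distance = "euclidean",
                   stringsAsFactors = FALSE)
  gs2 <- grid_search("kNN", g2, x2, y2, seed = 1)
  expect_equal(gs2$params$k, 1)
  expect_equal(gs2$score, 1)

  expect_error(grid_search("wat", g1, x, y), "unknown classifier")
  expect_error(grid_search("kNN", g1[0, , drop = FALSE], x, y), "empty grid")
})

test_that("all five classifier categories learn a separable problem", {
  set.seed(13)
  n <- 30
  x <- rbind(matrix(rnorm(2 * n, -2, 0.5), n, 2),
             matrix(rnorm(2 * n, 2, 0.5), n, 2))
  y <- factor(rep(c("a", "b"), each = n))
  ho <- rbind(matrix(rnorm(20, -2, 0.5), 10, 2),
              matrix(rnorm(20, 2, 0.5), 10, 2))
  truth <- factor(rep(c("a", "b"), each = 10))
  for (tag in c("SVM", "kNN", "DT", "NB", "BT")) {
    params <- as.list(default_grid(tag)[1, , drop = FALSE])
    model <- orthim:::classifier_fit(tag, x, y, params, seed = 7)
    pred <- orthim:::classifier_predict(tag, model, ho)
    expect_gte(weighted_accuracy(confusion_matrix(truth, pred)), 0.9)
  }
})

test_that("run_benchmark is deterministic and guards degenerate input", {
  ds <- generate_dataset(3, 6, c(32, 32), seed = 2)
  r1 <- run_benchmark(ds, c("CHM"), c("kNN"), k = 3, seed = 11)
  r2 <- run_benchmark(ds, c("CHM"), c("kNN"), k = 3, seed = 11)
  expect_identical(r1$table, r2$table)
  expect_true(all(r1$table$kNN >= 0 & r1$table$kNN <= 1))
  expect_equal(unname(r1$feature_sizes["CHM"]), 21)

  bad <- list(images = ds$images[1:6], labels = factor(rep("a", 6)))
  expect_error(run_benchmark(bad, c("CHM"), c("kNN"), k = 2), "2 classes")
})

test_that("aggregate_by_category reproduces mean/sd/min/max", {
  vals <- c(LM = 66.6, CHM = 68.4, CH2M = 70.2)
  agg <- aggregate_by_category(vals)
  expect_equal(agg$mean[agg$category == "CM"], 68.4)
  expect_equal(agg$min[agg$category == "CM"], 66.6)
  single <- aggregate_by_category(c(BFM = 66.9))
  expect_equal(single$sd, 0)
  two <- aggregate_by_category(c(LM = 0.5, CHM = 0.7))
  expect_equal(two$mean, 0.6)
  expect_error(aggregate_by_category(c(XX = 1)), "without a category")
})
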