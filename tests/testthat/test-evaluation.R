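# Fold construction, confusion matrices, the five metrics and the
# cross-validated pipeline.

test_that("sequential stratified folds follow the block protocol", {
  # 100 + 100 samples, 10 folds: fold 1 holds the first 10 of each class
  y <- rep(c("neg", "pos"), each = 100)
  folds <- stratified_folds(y, 10)
  expect_length(folds, 10L)
  expect_setequal(folds[[1]]$test, c(1:10, 101:110))
  expect_setequal(folds[[2]]$test, c(11:20, 111:120))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_along(y))  # exact partition
  for (f in folds) {
    expect_identical(sort(c(f$test, f$train)), seq_along(y))
    expect_identical(unname(table(y[f$test])), unname(table(c("neg", "pos"))) * 10L)
  }
})

test_that("remainders spread across earlier folds and small classes error", {
  y <- c(rep("a", 95), rep("b", 40))
  folds <- stratified_folds(y, 10)
  sizes_a <- vapply(folds, function(f) sum(f$test <= 95), integer(1))
  expect_identical(sizes_a, c(rep(10L, 5), rep(9L, 5)))  # 95 = 5x10 + 5x9
  expect_true(all(abs(diff(range(sizes_a))) <= 1))
  expect_error(stratified_folds(c(rep("a", 20), rep("b", 5)), 10), "has 5 < 10")
  # shuffled mode still partitions and stratifies
  fs <- stratified_folds(y, 5, shuffle = TRUE, seed = 3)
  expect_identical(sort(unlist(lapply(fs, `[[`, "test"))), seq_along(y))
})

test_that("confusion matrices count truth by row and add across folds", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"), levels = c("a", "b"))
  expect_identical(cm, matrix(c(1L, 0L, 1L, 1L), 2,
                              dimnames = list(truth = c("a", "b"),
                                              predicted = c("a", "b"))))
  expect_identical(sum(cm), 3L)
  # all-correct gives a diagonal matrix
  cmd <- confusion_matrix(c(1, 2, 2), c(1, 2, 2), levels = c("1", "2"))
  expect_identical(sum(diag(cmd)), 3L)
  # additivity: summed per-fold matrices equal the pooled matrix
  set.seed(12)
  truth <- sample(c("x", "y"), 60, replace = TRUE)
  pred <- sample(c("x", "y"), 60, replace = TRUE)
  parts <- split(seq_len(60), rep(1:3, each = 20))
  summed <- Reduce(`+`, lapply(parts, function(i)
    confusion_matrix(truth[i], pred[i], levels = c("x", "y"))))
  expect_equal(summed, confusion_matrix(truth, pred, levels = c("x", "y")),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(c("a"), c("a", "b")), "length")
})

test_that("binary metrics reproduce the printed seizure-detection arithmetic", {
  cm <- matrix(c(1288L, 16L, 8L, 829L), 2,
               dimnames = list(truth = c("background", "seizure"),
                               predicted = c("background", "seizure")))
  met <- classification_metrics(cm, positive = "seizure")
  expect_equal(round(met$recall, 1), 98.1)
  expect_equal(round(met$precision, 1), 99.0)
  expect_equal(met$accuracy, 100 * (1288 + 829) / 2141, tolerance = 1e-12)
  expect_equal(met$specificity, 100 * 1288 / 1296, tolerance = 1e-12)
  expect_equal(met$f1, 2 * met$precision * met$recall / (met$precision + met$recall),
               tolerance = 1e-12)
})

test_that("three-class recalls match the row-normalized diagonal", {
  cm <- matrix(c(191L, 4L, 5L,
                 6L, 189L, 6L,
                 3L, 7L, 89L), 3,
               dimnames = list(truth = c("AB", "CD", "E"),
                               predicted = c("AB", "CD", "E")))
  met <- classification_metrics(cm)
  expect_equal(met$per_class$recall, c(95.5, 94.5, 89.0), tolerance = 1e-12)
  expect_equal(met$accuracy, 100 * 469 / 500, tolerance = 1e-12)
  expect_equal(met$f1, 2 * met$precision * met$recall / (met$precision + met$recall),
               tolerance = 1e-12)
  # specificity of one class equals the recall of the complement in binary
  cm2 <- matrix(c(40L, 5L, 10L, 45L), 2,
                dimnames = list(truth = c("n", "p"), predicted = c("n", "p")))
  m2 <- classification_metrics(cm2, positive = "p")
  m2n <- classification_metrics(cm2, positive = "n")
  expect_equal(m2$specificity, m2n$recall, tolerance = 1e-12)
})

test_that("perfect and degenerate matrices behave as documented", {
  cm <- diag(c(10L, 20L)); dimnames(cm) <- list(truth = c("a", "b"), predicted = c("a", "b"))
  met <- classification_metrics(cm, positive = 2)
  expect_equal(unlist(met[c("accuracy", "precision", "recall", "specificity", "f1")]),
               c(accuracy = 100, precision = 100, recall = 100,
                 specificity = 100, f1 = 100))
  # nothing predicted positive: zero-denominator metrics flagged, not NaN
  cm0 <- matrix(c(30L, 5L, 0L, 0L), 2,
                dimnames = list(truth = c("n", "p"), predicted = c("n", "p")))
  m0 <- classification_metrics(cm0, positive = "p")
  expect_identical(m0$precision, 0)
  expect_true(m0$flagged)
})

test_that("cross-validation partitions exactly, is deterministic and leak-free", {
  set.seed(14)
  D <- 10
  X <- matrix(rnorm(80 * D), 80, D)
  y <- rep(c("a", "b"), each = 40)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 3
  cv1 <- dysc_cv(X, y, n_folds = 4, dims = c(4, 3, 3), hidden_pathway = 4,
                 hidden_fusion = 6, max_iter = 25, seed = 5)
  expect_identical(sum(cv1$cm), 80L)
  expect_identical(nrow(cv1$per_fold), 4L)
  cv2 <- dysc_cv(X, y, n_folds = 4, dims = c(4, 3, 3), hidden_pathway = 4,
                 hidden_fusion = 6, max_iter = 25, seed = 5)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$cm, cv2$cm)
  expect_gte(cv1$mean[["accuracy"]], 95)
  # metric identity on the report
  expect_equal(cv1$aggregate$f1,
               2 * cv1$aggregate$precision * cv1$aggregate$recall /
                 (cv1$aggregate$precision + cv1$aggregate$recall),
               tolerance = 1e-12)
  # no leakage: fold-1 training ignores fold-1 test samples entirely
  folds <- stratified_folds(y, 4)
  fit_a <- dysc(X[folds[[1]]$train, ], y[folds[[1]]$train], dims = c(4, 3, 3),
                hidden_pathway = 4, hidden_fusion = 6, max_iter = 25, seed = 6)
  Xmut <- X; Xmut[folds[[1]]$test[1], ] <- 99
  fit_b <- dysc(Xmut[folds[[1]]$train, ], y[folds[[1]]$train], dims = c(4, 3, 3),
                hidden_pathway = 4, hidden_fusion = 6, max_iter = 25, seed = 6)
  expect_identical(fit_a$flat, fit_b$flat)
})

test_that("cv reports serialize to JSON and CSV", {
  set.seed(15)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("a", "b"), each = 20)
  X[y == "b", 1] <- X[y == "b", 1] + 4
  cv <- dysc_cv(X, y, n_folds = 2, dims = c(2, 2, 2), hidden_pathway = 3,
                hidden_fusion = 4, max_iter = 10, seed = 1)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  cv_report_write(cv, jp, cp)
  doc <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_identical(doc$format, "dysc-cv-report")
  expect_equal(doc$mean$accuracy, cv$mean[["accuracy"]], tolerance = 1e-12)
  expect_identical(nrow(utils::read.csv(cp)), 3L)  # 2 folds + summary row
})
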