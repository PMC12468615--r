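## Cross-validation protocol, confusion matrices and the five standard
## detection metrics (accuracy, precision, recall, specificity, F1),
## reported as percentages per fold and aggregated.

#' Stratified sequential cross-validation folds
#'
#' Within each class, samples are assigned to folds in contiguous blocks in
#' dataset order: fold 1 takes the first block of every class, fold 2 the
#' next, and so on, so class proportions are preserved per fold.  When a
#' class size is not divisible by `n_folds`, earlier folds receive the extra
#' sample.  `shuffle = TRUE` permutes within class first (seeded).
#'
#' @param labels Vector of class labels.
#' @param n_folds Number of folds (default 10).
#' @param shuffle Permute within class before blocking (default `FALSE`,
#'   the sequential protocol).
#' @param seed Seed used when `shuffle = TRUE`.
#' @return A list of `n_folds` fold specifications, each a list with
#'   `fold`, `test` and `train` index vectors.  Test sets partition
#'   `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, n_folds = 10L, shuffle = FALSE, seed = 1L) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab < n_folds))
    stop(sprintf("class '%s' has %d < %d members",
                 names(tab)[which.min(tab)], min(tab), n_folds), call. = FALSE)
  assignment <- integer(length(labels))
  if (shuffle) set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (shuffle) idx <- sample(idx)
    n <- length(idx)
    base <- n %/% n_folds
    extra <- n %% n_folds
    sizes <- rep(base, n_folds) + c(rep(1L, extra), rep(0L, n_folds - extra))
    assignment[idx] <- rep(seq_len(n_folds), times = sizes)
  }
  lapply(seq_len(n_folds), function(f)
    list(fold = f, test = which(assignment == f), train = which(assignment != f)))
}

#' Confusion matrix
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Class levels defining the row/column order (default: sorted
#'   union of the observed labels).
#' @return A K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth), as.character(pred))))
  t_ <- factor(truth, levels = levels)
  p_ <- factor(pred, levels = levels)
  cm <- table(truth = t_, predicted = p_)
  matrix(as.integer(cm), nrow = length(levels),
         dimnames = list(truth = levels, predicted = levels))
}

## TP/TN/FP/FN metrics for one positive class of a K x K matrix, percent.
ovr_metrics <- function(cm, pos) {
  tp <- cm[pos, pos]
  fn <- sum(cm[pos, ]) - tp
  fp <- sum(cm[, pos]) - tp
  tn <- sum(cm) - tp - fn - fp
  safe <- function(num, den) if (den > 0) 100 * num / den else 0
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall,
    specificity = safe(tn, tn + fp), f1 = f1,
    flagged = as.numeric((tp + fp) == 0 || (tp + fn) == 0 || (tn + fp) == 0))
}

#' Classification metrics from a confusion matrix
#'
#' Binary case: accuracy, precision, recall (sensitivity), specificity and
#' F1 for the designated positive class, each in percent.  Multi-class case:
#' the same metrics per class (one-vs-rest) plus their macro averages, with
#' the macro F1 the harmonic mean of macro precision and macro recall.
#' Zero-denominator metrics return 0 and set the `flagged` field.
#'
#' @param cm Confusion matrix (rows = truth), e.g. from [confusion_matrix()].
#' @param positive For the binary case, index or name of the positive class
#'   (default: the second class).
#' @return A list of class `"dysc_metrics"`: `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1` (percent), `per_class` (data frame, K > 2
#'   only), `cm`, `positive`, `flagged`.
#' @examples
#' cm <- matrix(c(1288, 16, 8, 829), 2, dimnames = list(
#'   truth = c("background", "seizure"), predicted = c("background", "seizure")))
#' classification_metrics(cm, positive = "seizure")
#' @export
classification_metrics <- function(cm, positive = NULL) {
  cm <- as.matrix(cm)
  K <- nrow(cm)
  if (K != ncol(cm) || sum(cm) == 0) stop("invalid or empty confusion matrix", call. = FALSE)
  lev <- rownames(cm)
  if (is.null(lev)) lev <- as.character(seq_len(K))
  accuracy <- 100 * sum(diag(cm)) / sum(cm)
  if (K == 2L) {
    if (is.null(positive)) positive <- 2L
    pos <- if (is.character(positive)) match(positive, lev) else as.integer(positive)
    if (is.na(pos) || pos < 1L || pos > 2L) stop("unknown positive class", call. = FALSE)
    v <- ovr_metrics(cm, pos)
    out <- list(accuracy = accuracy, precision = v[["precision"]],
                recall = v[["recall"]], specificity = v[["specificity"]],
                f1 = v[["f1"]], per_class = NULL, cm = cm,
                positive = lev[pos], flagged = v[["flagged"]] > 0)
  } else {
    per <- t(vapply(seq_len(K), function(j) ovr_metrics(cm, j), numeric(5)))
    pc <- data.frame(class = lev, precision = per[, 1], recall = per[, 2],
                     specificity = per[, 3], f1 = per[, 4],
                     row.names = NULL, stringsAsFactors = FALSE)
    mp <- mean(per[, 1]); mr <- mean(per[, 2])
    mf1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
    out <- list(accuracy = accuracy, precision = mp, recall = mr,
                specificity = mean(per[, 3]), f1 = mf1, per_class = pc,
                cm = cm, positive = NA_character_, flagged = any(per[, 5] > 0))
  }
  class(out) <- "dysc_metrics"
  out
}

#' @export
print.dysc_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  specificity %.2f%%  F1 %.2f%%\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$f1))
  if (!is.null(x$per_class)) {
    cat("per-class (one-vs-rest):\n")
    print(cbind(x$per_class[1], round(x$per_class[-1], 2)))
  }
  invisible(x)
}

#' Cross-validated evaluation of the DySC pipeline
#'
#' For each fold: fit the feature standardizer and train a [dysc()] model on
#' the training indices only, predict the held-out test indices, and score.
#' Reports the five metrics per fold, their mean and standard deviation, and
#' the aggregate (summed) confusion matrix.  Fully deterministic for a fixed
#' `seed`.
#'
#' @inheritParams dysc
#' @param n_folds Number of folds (default 10).
#' @param positive Positive class for binary metrics (default: second level).
#' @param shuffle,seed Fold construction and weight initialization seeds; see
#'   [stratified_folds()].
#' @param ... Further arguments passed to [dysc()].
#' @return An object of class `"dysc_cv"`: `per_fold` (data frame of metric
#'   rows), `mean`, `sd`, `aggregate` (metrics on the summed confusion
#'   matrix), `cm` (summed confusion matrix), `n_folds`, `seed`.
#' @export
dysc_cv <- function(x, y, n_folds = 10L, dims = NULL, positive = NULL,
                    shuffle = FALSE, seed = 1L, ...) {
  X <- as.matrix(x)
  if (is.null(dims)) dims <- attr(x, "dims")
  y <- factor(y)
  folds <- stratified_folds(y, n_folds = n_folds, shuffle = shuffle, seed = seed)
  lev <- levels(y)
  metric_names <- c("accuracy", "precision", "recall", "specificity", "f1")
  rows <- vector("list", n_folds)
  cm_total <- matrix(0L, nlevels(y), nlevels(y), dimnames = list(truth = lev, predicted = lev))
  for (fs in folds) {
    fit <- tryCatch(
      dysc(X[fs$train, , drop = FALSE], y[fs$train], dims = dims,
           seed = seed + fs$fold, ...),
      error = function(e) stop(sprintf("training failed in fold %d: %s",
                                       fs$fold, conditionMessage(e)), call. = FALSE))
    pred <- predict(fit, X[fs$test, , drop = FALSE])
    cm <- confusion_matrix(y[fs$test], pred, levels = lev)
    met <- classification_metrics(cm, positive = positive)
    cm_total <- cm_total + cm
    rows[[fs$fold]] <- data.frame(fold = fs$fold, accuracy = met$accuracy,
                                  precision = met$precision, recall = met$recall,
                                  specificity = met$specificity, f1 = met$f1)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_names]),
    sd = apply(per_fold[metric_names], 2L, stats::sd),
    aggregate = classification_metrics(cm_total, positive = positive),
    cm = cm_total, n_folds = n_folds, seed = as.integer(seed)),
    class = "dysc_cv")
}

#' @export
print.dysc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$n_folds, x$seed))
  for (mn in names(x$mean))
    cat(sprintf("  %-12s %6.2f%% +/- %.2f\n", mn, x$mean[[mn]], x$sd[[mn]]))
  cat("aggregate confusion matrix:\n")
  print(x$cm)
  invisible(x)
}

#' Write a cross-validation report to JSON (and optionally CSV)
#'
#' The JSON document carries per-fold metrics, the mean/sd summary, the
#' aggregate confusion matrix and the seed; the CSV has one row per fold
#' plus a summary row.
#'
#' @param report A [dysc_cv()] result.
#' @param json_path Output JSON file.
#' @param csv_path Optional output CSV file.
#' @return `json_path`, invisibly.
#' @export
cv_report_write <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "dysc_cv"))
  doc <- list(format = "dysc-cv-report", version = 1L,
              n_folds = report$n_folds, seed = report$seed,
              per_fold = report$per_fold,
              mean = as.list(report$mean), sd = as.list(report$sd),
              aggregate_confusion = unclass(report$cm),
              aggregate = list(accuracy = report$aggregate$accuracy,
                               precision = report$aggregate$precision,
                               recall = report$aggregate$recall,
                               specificity = report$aggregate$specificity,
                               f1 = report$aggregate$f1))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    summary_row <- data.frame(fold = NA_integer_, t(report$mean))
    utils::write.csv(rbind(report$per_fold, summary_row), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
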