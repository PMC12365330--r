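#' Confusion counts from truth and prediction vectors
#'
#' Tabulates predictions against truth as a k x k contingency table with
#' truth in rows and predictions in columns, using the union of observed
#' levels in a fixed order.
#'
#' @param truth Vector (factor) of true labels.
#' @param pred Vector (factor) of predicted labels, same length.
#' @return An integer matrix with truth rows and prediction columns.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  lev <- union(levels(factor(truth)), levels(factor(pred)))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  as.matrix(table(truth = truth, pred = pred))
}

# safe ratio with the degenerate-denominator convention: 0 plus a warning
safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reporting 0.")
    return(0)
  }
  num / den
}

#' Classification metrics from a confusion table
#'
#' Accuracy, precision, recall and F1 from a confusion matrix. For a 2 x 2
#' table the second level is treated as the positive class unless
#' `positive` names another; for k > 2 classes, macro averaging (the
#' unweighted mean of per-class one-vs-rest values) is used. Degenerate
#' denominators (e.g. nothing predicted positive) yield 0 with a warning.
#'
#' @param counts A square confusion matrix (truth rows, prediction columns),
#'   e.g. from [confusion_counts()], or a named vector/list with `tp`, `fp`,
#'   `fn`, `tn` for the binary case.
#' @param averaging `"auto"` (binary when 2 x 2, macro otherwise),
#'   `"binary"`, or `"macro"`.
#' @param positive For binary tables, the level regarded as positive
#'   (default: the second row/column name).
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `averaging`, `n`.
#' @examples
#' compute_metrics(c(tp = 50, fp = 10, fn = 5, tn = 35))
#' @export
compute_metrics <- function(counts, averaging = c("auto", "binary", "macro"),
                            positive = NULL) {
  averaging <- match.arg(averaging)
  if (!is.matrix(counts)) {
    counts <- unlist(counts)
    stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
    m <- matrix(c(counts["tn"], counts["fp"], counts["fn"], counts["tp"]),
                2, 2, byrow = TRUE,
                dimnames = list(c("neg", "pos"), c("neg", "pos")))
    counts <- m
  }
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  total <- sum(counts)
  if (total < 1) stop("confusion table is empty.")
  k <- nrow(counts)
  if (averaging == "auto") averaging <- if (k == 2) "binary" else "macro"
  acc <- sum(diag(counts)) / total
  if (averaging == "binary") {
    stopifnot(k == 2)
    pos <- positive %||% rownames(counts)[2]
    pi <- match(pos, rownames(counts))
    if (is.na(pi)) stop("positive class '", pos, "' not found in the table.")
    tp <- counts[pi, pi]
    fp <- sum(counts[-pi, pi])
    fn <- sum(counts[pi, -pi])
    prec <- safe_div(tp, tp + fp, "precision")
    rec <- safe_div(tp, tp + fn, "recall")
    f1 <- if (prec + rec == 0) {
      warning("F1 undefined (precision + recall = 0); reporting 0.")
      0
    } else 2 * prec * rec / (prec + rec)
  } else {
    per <- lapply(seq_len(k), function(i) {
      tp <- counts[i, i]
      fp <- sum(counts[-i, i])
      fn <- sum(counts[i, -i])
      p <- safe_div(tp, tp + fp, paste0("precision[", rownames(counts)[i], "]"))
      r <- safe_div(tp, tp + fn, paste0("recall[", rownames(counts)[i], "]"))
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      c(p, r, f)
    })
    per <- do.call(rbind, per)
    prec <- mean(per[, 1]); rec <- mean(per[, 2]); f1 <- mean(per[, 3])
  }
  tibble::tibble(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 averaging = averaging, n = total)
}

#' ROC curve and AUC from scores
#'
#' Builds the step ROC curve by sweeping a threshold over the distinct
#' scores, and computes the AUC as the Mann-Whitney pair statistic
#' `P(score+ > score-) + 0.5 P(tie)`. The trapezoidal area under the step
#' curve equals this statistic; both routes are exposed so they can be
#' checked against each other.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels Logical vector (or coercible) marking positives.
#' @return A list with `points` (tibble of `threshold`, `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE))$auc  # 0.5
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve.")
  }
  # pair statistic via midranks
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # step curve: descending threshold sweep over distinct scores
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n_neg, numeric(1))
  points <- tibble::tibble(threshold = c(Inf, thr),
                           fpr = c(0, fpr), tpr = c(0, tpr))
  list(points = points, auc = auc)
}

# trapezoidal area under an ROC point set (used as the cross-check route)
trapezoid_auc <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                            utils::tail(points$tpr, -1)) / 2)
}

# Pooled cross-validated scores for one mask + classifier: every observation
# is scored by the fold model that did not train on it. Returns numeric
# scores (probability of the positive class for binary problems) and hard
# predictions.
cv_scores <- function(fsd, mask, spec) {
  withr::with_seed(spec$cv_seed, {
    k <- spec$cv_folds
    min_class <- min(table(fsd$y))
    if (min_class < k) k <- max(2L, min_class)
    folds <- stratified_folds(fsd$y, k)
    x <- fsd$x[, mask, drop = FALSE]
    n <- nrow(x)
    pred <- factor(rep(levels(fsd$y)[1], n), levels = levels(fsd$y))
    score <- numeric(n)
    for (f in seq_len(k)) {
      te <- folds == f
      res <- predict_scores(spec$classifier, spec$classifier_params,
                            x[!te, , drop = FALSE], fsd$y[!te],
                            x[te, , drop = FALSE])
      pred[te] <- res$pred
      score[te] <- res$score
    }
    list(pred = pred, score = score, folds = folds)
  })
}

# Label + positive-class-score predictions per backend (binary focus; for
# multiclass the score is the winning-class probability and ROC is skipped
# upstream).
predict_scores <- function(classifier, params, xtr, ytr, xte) {
  nlev <- nlevels(ytr)
  pos <- levels(ytr)[nlev]
  switch(classifier,
    knn = {
      k <- params$k %||% 5L
      pred <- class::knn(xtr, xte, cl = ytr, k = min(k, nrow(xtr)), prob = TRUE)
      pwin <- attr(pred, "prob")
      score <- ifelse(pred == pos, pwin, 1 - pwin)
      list(pred = pred, score = score)
    },
    svm = {
      args <- utils::modifyList(list(kernel = "radial", scale = FALSE,
                                     probability = TRUE), params)
      fit <- do.call(e1071::svm, c(list(x = xtr, y = ytr), args))
      pred <- stats::predict(fit, xte, probability = TRUE)
      pr <- attr(pred, "probabilities")
      list(pred = pred, score = pr[, pos])
    },
    random_forest = {
      args <- utils::modifyList(list(ntree = 100L), params)
      fit <- do.call(randomForest::randomForest, c(list(x = xtr, y = ytr), args))
      pr <- stats::predict(fit, xte, type = "prob")
      pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                     levels = levels(ytr))
      list(pred = pred, score = pr[, pos])
    },
    decision_tree = {
      df_tr <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      pr <- stats::predict(fit, data.frame(xte, check.names = FALSE))
      pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                     levels = levels(ytr))
      list(pred = pred, score = pr[, pos])
    },
    xgboost = {
      args <- utils::modifyList(
        list(nrounds = 30L, max_depth = 4L, learning_rate = 0.3,
             verbosity = 0L, nthreads = 1L),
        params)
      fit <- do.call(xgboost::xgboost, c(list(x = xtr, y = ytr), args))
      pred <- stats::predict(fit, xte, type = "class")
      p <- stats::predict(fit, xte)
      score <- if (nlev == 2) as.numeric(p) else p[, pos]
      list(pred = pred, score = score)
    },
    stop("unknown classifier: ", classifier)
  )
}

#' Evaluate a final feature mask with a classifier
#'
#' Produces the full assessment report for a chosen mask and classifier:
#' pooled cross-validated predictions (every observation scored out-of-fold),
#' the confusion matrix, accuracy / precision / recall / F1, and for binary
#' targets the ROC curve and AUC.
#'
#' @inheritParams evaluate_fitness
#' @param mask Logical mask, a character vector of feature names, or a
#'   `cfa_sa_fit` object whose best mask is used.
#' @param averaging Passed to [compute_metrics()].
#' @return An object of class `eval_report`: `counts`, `metrics` (tibble),
#'   `roc` (tibble or `NULL`), `auc` (or `NA` for multiclass), `classifier`.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' d <- generate_synthetic(synth_spec(n = 100, d = 4, informative = 1,
#'                                    effect_size = 4, seed = 2))
#' rep <- evaluate_mask(d, "class", c(TRUE, FALSE, FALSE, FALSE),
#'                      fitness_spec(cv_folds = 4))
#' glance(rep)
#' @export
evaluate_mask <- function(data, target, mask, spec = fitness_spec(),
                          averaging = c("auto", "binary", "macro")) {
  averaging <- match.arg(averaging)
  fsd <- as_fs_dataset(data, target)
  d <- ncol(fsd$x)
  if (inherits(mask, "cfa_sa_fit")) mask <- mask$best$mask
  if (is.character(mask)) {
    unknown <- setdiff(mask, fsd$feature_names)
    if (length(unknown)) stop("unknown feature names: ",
                              paste(unknown, collapse = ", "))
    mask <- fsd$feature_names %in% mask
  }
  if (length(mask) != d) {
    stop("mask length ", length(mask), " does not match feature count ", d, ".")
  }
  if (!any(mask)) stop("mask must select at least one feature.")
  cv <- cv_scores(fsd, mask, spec)
  counts <- confusion_counts(fsd$y, cv$pred)
  metrics <- compute_metrics(counts, averaging)
  roc <- NULL
  auc <- NA_real_
  if (nlevels(fsd$y) == 2) {
    pos <- levels(fsd$y)[2]
    ra <- roc_auc(cv$score, fsd$y == pos)
    roc <- ra$points
    auc <- ra$auc
  }
  structure(list(counts = counts, metrics = metrics, roc = roc, auc = auc,
                 classifier = spec$classifier,
                 selected_features = fsd$feature_names[mask],
                 n_selected = sum(mask)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$classifier, "on", x$n_selected, "features\n")
  print(x$counts)
  m <- x$metrics
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f",
              m$accuracy, m$precision, m$recall, m$f1))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the scalar metrics as JSON and CSV, and the ROC points (when
#' present) as CSV, into `dir` with the given file stem.
#'
#' @param report An `eval_report` object.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, default `"eval"`.
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir, stem = "eval") {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(as.list(report$metrics), list(auc = report$auc,
                                         classifier = report$classifier,
                                         n_selected = report$n_selected))
  jsonlite::write_json(out, file.path(dir, paste0(stem, "_metrics.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$metrics, file.path(dir, paste0(stem, "_metrics.csv")),
                   row.names = FALSE)
  if (!is.null(report$roc)) {
    utils::write.csv(report$roc, file.path(dir, paste0(stem, "_roc.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
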