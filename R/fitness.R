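#' Wrapper-objective specification
#'
#' The wrapper objective scores a candidate feature mask by the stratified
#' k-fold cross-validated accuracy of a classifier trained on exactly the
#' masked columns, blended with an optional parsimony term:
#'
#' \deqn{f(m) = w \cdot \overline{acc}_{CV}(m) + (1 - w)\,(1 - |m| / d)}
#'
#' With `penalty_weight = 1` (the default) the objective is pure CV accuracy.
#' The CV split and every stochastic classifier are seeded from `cv_seed`
#' inside the evaluation, so the objective is a deterministic function of the
#' mask and evaluating it never disturbs the optimizer's RNG stream.
#'
#' @param classifier One of `"knn"`, `"svm"`, `"random_forest"`,
#'   `"xgboost"`, `"decision_tree"`. kNN (k = 5) is the default search-time
#'   classifier: it is fast, has no fitting phase, and is sensitive to
#'   irrelevant columns, which is exactly what a wrapper needs.
#' @param classifier_params Named list of classifier arguments
#'   (e.g. `list(k = 5)` for knn, `list(ntree = 100)` for random forest,
#'   `list(nrounds = 30)` for xgboost).
#' @param cv_folds Number of stratified folds (>= 2). Reduced with a warning
#'   when the rarest class has fewer members than folds.
#' @param cv_seed Seed for the fold assignment and classifier randomness.
#' @param penalty_weight Weight w in `[0, 1]`; 1 means pure accuracy, lower
#'   values reward smaller subsets.
#'
#' @return An object of class `fitness_spec`.
#' @examples
#' fitness_spec()
#' fitness_spec("random_forest", list(ntree = 100), penalty_weight = 0.9)
#' @export
fitness_spec <- function(classifier = c("knn", "svm", "random_forest",
                                        "xgboost", "decision_tree"),
                         classifier_params = list(),
                         cv_folds = 5, cv_seed = 2026L, penalty_weight = 1) {
  classifier <- match.arg(classifier)
  stopifnot(is.list(classifier_params))
  stopifnot(is.numeric(cv_folds), cv_folds >= 2, cv_folds == as.integer(cv_folds))
  stopifnot(is.numeric(penalty_weight), penalty_weight >= 0, penalty_weight <= 1)
  structure(list(classifier = classifier, classifier_params = classifier_params,
                 cv_folds = as.integer(cv_folds), cv_seed = as.integer(cv_seed),
                 penalty_weight = penalty_weight),
            class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat("<fitness_spec>", x$classifier, "|", x$cv_folds, "folds | w =",
      x$penalty_weight, "| cv_seed =", x$cv_seed, "\n")
  invisible(x)
}

# Stratified fold assignment: within each class, members are shuffled and
# dealt round-robin, so fold class proportions match the data as closely as
# integer counts allow. Deterministic given the current RNG state.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Train on (xtr, ytr), predict hard labels for xte. x matrices are numeric
# with >= 1 column; y is a factor. Each backend receives its params merged
# over sensible defaults.
train_predict <- function(classifier, params, xtr, ytr, xte) {
  switch(classifier,
    knn = {
      k <- params$k %||% 5L
      class::knn(xtr, xte, cl = ytr, k = min(k, nrow(xtr)))
    },
    svm = {
      args <- utils::modifyList(list(kernel = "radial", scale = FALSE), params)
      fit <- do.call(e1071::svm, c(list(x = xtr, y = ytr), args))
      stats::predict(fit, xte)
    },
    random_forest = {
      args <- utils::modifyList(list(ntree = 100L), params)
      fit <- do.call(randomForest::randomForest, c(list(x = xtr, y = ytr), args))
      stats::predict(fit, xte)
    },
    decision_tree = {
      df_tr <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      pred <- stats::predict(fit, data.frame(xte, check.names = FALSE), type = "class")
      pred
    },
    xgboost = {
      args <- utils::modifyList(
        list(nrounds = 30L, max_depth = 4L, learning_rate = 0.3,
             verbosity = 0L, nthreads = 1L),
        params)
      fit <- do.call(xgboost::xgboost, c(list(x = xtr, y = ytr), args))
      stats::predict(fit, xte, type = "class")
    },
    stop("unknown classifier: ", classifier)
  )
}

#' Evaluate the wrapper objective for one feature mask
#'
#' Computes `w * mean CV accuracy + (1 - w) * (1 - |mask| / d)` for the masked
#' columns of the dataset. Deterministic given `spec$cv_seed`; the global RNG
#' stream is left untouched.
#'
#' @param mask Logical vector of length d with at least one `TRUE`.
#' @param data A data frame containing features and the target column.
#' @param target Name of the target column.
#' @param spec A [fitness_spec()] object.
#' @return A single numeric fitness in `[0, 1]`.
#' @examples
#' d <- generate_synthetic(synth_spec(n = 80, d = 4, informative = 1,
#'                                    effect_size = 3, seed = 1))
#' evaluate_fitness(c(TRUE, FALSE, FALSE, FALSE), d, "class",
#'                  fitness_spec(cv_folds = 4))
#' @export
evaluate_fitness <- function(mask, data, target, spec = fitness_spec()) {
  fsd <- as_fs_dataset(data, target)
  evaluate_fitness_impl(mask, fsd, spec)
}

# Implementation against the validated internal container.
evaluate_fitness_impl <- function(mask, fsd, spec) {
  d <- ncol(fsd$x)
  if (length(mask) != d) {
    stop("mask length ", length(mask), " does not match feature count ", d, ".")
  }
  if (!any(mask)) stop("mask must select at least one feature.")
  acc <- withr::with_seed(spec$cv_seed, {
    k <- spec$cv_folds
    min_class <- min(table(fsd$y))
    if (min_class < k) {
      k <- max(2L, min_class)
      warning("reducing cv_folds to ", k,
              ": rarest class has only ", min_class, " members.")
    }
    folds <- stratified_folds(fsd$y, k)
    x <- fsd$x[, mask, drop = FALSE]
    fold_acc <- vapply(seq_len(k), function(f) {
      te <- folds == f
      pred <- tryCatch(
        train_predict(spec$classifier, spec$classifier_params,
                      x[!te, , drop = FALSE], fsd$y[!te], x[te, , drop = FALSE]),
        error = function(e) {
          stop("classifier '", spec$classifier, "' failed on mask {",
               paste(which(mask), collapse = ","), "}: ", conditionMessage(e))
        })
      mean(pred == fsd$y[te])
    }, numeric(1))
    mean(fold_acc)
  })
  w <- spec$penalty_weight
  w * acc + (1 - w) * (1 - sum(mask) / d)
}

#' Build a memoised fitness function for one dataset/spec pair
#'
#' Wrapper cross-validation dominates the optimizer's cost and the same masks
#' recur constantly, so fitness values are cached by the mask's bit-string
#' key within a run. The returned closure maps a logical mask to its fitness;
#' `attr(fn, "stats")()` reports hits and misses, and `attr(fn, "evals")()`
#' the number of distinct CV evaluations performed.
#'
#' @param data A data frame containing features and the target column.
#' @param target Name of the target column.
#' @param spec A [fitness_spec()] object.
#' @return A function `mask -> fitness` with `stats`/`evals` accessor
#'   attributes.
#' @export
make_fitness_fn <- function(data, target, spec = fitness_spec()) {
  fsd <- as_fs_dataset(data, target)
  make_fitness_fn_impl(fsd, spec)
}

make_fitness_fn_impl <- function(fsd, spec) {
  cache <- new.env(parent = emptyenv())
  hits <- 0L
  misses <- 0L
  fn <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- evaluate_fitness_impl(mask, fsd, spec)
      cache[[key]] <- val
      misses <<- misses + 1L
    } else {
      hits <<- hits + 1L
    }
    val
  }
  attr(fn, "stats") <- function() c(hits = hits, misses = misses)
  attr(fn, "evals") <- function() misses
  fn
}

`%||%` <- function(a, b) if (is.null(a)) b else a
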