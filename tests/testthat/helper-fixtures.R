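# Fixtures are built in code at test time; nothing is read from disk except
# the tiny CSV/ARFF files the io tests write themselves.

# Perfectly separable binary dataset: feature 1 determines the class with a
# wide margin, remaining columns are pure noise.
make_separable <- function(n = 100, d = 3, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(c("neg", "pos"), length.out = n)
    x <- matrix(stats::rnorm(n * d), n, d)
    x[, 1] <- ifelse(y == "pos", 1, 0) + stats::runif(n, 0, 0.2)
    colnames(x) <- paste0("f", seq_len(d))
    df <- tibble::as_tibble(as.data.frame(x))
    df$class <- factor(y, levels = c("neg", "pos"))
    df
  })
}

# Toy mask objective with a unique optimum at `target`: 1 - hamming/d.
# Used as a classifier-free stand-in where only optimizer mechanics matter.
make_toy_fitness <- function(target) {
  d <- length(target)
  function(mask) 1 - sum(mask != target) / d
}

# Fast fitness spec shared by optimizer tests.
fast_spec <- function(...) fitness_spec("knn", list(k = 5L), cv_folds = 4, ...)
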