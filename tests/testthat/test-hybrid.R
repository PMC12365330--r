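test_that("exhaustive search enumerates every non-empty mask", {
  d <- make_separable(n = 60, d = 3, seed = 14)
  or <- exhaustive_select(d, "class", fast_spec())
  expect_equal(or$n_evals, 7L)
  expect_equal(nrow(or$table), 7L)
  expect_true(all(or$table$fitness <= or$best$fitness))
  # the separating feature must be in the optimum
  expect_true("f1" %in% or$selected_features)
  expect_error(exhaustive_select(make_separable(20, 4), "class",
                                 fast_spec(), max_d = 3), "guard bound")
})

test_that("exhaustive ties break to fewer features, then lowest indices", {
  # with w = 0 the objective depends only on subset size: all singletons tie
  d <- make_separable(n = 40, d = 4, seed = 15)
  or <- exhaustive_select(d, "class", fast_spec(penalty_weight = 0))
  expect_equal(or$best$mask, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(or$best$fitness, 1 - 1 / 4)
})

test_that("the hybrid attains the exhaustive optimum on a separable problem", {
  d <- make_separable(n = 80, d = 3, seed = 16)
  spec <- fast_spec()
  or <- exhaustive_select(d, "class", spec)
  fit <- cuttlefish_select(d, "class",
                           cfa = cfa_params(n_pop = 8, max_iter = 10),
                           sa = sa_params(n_iter = 30),
                           fitness = spec, seed = 2)
  expect_equal(fit$best$fitness, or$best$fitness)
  expect_true("f1" %in% fit$selected_features)
})

test_that("a one-iteration run completes with a single history record", {
  d <- make_separable(n = 40, d = 3, seed = 17)
  fit <- cuttlefish_select(d, "class", cfa = cfa_params(n_pop = 4, max_iter = 1),
                           sa = sa_params(n_iter = 5), fitness = fast_spec(),
                           seed = 3)
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$history$iteration, 1L)
})

test_that("identical seeds give identical runs; different seeds may differ", {
  d <- make_separable(n = 60, d = 4, seed = 18)
  args <- list(d, "class", cfa = cfa_params(n_pop = 8, max_iter = 8),
               sa = sa_params(n_iter = 20), fitness = fast_spec())
  f1 <- do.call(cuttlefish_select, c(args, seed = 7))
  f2 <- do.call(cuttlefish_select, c(args, seed = 7))
  expect_identical(f1$best, f2$best)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$selected_features, f2$selected_features)
})

test_that("best-so-far fitness is non-decreasing and cache-coherent", {
  d <- make_separable(n = 60, d = 5, seed = 19)
  spec <- fast_spec()
  fit <- cuttlefish_select(d, "class", cfa = cfa_params(n_pop = 8, max_iter = 15),
                           sa = sa_params(n_iter = 20), fitness = spec, seed = 5)
  expect_true(all(diff(fit$history$best_fitness) >= 0))
  # re-evaluating the reported mask reproduces the reported fitness exactly
  expect_identical(evaluate_fitness(fit$best$mask, d, "class", spec),
                   fit$best$fitness)
  # selected names are the true positions of the mask
  expect_identical(fit$selected_features, fit$feature_names[fit$best$mask])
})

test_that("a zero SA budget reduces the hybrid to plain CFA", {
  d <- make_separable(n = 60, d = 4, seed = 20)
  args <- list(d, "class", cfa = cfa_params(n_pop = 8, max_iter = 10),
               fitness = fast_spec())
  sa_off <- do.call(cuttlefish_select,
                    c(args, list(sa = sa_params(n_iter = 0), seed = 9)))
  cfa_only <- do.call(cuttlefish_select,
                      c(args, list(sa = sa_params(), seed = 9,
                                   mode = "cfa_only")))
  expect_identical(sa_off$best, cfa_only$best)
  expect_identical(sa_off$history, cfa_only$history)
})

test_that("the run manifest reproduces the run and serialises faithfully", {
  d <- make_separable(n = 40, d = 3, seed = 21)
  fit <- cuttlefish_select(d, "class", cfa = cfa_params(n_pop = 4, max_iter = 3),
                           sa = sa_params(n_iter = 5), fitness = fast_spec(),
                           seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(fit, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$seed, 11)
  expect_equal(m$best_fitness, fit$best$fitness)
  expect_equal(m$selected_features, fit$selected_features)
  expect_equal(m$history$best_fitness, fit$history$best_fitness)
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- make_separable(n = 40, d = 3, seed = 22)
  fit <- cuttlefish_select(d, "class", cfa = cfa_params(n_pop = 4, max_iter = 2),
                           sa = sa_params(n_iter = 5), fitness = fast_spec(),
                           seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_named(td, c("feature", "position", "selected"))
  g <- glance(fit)
  expect_equal(g$n_selected, sum(fit$best$mask))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("degenerate datasets are rejected before any optimization", {
  d <- make_separable(20, 3)
  single <- d; single$class <- factor(rep("neg", 20))
  expect_error(cuttlefish_select(single, "class"), "2 distinct classes")
  expect_error(cuttlefish_select(d[0, ], "class"), "2 rows")
})
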