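test_that("CSV reading imputes '?' cells by the column median", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,tsh,on_thyroxine,diagnosis",
               "30,1.2,t,neg",
               "40,?,f,pos",
               "50,2.2,t,neg"), path)
  d <- read_dataset_csv(path, "diagnosis")
  expect_equal(d$tsh[2], median(c(1.2, 2.2)))
  expect_equal(d$on_thyroxine, c(1, 0, 1))
  expect_equal(attr(d, "missing_counts")[["tsh"]], 1L)
  expect_equal(unname(attr(d, "feature_kinds")),
               c("numeric", "numeric", "boolean"))
  expect_s3_class(d$diagnosis, "factor")
})

test_that("a missing target column is reported with the available names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_dataset_csv(path, "label"), "a, b")
})

test_that("categorical columns are label-encoded deterministically", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,tsh,diagnosis",
               "M,1,neg", "F,2,pos", "F,3,neg", "M,4,pos"), path)
  d <- read_dataset_csv(path, "diagnosis")
  expect_equal(d$sex, c(1, 0, 0, 1))  # alphabetical: F = 0, M = 1
  expect_equal(unname(attr(d, "feature_kinds")[["sex"]]), "categorical")
})

test_that("ARFF round-trips through the same contract as CSV", {
  path <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation thyroid_mini",
               "@attribute age numeric",
               "@attribute tsh numeric",
               "@attribute sex {M,F}",
               "@attribute diagnosis {neg,pos}",
               "@data",
               "30,1.2,M,neg",
               "41,?,F,pos",
               "52,2.0,F,neg",
               "63,3.1,M,pos"), path)
  d <- read_dataset_arff(path, "diagnosis")
  expect_equal(nrow(d), 4)
  expect_equal(d$tsh[2], median(c(1.2, 2.0, 3.1)))
  expect_true(all(vapply(d[setdiff(names(d), "diagnosis")], is.numeric,
                         logical(1))))
  expect_error(read_dataset_arff(path, "label"), "available attributes")
})

test_that("an encoded dataset round-trips exactly through CSV", {
  d <- generate_synthetic(synth_spec(n = 30, d = 4, informative = 1,
                                     effect_size = 2, seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, path)
  d2 <- read_dataset_csv(path, "class")
  expect_equal(as.matrix(d2[paste0("f", 1:4)]), as.matrix(d[paste0("f", 1:4)]),
               tolerance = 1e-12)
  expect_equal(d2$class, d$class)
})

test_that("the generator is reproducible and respects its spec", {
  sp <- synth_spec(n = 200, d = 6, informative = c(1, 2), effect_size = 2,
                   class_balance = 0.3, missing_rate = 0.05, seed = 10)
  d1 <- generate_synthetic(sp)
  d2 <- generate_synthetic(sp)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(anyNA(d1))
  expect_equal(levels(d1$class), c("neg", "pos"))
  expect_gt(sum(attr(d1, "missing_counts")), 0)
})

test_that("informative features carry the specified effect size", {
  sp <- synth_spec(n = 1e4, d = 5, informative = c(1, 3), effect_size = 2,
                   class_balance = 0.4, seed = 11)
  d <- generate_synthetic(sp)
  x <- as.matrix(d[paste0("f", 1:5)])
  y <- d$class == "pos"
  for (j in sp$informative) {
    diff_mean <- mean(x[y, j]) - mean(x[!y, j])
    se <- sqrt(1 / sum(y) + 1 / sum(!y))
    expect_lt(abs(diff_mean - 2), 3 * se)
  }
  for (j in sp$noise) {
    diff_mean <- mean(x[y, j]) - mean(x[!y, j])
    se <- sqrt(1 / sum(y) + 1 / sum(!y))
    expect_lt(abs(diff_mean), 4 * se)
  }
})

test_that("redundant features track their source at the requested correlation", {
  sp <- synth_spec(n = 5e3, d = 4, informative = 1,
                   redundant = data.frame(feature = 2, source = 1, rho = 0.9),
                   effect_size = 1.5, seed = 12)
  d <- generate_synthetic(sp)
  # the source carries the class shift, so the realized correlation sits a
  # little above rho: rho * sd(source) / sqrt(rho^2 var(source) + 1 - rho^2)
  v1 <- stats::var(d$f1)
  expected <- 0.9 * sqrt(v1) / sqrt(0.81 * v1 + 0.19)
  expect_equal(cor(d$f1, d$f2), expected, tolerance = 0.03)
  expect_gt(cor(d$f1, d$f2), 0.85)
  expect_equal(sp$noise, c(3, 4))
})

test_that("a null generator yields label-independent features", {
  sp <- synth_spec(n = 1000, d = 4, informative = 1, effect_size = 0,
                   class_balance = 0.3, seed = 13)
  d <- generate_synthetic(sp)
  f <- evaluate_fitness(rep(TRUE, 4), d, "class",
                        fitness_spec("decision_tree", cv_folds = 5))
  p_maj <- max(table(d$class)) / nrow(d)
  expect_lt(abs(f - p_maj), 0.08)
})

test_that("recovery_score counts informative hits and noise false positives", {
  sp <- synth_spec(n = 10, d = 10, informative = c(1, 2), effect_size = 2,
                   seed = 1)
  exact <- recovery_score(c(TRUE, TRUE, rep(FALSE, 8)), sp)
  expect_equal(exact$recall_informative, 1)
  expect_equal(exact$fp_noise_rate, 0)
  all_sel <- recovery_score(rep(TRUE, 10), sp)
  expect_equal(all_sel$recall_informative, 1)
  expect_equal(all_sel$fp_noise_rate, 1)
  half <- recovery_score(c(TRUE, rep(FALSE, 4), TRUE, rep(FALSE, 4)), sp)
  expect_equal(half$recall_informative, 0.5)
  expect_equal(half$fp_noise_rate, 1 / 8)
})

test_that("dataset validation rejects degenerate input", {
  d <- make_separable(20, 3)
  one_class <- d; one_class$class <- factor(rep("neg", 20))
  expect_error(cuttleselect:::as_fs_dataset(one_class, "class"), "2 distinct classes")
  expect_error(cuttleselect:::as_fs_dataset(d[, c("f1", "class")], "class"),
               "2 candidate features")
  with_na <- d; with_na$f1[1] <- NA
  expect_error(cuttleselect:::as_fs_dataset(with_na, "class"), "missing values")
})
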