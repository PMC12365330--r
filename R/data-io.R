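#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# ---- internal validated container ------------------------------------------
# Every public entry point funnels its data through this single validation
# path, so file-derived and synthetic datasets obey identical invariants:
# numeric feature matrix, factor target with >= 2 levels, no missing values.
as_fs_dataset <- function(data, target) {
  stopifnot(is.data.frame(data))
  if (!target %in% names(data)) {
    stop("target column '", target, "' not found; available columns: ",
         paste(names(data), collapse = ", "))
  }
  if (nrow(data) < 2) stop("at least 2 rows are required.")
  y <- data[[target]]
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("target must have at least 2 distinct classes.")
  xdf <- data[setdiff(names(data), target)]
  if (ncol(xdf) < 2) stop("at least 2 candidate features are required.")
  not_num <- names(xdf)[!vapply(xdf, is.numeric, logical(1))]
  if (length(not_num)) {
    stop("non-numeric feature columns after encoding: ",
         paste(not_num, collapse = ", "),
         ". Use read_dataset_csv()/read_dataset_arff() or encode first.")
  }
  x <- as.matrix(xdf)
  if (anyNA(x)) stop("features contain missing values; impute before use.")
  storage.mode(x) <- "double"
  list(x = x, y = y, feature_names = colnames(x))
}

# ---- encoding & imputation -------------------------------------------------

impute_mode <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  names(tab)[1]
}

# Shared preprocessing: boolean-ish columns -> 0/1, character/factor columns
# label-encoded, then median (numeric) / mode (categorical, applied before
# encoding) imputation. Returns tibble + per-column kind + missing counts.
encode_and_impute <- function(df, target) {
  kinds <- character(ncol(df))
  names(kinds) <- names(df)
  missing_counts <- vapply(df, function(v) sum(is.na(v)), integer(1))
  bool_tokens <- list(c("t", "f"), c("T", "F"), c("true", "false"),
                      c("TRUE", "FALSE"), c("y", "n"), c("yes", "no"))
  for (nm in names(df)) {
    v <- df[[nm]]
    if (nm == target) {
      if (anyNA(v)) stop("target column '", nm, "' contains missing values.")
      df[[nm]] <- factor(v)
      kinds[nm] <- "target"
      next
    }
    if (is.logical(v)) {
      if (anyNA(v)) v[is.na(v)] <- as.logical(impute_mode(v))
      df[[nm]] <- as.numeric(v)
      kinds[nm] <- "boolean"
    } else if (is.numeric(v)) {
      if (all(is.na(v))) stop("column '", nm, "' is entirely missing.")
      if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      df[[nm]] <- v
      kinds[nm] <- "numeric"
    } else {
      v <- as.character(v)
      if (all(is.na(v))) stop("column '", nm, "' is entirely missing.")
      obs <- unique(v[!is.na(v)])
      is_bool <- any(vapply(bool_tokens, function(tk) all(obs %in% tk), logical(1)))
      if (anyNA(v)) v[is.na(v)] <- impute_mode(v)
      if (is_bool) {
        truthy <- c("t", "T", "true", "TRUE", "y", "yes")
        df[[nm]] <- as.numeric(v %in% truthy)
        kinds[nm] <- "boolean"
      } else {
        lev <- sort(unique(v))
        df[[nm]] <- as.numeric(factor(v, levels = lev)) - 1
        kinds[nm] <- "categorical"
      }
    }
  }
  out <- tibble::as_tibble(df)
  attr(out, "feature_kinds") <- kinds[names(kinds) != target]
  attr(out, "missing_counts") <- missing_counts
  attr(out, "target") <- target
  attr(out, "provenance") <- "file"
  out
}

#' Read a tabular classification dataset from CSV
#'
#' Reads an RFC-4180 CSV with a header row, treats `na_tokens` (by default
#' `"?"`, `"NA"` and the empty string) as missing, converts t/f-style boolean
#' columns to 0/1, label-encodes remaining categorical columns, and imputes
#' missing values (median for numeric, mode for boolean/categorical). Row
#' order is preserved. Imputation happens once, before any cross-validation;
#' the mild information leakage this implies is documented in the package
#' vignette.
#'
#' @param path Path to the CSV file.
#' @param target Name of the target column (kept as a factor, not encoded).
#' @param na_tokens Character vector of tokens to treat as missing.
#' @return A tibble of encoded features plus the target column, carrying
#'   `feature_kinds`, `missing_counts`, `target` and `provenance` attributes.
#' @export
read_dataset_csv <- function(path, target, na_tokens = c("?", "NA", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, na.strings = na_tokens,
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (!target %in% names(df)) {
    stop("target column '", target, "' not found; available columns: ",
         paste(names(df), collapse = ", "))
  }
  encode_and_impute(df, target)
}

#' Read a tabular classification dataset from ARFF
#'
#' Reads a Weka-dialect ARFF file (the format UCI thyroid distributions ship
#' in), where `'?'` marks missing values, then applies the same encoding and
#' imputation contract as [read_dataset_csv()]. Nominal attribute domains are
#' recorded in the `feature_kinds` attribute.
#'
#' @param path Path to the ARFF file.
#' @param target Name of the target attribute.
#' @return A tibble as for [read_dataset_csv()].
#' @export
read_dataset_arff <- function(path, target) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(foreign::read.arff(path), error = function(e) {
    stop("failed to parse ARFF file '", path, "': ", conditionMessage(e))
  })
  if (!target %in% names(df)) {
    stop("target attribute '", target, "' not found; available attributes: ",
         paste(names(df), collapse = ", "))
  }
  encode_and_impute(df, target)
}

# ---- synthetic generator ---------------------------------------------------

#' Specification for a ground-truth-bearing synthetic clinical dataset
#'
#' Describes the statistical structure a wrapper-selection experiment
#' assumes: a small subset of *informative* features whose class-conditional
#' means differ by `effect_size` standard deviations, optional *redundant*
#' features correlated with informative ones, and the rest pure label-free
#' *noise*. Labels are Bernoulli with minority-positive balance, mirroring
#' clinical screening data.
#'
#' @param n Number of observations.
#' @param d Number of features.
#' @param informative Either a single count (the first so-many features) or
#'   an integer vector of 1-based feature indices.
#' @param redundant Optional data frame with columns `feature`, `source`,
#'   `rho`: feature index, informative source index, and correlation.
#' @param effect_size Standardized between-class mean shift of each
#'   informative feature (> 0; 0 is allowed and yields a null dataset).
#' @param class_balance Probability of the positive class, in (0, 1).
#' @param missing_rate Fraction of feature cells planted missing and then
#'   imputed through the standard path, in `[0, 1)`.
#' @param seed Seed for the generator.
#' @return An object of class `synth_spec`.
#' @examples
#' synth_spec(n = 300, d = 8, informative = 2, effect_size = 3, seed = 42)
#' @export
synth_spec <- function(n, d, informative, redundant = NULL, effect_size = 2,
                       class_balance = 0.3, missing_rate = 0, seed = 1L) {
  stopifnot(n >= 2, d >= 2)
  if (length(informative) == 1 && informative <= d && informative >= 1 &&
      !any(informative > d)) {
    informative <- seq_len(informative)
  }
  informative <- sort(unique(as.integer(informative)))
  stopifnot(all(informative >= 1), all(informative <= d))
  red_idx <- integer(0)
  if (!is.null(redundant)) {
    redundant <- as.data.frame(redundant)
    stopifnot(all(c("feature", "source", "rho") %in% names(redundant)))
    red_idx <- as.integer(redundant$feature)
    stopifnot(all(red_idx >= 1), all(red_idx <= d),
              all(redundant$source %in% informative),
              all(abs(redundant$rho) <= 1))
    if (length(intersect(red_idx, informative))) {
      stop("redundant features must be disjoint from informative features.")
    }
  }
  stopifnot(effect_size >= 0, class_balance > 0, class_balance < 1,
            missing_rate >= 0, missing_rate < 1)
  noise <- setdiff(seq_len(d), c(informative, red_idx))
  structure(list(n = as.integer(n), d = as.integer(d),
                 informative = informative, redundant = redundant,
                 noise = noise, effect_size = effect_size,
                 class_balance = class_balance, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> n =", x$n, " d =", x$d,
      "| informative:", paste(x$informative, collapse = ","),
      "| redundant:", if (is.null(x$redundant)) 0 else nrow(x$redundant),
      "| effect =", x$effect_size,
      "| P(pos) =", x$class_balance, "\n")
  invisible(x)
}

#' Generate a synthetic clinical classification dataset
#'
#' Draws labels Bernoulli(`class_balance`); each informative feature is
#' N(0, 1) in the negative class and N(`effect_size`, 1) in the positive
#' class; each redundant feature equals `rho * source + sqrt(1 - rho^2) *`
#' independent N(0, 1) noise; noise features are N(0, 1) independent of the
#' label. When `missing_rate > 0`, that fraction of feature cells is set
#' missing and imputed by the same path the file readers use. The generating
#' spec travels with the result so selections can be scored against ground
#' truth with [recovery_score()].
#'
#' @param spec A [synth_spec()] object.
#' @return A tibble with feature columns `f1...fd` and a factor target
#'   `class` (levels `neg`, `pos`), with the spec attached as the
#'   `synth_spec` attribute and `provenance = "synthetic"`.
#' @examples
#' d <- generate_synthetic(synth_spec(n = 100, d = 5, informative = 2,
#'                                    effect_size = 3, seed = 7))
#' table(d$class)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    y <- stats::rbinom(spec$n, 1, spec$class_balance)
    # guarantee both classes are present even at tiny n
    if (all(y == 0)) y[1] <- 1
    if (all(y == 1)) y[1] <- 0
    x <- matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d)
    for (j in spec$informative) {
      x[, j] <- x[, j] + spec$effect_size * y
    }
    if (!is.null(spec$redundant)) {
      for (r in seq_len(nrow(spec$redundant))) {
        j <- spec$redundant$feature[r]
        src <- spec$redundant$source[r]
        rho <- spec$redundant$rho[r]
        x[, j] <- rho * x[, src] + sqrt(1 - rho^2) * x[, j]
      }
    }
    if (spec$missing_rate > 0) {
      holes <- stats::runif(length(x)) < spec$missing_rate
      x[holes] <- NA_real_
    }
    colnames(x) <- paste0("f", seq_len(spec$d))
    df <- as.data.frame(x)
    df$class <- factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
    out <- encode_and_impute(df, "class")
    attr(out, "synth_spec") <- spec
    attr(out, "provenance") <- "synthetic"
    out
  })
}

#' Score a selected mask against synthetic ground truth
#'
#' `recall_informative` is the fraction of truly informative features the
#' mask selected; `fp_noise_rate` is the fraction of pure-noise features it
#' selected. Redundant features count toward neither.
#'
#' @param mask Logical vector of length `spec$d` (or a `cfa_sa_fit` object,
#'   whose best mask is used).
#' @param spec The [synth_spec()] that generated the data (taken from the
#'   data's attribute if a fit object is supplied and carries one).
#' @return A one-row tibble with columns `recall_informative` and
#'   `fp_noise_rate`.
#' @export
recovery_score <- function(mask, spec) {
  if (inherits(mask, "cfa_sa_fit")) mask <- mask$best$mask
  stopifnot(inherits(spec, "synth_spec"))
  if (length(mask) != spec$d) {
    stop("mask length ", length(mask), " does not match spec dimension ",
         spec$d, ".")
  }
  sel <- which(mask)
  tibble::tibble(
    recall_informative = length(intersect(sel, spec$informative)) /
      length(spec$informative),
    fp_noise_rate = if (length(spec$noise) == 0) 0 else
      length(intersect(sel, spec$noise)) / length(spec$noise)
  )
}

#' Write a dataset tibble to CSV
#'
#' Plain CSV writer used by the command-line `simulate` subcommand; the
#' encoded matrix round-trips exactly through [read_dataset_csv()].
#'
#' @param data A dataset tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
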