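#' Hybrid cuttlefish / simulated-annealing feature selection
#'
#' Runs the hybrid wrapper feature selector: a cuttlefish-algorithm (CFA)
#' outer loop whose group-2 and group-3 proposals are each refined by a
#' simulated-annealing (SA) inner loop, keeping the better of the raw and
#' refined solutions. The wrapper objective is cross-validated classifier
#' accuracy on the masked columns (see [fitness_spec()]); fitness values are
#' memoised by mask within the run.
#'
#' Per outer iteration: the scalar mean of the best position (`AVtop`) is
#' recomputed; group 1 members move by stretch/shrink toward the best
#' ([case12_update()]); group 2 members mirror the best ([case34_update()])
#' and are SA-refined; group 3 members sample an interval around the best
#' ([case5_update()]) and are SA-refined; group 4 members are redrawn
#' uniformly ([case6_position()]). A proposal replaces the member it came
#' from only if strictly fitter (greedy replacement), and the global best is
#' updated whenever any evaluated solution beats it, so the best-so-far
#' fitness trace is non-decreasing. The whole run is deterministic given
#' `seed`.
#'
#' @param data A data frame of numeric/encoded features plus the target
#'   column (from [read_dataset_csv()], [read_dataset_arff()],
#'   [generate_synthetic()], or your own encoding).
#' @param target Name of the target column.
#' @param cfa A [cfa_params()] object.
#' @param sa An [sa_params()] object; `n_iter = 0` disables annealing.
#' @param fitness A [fitness_spec()] object.
#' @param bounds An [fs_bounds()] object; defaults to the unit cube of the
#'   right dimension.
#' @param threshold Decode threshold for [decode_mask()].
#' @param seed Integer seed controlling every stochastic stream of the run.
#' @param mode `"hybrid"` (CFA + SA) or `"cfa_only"`, which forces the SA
#'   budget to zero and reduces the algorithm to plain CFA.
#' @param verbose Print per-iteration progress.
#'
#' @return An object of class `cfa_sa_fit` with components `best` (position,
#'   mask, fitness), `selected_features`, `history` (per-iteration tibble:
#'   best fitness and group-wise accepted replacements), `config`, `seed`,
#'   `n_evals`, and `cache_stats`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' d <- generate_synthetic(synth_spec(n = 120, d = 5, informative = 1,
#'                                    effect_size = 3, seed = 3))
#' fit <- cuttlefish_select(d, "class",
#'                          cfa = cfa_params(n_pop = 8, max_iter = 5),
#'                          sa = sa_params(n_iter = 10), seed = 1)
#' fit$selected_features
#' @export
cuttlefish_select <- function(data, target,
                              cfa = cfa_params(),
                              sa = sa_params(),
                              fitness = fitness_spec(),
                              bounds = NULL,
                              threshold = 0.5,
                              seed = 1L,
                              mode = c("hybrid", "cfa_only"),
                              verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfa, "cfa_params"), inherits(sa, "sa_params"),
            inherits(fitness, "fitness_spec"))
  fsd <- as_fs_dataset(data, target)
  d <- ncol(fsd$x)
  if (is.null(bounds)) bounds <- fs_bounds(d)
  stopifnot(inherits(bounds, "fs_bounds"))
  if (bounds$d != d) stop("bounds dimension ", bounds$d,
                          " does not match feature count ", d, ".")
  if (threshold <= bounds$lower || threshold >= bounds$upper) {
    stop("decode threshold must lie strictly inside the bounds.")
  }
  if (mode == "cfa_only") sa <- sa_params(sa$t0, sa$alpha, 0L, sa$step)

  fitness_fn <- make_fitness_fn_impl(fsd, fitness)

  run <- withr::with_seed(as.integer(seed), {
    pop <- init_population(bounds, cfa)
    sols <- lapply(pop$positions, function(p) {
      mask <- decode_mask(p, threshold)
      list(position = p, mask = mask, fitness = fitness_fn(mask),
           provenance = "init")
    })
    fits <- vapply(sols, `[[`, numeric(1), "fitness")
    best <- sols[[which.max(fits)]]

    hist_iter <- integer(cfa$max_iter)
    hist_best <- numeric(cfa$max_iter)
    hist_repl <- matrix(0L, cfa$max_iter, 4,
                        dimnames = list(NULL, paste0("repl_s", 1:4)))
    hist_evals <- integer(cfa$max_iter)

    propose <- function(i, av_top) {
      g <- pop$group[i]
      x <- sols[[i]]$position
      if (g == 1L) {
        R <- sample_reflection(cfa$r1, cfa$r2)
        newp <- case12_update(x, best$position, R, bounds)
        prov <- "case12"
      } else if (g == 2L) {
        V <- sample_visibility(cfa$v1, cfa$v2)
        newp <- case34_update(x, best$position, V, bounds)
        prov <- "case34"
      } else if (g == 3L) {
        V <- sample_visibility(cfa$v1, cfa$v2)
        newp <- case5_update(best$position, av_top, V, bounds)
        prov <- "case5"
      } else {
        newp <- case6_position(bounds)
        prov <- "case6"
      }
      mask <- decode_mask(newp, threshold)
      cand <- list(position = newp, mask = mask, fitness = fitness_fn(mask),
                   provenance = prov)
      if (g %in% c(2L, 3L)) {
        refined <- sa_refine(cand$position, cand$fitness, sa, fitness_fn,
                             bounds, threshold)
        # keep the better of the CFA proposal and its SA refinement
        if (refined$fitness > cand$fitness) {
          cand <- list(position = refined$position, mask = refined$mask,
                       fitness = refined$fitness, provenance = "sa_refined")
        }
      }
      cand
    }

    for (iter in seq_len(cfa$max_iter)) {
      av_top <- compute_av_top(best$position)
      repl <- integer(4)
      for (i in seq_len(cfa$n_pop)) {
        cand <- propose(i, av_top)
        if (cand$fitness > best$fitness) best <- cand
        if (cand$fitness > sols[[i]]$fitness) {
          sols[[i]] <- cand
          repl[pop$group[i]] <- repl[pop$group[i]] + 1L
        }
      }
      hist_iter[iter] <- iter
      hist_best[iter] <- best$fitness
      hist_repl[iter, ] <- repl
      hist_evals[iter] <- attr(fitness_fn, "evals")()
      if (verbose) {
        message(sprintf("iter %3d  best %.4f  evals %d",
                        iter, best$fitness, hist_evals[iter]))
      }
    }
    list(best = best,
         history = tibble::tibble(
           iteration = hist_iter, best_fitness = hist_best,
           repl_s1 = hist_repl[, 1], repl_s2 = hist_repl[, 2],
           repl_s3 = hist_repl[, 3], repl_s4 = hist_repl[, 4],
           n_evals = hist_evals))
  })

  structure(list(
    best = run$best,
    selected_features = fsd$feature_names[run$best$mask],
    history = run$history,
    config = list(cfa = cfa, sa = sa, fitness = fitness, bounds = bounds,
                  threshold = threshold, mode = mode, target = target),
    feature_names = fsd$feature_names,
    seed = as.integer(seed),
    n_evals = attr(fitness_fn, "evals")(),
    cache_stats = attr(fitness_fn, "stats")()
  ), class = "cfa_sa_fit")
}

#' @export
print.cfa_sa_fit <- function(x, ...) {
  cat("<cfa_sa_fit> mode:", x$config$mode,
      "| best fitness:", format(x$best$fitness, digits = 6),
      "| features:", sum(x$best$mask), "of", length(x$best$mask), "\n")
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  cat("  distinct fitness evaluations:", x$n_evals, "\n")
  invisible(x)
}

#' Exhaustive feature-subset search oracle
#'
#' Evaluates every non-empty feature mask (all `2^d - 1` of them) with the
#' identical wrapper objective and returns the maximum. Feasible only for
#' small `d`; refuses above `max_d`. Ties are broken toward fewer selected
#' features, then toward the subset whose sorted index list is
#' lexicographically smallest. Used to certify optimizer output.
#'
#' @inheritParams cuttlefish_select
#' @param max_d Guard bound on dimension (default 15).
#' @return An object of class `exhaustive_fit`: `best` (mask + fitness),
#'   `selected_features`, `table` (a tibble of all masks with their
#'   fitness), `n_evals`.
#' @examples
#' d <- generate_synthetic(synth_spec(n = 80, d = 3, informative = 1,
#'                                    effect_size = 4, seed = 5))
#' exhaustive_select(d, "class", fitness_spec(cv_folds = 4))
#' @export
exhaustive_select <- function(data, target, fitness = fitness_spec(),
                              max_d = 15) {
  stopifnot(inherits(fitness, "fitness_spec"))
  fsd <- as_fs_dataset(data, target)
  d <- ncol(fsd$x)
  if (d > max_d) {
    stop("exhaustive search refused: d = ", d, " exceeds the guard bound ",
         max_d, " (2^d - 1 evaluations).")
  }
  n_masks <- 2L^d - 1L
  masks <- vector("list", n_masks)
  fits <- numeric(n_masks)
  sizes <- integer(n_masks)
  keys <- character(n_masks)
  for (m in seq_len(n_masks)) {
    mask <- as.logical(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))))
    masks[[m]] <- mask
    fits[m] <- evaluate_fitness_impl(mask, fsd, fitness)
    sizes[m] <- sum(mask)
    keys[m] <- paste(sprintf("%02d", which(mask)), collapse = ",")
  }
  ord <- order(-fits, sizes, keys)
  top <- ord[1]
  structure(list(
    best = list(mask = masks[[top]], fitness = fits[top]),
    selected_features = fsd$feature_names[masks[[top]]],
    table = tibble::tibble(
      mask_id = seq_len(n_masks),
      features = vapply(masks, function(mk)
        paste(fsd$feature_names[mk], collapse = ","), character(1)),
      n_selected = sizes,
      fitness = fits),
    feature_names = fsd$feature_names,
    n_evals = n_masks
  ), class = "exhaustive_fit")
}

#' @export
print.exhaustive_fit <- function(x, ...) {
  cat("<exhaustive_fit>", x$n_evals, "masks evaluated | optimum:",
      format(x$best$fitness, digits = 6), "\n")
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Write a reproducibility manifest for a selection run
#'
#' Serialises everything needed to reproduce a [cuttlefish_select()] run
#' bit-for-bit: the resolved configuration, seed, selected features, best
#' fitness, evaluation counts, and the per-iteration history.
#'
#' @param fit A `cfa_sa_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path) {
  stopifnot(inherits(fit, "cfa_sa_fit"))
  cfg <- fit$config
  manifest <- list(
    package = "cuttleselect",
    mode = cfg$mode,
    seed = fit$seed,
    target = cfg$target,
    cfa = unclass(cfg$cfa),
    sa = unclass(cfg$sa),
    fitness = unclass(cfg$fitness),
    bounds = unclass(cfg$bounds),
    threshold = cfg$threshold,
    feature_names = fit$feature_names,
    selected_features = fit$selected_features,
    best_mask = as.integer(fit$best$mask),
    best_fitness = fit$best$fitness,
    n_evals = fit$n_evals,
    cache_stats = as.list(fit$cache_stats),
    history = fit$history
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
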