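#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection fit
#'
#' One row per candidate feature: its name, final best position component,
#' and whether it was selected.
#'
#' @param x A `cfa_sa_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `position`, `selected`.
#' @method tidy cfa_sa_fit
#' @export
tidy.cfa_sa_fit <- function(x, ...) {
  tibble::tibble(feature = x$feature_names,
                 position = x$best$position,
                 selected = x$best$mask)
}

#' Glance at a selection fit
#'
#' @param x A `cfa_sa_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: best fitness, number of selected features,
#'   iterations, distinct fitness evaluations, cache hits, seed, mode.
#' @method glance cfa_sa_fit
#' @export
glance.cfa_sa_fit <- function(x, ...) {
  tibble::tibble(best_fitness = x$best$fitness,
                 n_selected = sum(x$best$mask),
                 n_features = length(x$best$mask),
                 iterations = nrow(x$history),
                 n_evals = x$n_evals,
                 cache_hits = unname(x$cache_stats["hits"]),
                 seed = x$seed,
                 mode = x$config$mode)
}

#' Convergence plot for a selection fit
#'
#' Best-so-far fitness against outer iteration; the trace is non-decreasing
#' by construction (greedy replacement and best-ever bookkeeping).
#'
#' @param object A `cfa_sa_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cfa_sa_fit
#' @export
autoplot.cfa_sa_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = "Hybrid CFA-SA convergence",
                  subtitle = paste0("mode: ", object$config$mode,
                                    ", seed ", object$seed)) +
    ggplot2::theme_minimal()
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` object.
#' @param ... Unused.
#' @return The metrics tibble (accuracy, precision, recall, F1, averaging, n).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' Glance at an evaluation report
#'
#' @param x An `eval_report` object.
#' @param ... Unused.
#' @return A one-row tibble of the scalar metrics plus AUC, classifier and
#'   subset size.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(auc = x$auc, classifier = x$classifier,
                                  n_selected = x$n_selected))
}

#' ROC plot for an evaluation report
#'
#' @param object An `eval_report` object with a binary target.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) {
    stop("no ROC curve available (multiclass target); nothing to plot.")
  }
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (%s), AUC = %.3f",
                                  object$classifier, object$auc)) +
    ggplot2::theme_minimal()
}
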