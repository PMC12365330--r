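#' Simulated-annealing hyperparameters
#'
#' Defaults are the method's reference settings: initial temperature
#' 9, geometric cooling rate 0.95, 100 iterations, and a neighbour move that
#' perturbs each component by an independent Uniform(-0.1, 0.1) draw.
#'
#' @param t0 Initial temperature (> 0).
#' @param alpha Cooling rate in (0, 1]; the temperature after k steps is
#'   `t0 * alpha^k`.
#' @param n_iter Number of annealing iterations. Zero is allowed internally
#'   and makes [sa_refine()] a no-op, which is how the plain-CFA variant is
#'   obtained.
#' @param step Neighbour half-width: the perturbation of each component is
#'   uniform on `[-step, step]`.
#'
#' @return An object of class `sa_params`.
#' @examples
#' sa_params()
#' sa_params(n_iter = 0)  # disables annealing
#' @export
sa_params <- function(t0 = 9, alpha = 0.95, n_iter = 100, step = 0.1) {
  stopifnot(is.numeric(t0), t0 > 0)
  stopifnot(is.numeric(alpha), alpha > 0, alpha <= 1)
  stopifnot(is.numeric(n_iter), n_iter >= 0, n_iter == as.integer(n_iter))
  stopifnot(is.numeric(step), step > 0)
  structure(list(t0 = t0, alpha = alpha, n_iter = as.integer(n_iter), step = step),
            class = "sa_params")
}

#' @export
print.sa_params <- function(x, ...) {
  cat("<sa_params> t0 =", x$t0, " alpha =", x$alpha,
      " n_iter =", x$n_iter, " step =", x$step, "\n")
  invisible(x)
}

#' Geometric cooling step
#'
#' One application of the cooling schedule `t <- t * alpha`; after k steps
#' from `t0` the temperature is exactly `t0 * alpha^k`.
#'
#' @param t Current temperature (> 0).
#' @param alpha Cooling rate.
#' @return The lowered temperature.
#' @examples
#' cool_temperature(9, 0.95)  # 8.55
#' @export
cool_temperature <- function(t, alpha) {
  if (!is.numeric(t) || t <= 0) stop("temperature must be positive.")
  t * alpha
}

#' Metropolis acceptance probability
#'
#' Probability of accepting a candidate whose *cost* exceeds the current cost
#' by `delta_c` at temperature `t`: 1 whenever `delta_c <= 0` (improvements
#' and ties are always accepted) and `exp(-delta_c / t)` otherwise. Cost is
#' the negative of the fitness being maximized, so improving moves have
#' `delta_c <= 0`.
#'
#' @param delta_c Candidate cost minus current cost.
#' @param t Temperature (> 0).
#' @return A probability in `[0, 1]`, non-increasing in `delta_c` and
#'   non-decreasing in `t`.
#' @examples
#' acceptance_probability(-5, 9)  # 1: improvement
#' acceptance_probability(9, 9)   # exp(-1)
#' @export
acceptance_probability <- function(delta_c, t) {
  if (!is.numeric(t) || t <= 0) stop("temperature must be positive.")
  ifelse(delta_c <= 0, 1, exp(-delta_c / t))
}

#' Neighbour move for the annealer
#'
#' Perturbs every component of `current` by an independent uniform draw on
#' `[-step, step]`, then clamps the result into `bounds`. Before clamping,
#' no component moves further than `step`.
#'
#' @param current Current position vector (inside `bounds`).
#' @param bounds An [fs_bounds()] object.
#' @param step Half-width of the uniform perturbation.
#' @return A new position vector inside `bounds`.
#' @export
perturb_position <- function(current, bounds, step = 0.1) {
  clip_to_bounds(current + stats::runif(length(current), -step, step), bounds)
}

#' Simulated-annealing refinement of a solution
#'
#' Runs `n_iter` iterations of neighbour-propose / Metropolis-accept /
#' geometric-cool starting from `position`, evaluating each proposal through
#' `fitness_fn` on its decoded mask. The *best-ever* solution visited is
#' returned (not the final accepted state), so the returned fitness is never
#' below the starting fitness.
#'
#' @param position Starting position vector (inside `bounds`).
#' @param fitness Fitness of the starting position's mask (scalar).
#' @param params An [sa_params()] object.
#' @param fitness_fn Function mapping a logical mask to a scalar fitness
#'   (typically a memoised wrapper objective, see [make_fitness_fn()]).
#' @param bounds An [fs_bounds()] object.
#' @param threshold Decode threshold for [decode_mask()].
#' @return A list with elements `position`, `mask`, `fitness`.
#' @export
sa_refine <- function(position, fitness, params, fitness_fn, bounds,
                      threshold = 0.5) {
  stopifnot(inherits(params, "sa_params"))
  best_pos <- cur_pos <- position
  best_fit <- cur_fit <- fitness
  t <- params$t0
  n <- params$n_iter
  if (n > 0) {
    for (i in seq_len(n)) {
      cand_pos <- perturb_position(cur_pos, bounds, params$step)
      cand_mask <- decode_mask(cand_pos, threshold)
      cand_fit <- tryCatch(fitness_fn(cand_mask), error = function(e) {
        stop("fitness evaluation failed at annealing iteration ", i, ": ",
             conditionMessage(e))
      })
      delta_c <- (-cand_fit) - (-cur_fit)
      if (delta_c <= 0 || stats::runif(1) < acceptance_probability(delta_c, t)) {
        cur_pos <- cand_pos
        cur_fit <- cand_fit
        if (cand_fit > best_fit) {
          best_fit <- cand_fit
          best_pos <- cand_pos
        }
      }
      t <- cool_temperature(t, params$alpha)
    }
  }
  list(position = best_pos, mask = decode_mask(best_pos, threshold),
       fitness = best_fit)
}
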