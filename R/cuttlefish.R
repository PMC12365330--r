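#' Cuttlefish-algorithm hyperparameters
#'
#' The cuttlefish algorithm (CFA) mimics the light-reflection machinery of
#' cuttlefish skin: a population of candidate solutions is split into four
#' groups, each updated by one of six "cases" combining a *reflection* term
#' (a scaled existing position) and a *visibility* term (a scaled difference
#' toward the global best). `r1, r2` bound the random reflection coefficient
#' R and `v1, v2` bound the random visibility coefficient V.
#'
#' Defaults are the method's reference hyperparameter values:
#' `r1 = 0.5`, `r2 = -2`, `v1 = 1`, `v2 = -1`. With these, R is uniform on
#' `[-2, 0.5]` and V uniform on `[-1, 1]`.
#'
#' @param n_pop Population size N; at least 4 so that all four groups are
#'   non-empty.
#' @param r1,r2 Reflection-range constants (R ~ Uniform(min(r1,r2), max(r1,r2))).
#' @param v1,v2 Visibility-range constants.
#' @param max_iter Outer-loop iteration budget.
#'
#' @return An object of class `cfa_params`.
#' @examples
#' cfa_params(n_pop = 12, max_iter = 25)
#' @export
cfa_params <- function(n_pop = 12, r1 = 0.5, r2 = -2, v1 = 1, v2 = -1,
                       max_iter = 100) {
  stopifnot(is.numeric(n_pop), length(n_pop) == 1, n_pop == as.integer(n_pop))
  if (n_pop < 4) stop("`n_pop` must be at least 4: four non-empty groups are required.")
  stopifnot(is.numeric(max_iter), max_iter >= 1, max_iter == as.integer(max_iter))
  stopifnot(is.numeric(r1), is.numeric(r2), is.numeric(v1), is.numeric(v2))
  structure(list(n_pop = as.integer(n_pop), r1 = r1, r2 = r2, v1 = v1, v2 = v2,
                 max_iter = as.integer(max_iter)),
            class = "cfa_params")
}

#' @export
print.cfa_params <- function(x, ...) {
  cat("<cfa_params> N =", x$n_pop, " r1 =", x$r1, " r2 =", x$r2,
      " v1 =", x$v1, " v2 =", x$v2, " max_iter =", x$max_iter, "\n")
  invisible(x)
}

#' Draw reflection and visibility coefficients
#'
#' `sample_reflection()` returns `u * (r1 - r2) + r2`, a uniform draw on the
#' interval spanned by the two reflection constants; `sample_visibility()`
#' does the same for the visibility constants. With the default constants the
#' ranges are `[-2, 0.5]` and `[-1, 1]`.
#'
#' @param r1,r2,v1,v2 Range constants.
#' @param u A Uniform(0, 1) draw; defaults to a fresh draw from the current
#'   RNG stream (pass explicitly for closed-form checks).
#' @return A single numeric coefficient.
#' @examples
#' sample_reflection(0.5, -2, u = 0.5)   # -0.75
#' sample_visibility(1, -1, u = 1)       #  1
#' @export
sample_reflection <- function(r1 = 0.5, r2 = -2, u = stats::runif(1)) {
  u * (r1 - r2) + r2
}

#' @rdname sample_reflection
#' @export
sample_visibility <- function(v1 = 1, v2 = -1, u = stats::runif(1)) {
  u * (v1 - v2) + v2
}

# ---- group update cases ----------------------------------------------------
# All case updates are pure: they take positions, return a new clipped
# position, and never mutate their inputs.

#' CFA group update moves
#'
#' The four group moves of the cuttlefish algorithm, each producing a new
#' continuous position which is clamped into `bounds`:
#'
#' * `case12_update()` (group 1, chromatophore stretch/shrink): the new
#'   position is `R * x + (best - x)`; the visibility coefficient is fixed
#'   at 1 for this group and only R is drawn.
#' * `case34_update()` (group 2, iridophore mirror): reflection locks onto
#'   the best with coefficient 1, visibility is drawn:
#'   `best + V * (best - x)`.
#' * `case5_update()` (group 3, interval around the best): visibility uses
#'   the scalar mean of the best position (`av_top`):
#'   `best + V * (best - av_top)`.
#' * `case6_position()` (group 4, leucophore matching): a fresh uniform
#'   random position inside the bounds, identical in law to an initial
#'   population member.
#'
#' @param position Current member position (numeric vector).
#' @param best Global best position (same length).
#' @param R,V Reflection / visibility coefficients (see
#'   [sample_reflection()]).
#' @param av_top Scalar mean of the best position's components
#'   (see [compute_av_top()]).
#' @param bounds An [fs_bounds()] object.
#' @return A new position vector inside `bounds`.
#' @examples
#' b <- fs_bounds(3)
#' case12_update(c(0.4, 0.4, 0.4), c(0.8, 0.8, 0.8), R = 0.5, bounds = b)
#' case34_update(c(0.2, 0.2, 0.2), c(0.6, 0.6, 0.6), V = -1, bounds = b)
#' @export
case12_update <- function(position, best, R, bounds) {
  if (length(position) != length(best)) {
    stop("`position` and `best` must share the same dimension.")
  }
  clip_to_bounds(R * position + (best - position), bounds)
}

#' @rdname case12_update
#' @export
case34_update <- function(position, best, V, bounds) {
  if (length(position) != length(best)) {
    stop("`position` and `best` must share the same dimension.")
  }
  clip_to_bounds(best + V * (best - position), bounds)
}

#' @rdname case12_update
#' @export
case5_update <- function(best, av_top, V, bounds) {
  stopifnot(is.finite(av_top))
  clip_to_bounds(best + V * (best - av_top), bounds)
}

#' @rdname case12_update
#' @export
case6_position <- function(bounds) {
  stats::runif(bounds$d) * (bounds$upper - bounds$lower) + bounds$lower
}

#' Scalar average of the best position
#'
#' The arithmetic mean over the components of the stored best solution,
#' recomputed every outer iteration and used by the group-3 move
#' ([case5_update()]) as the centre of its visibility interval.
#'
#' @param position Best position vector (length >= 1).
#' @return A single numeric value.
#' @examples
#' compute_av_top(c(0.2, 0.4, 0.6))  # 0.4
#' @export
compute_av_top <- function(position) {
  stopifnot(length(position) >= 1)
  mean(position)
}

# Initial population: n_pop positions i.i.d. uniform inside bounds, assigned
# round-robin (by index) into four near-equal groups; remainders fall to the
# earliest groups. Returns list(positions = list of vectors, group = integer).
init_population <- function(bounds, params) {
  stopifnot(inherits(bounds, "fs_bounds"), inherits(params, "cfa_params"))
  n <- params$n_pop
  positions <- lapply(seq_len(n), function(i) case6_position(bounds))
  group <- rep_len(1:4, n)
  list(positions = positions, group = group)
}
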