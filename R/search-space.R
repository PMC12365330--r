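#' Search-space bounds for continuous subset encodings
#'
#' Candidate feature subsets are encoded as length-`d` real vectors inside a
#' box `[lower, upper]^d` and decoded to binary masks by thresholding (see
#' [decode_mask()]). The unit cube is the default so that the conventional
#' decode threshold of 0.5 sits at its midpoint.
#'
#' @param d Number of candidate features (dimension of the search space).
#' @param lower,upper Per-dimension box limits; `lower < upper`.
#'
#' @return An object of class `fs_bounds`: a list with elements `lower`,
#'   `upper` and `d`.
#' @examples
#' fs_bounds(5)
#' @export
fs_bounds <- function(d, lower = 0, upper = 1) {
  stopifnot(is.numeric(d), length(d) == 1, d >= 1, d == as.integer(d))
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1,
            length(upper) == 1, is.finite(lower), is.finite(upper))
  if (lower >= upper) {
    stop("`lower` must be strictly below `upper` (got [", lower, ", ", upper, "]).")
  }
  structure(list(lower = lower, upper = upper, d = as.integer(d)),
            class = "fs_bounds")
}

#' @export
print.fs_bounds <- function(x, ...) {
  cat("<fs_bounds> [", x$lower, ", ", x$upper, "]^", x$d, "\n", sep = "")
  invisible(x)
}

#' Decode a continuous position vector to a feature mask
#'
#' A component strictly above `threshold` selects the corresponding feature.
#' If no component exceeds the threshold the mask is repaired: the single
#' largest component is forced on (ties break to the lowest index), because a
#' wrapper objective is undefined for an empty feature subset.
#'
#' @param position Numeric vector of positions, one per candidate feature.
#' @param threshold Decode threshold, strictly inside the box limits.
#'
#' @return Logical vector of the same length with at least one `TRUE`.
#' @examples
#' decode_mask(c(0.7, 0.2, 0.9))        # TRUE FALSE TRUE
#' decode_mask(c(0.1, 0.4, 0.2))        # repair: only the argmax survives
#' @export
decode_mask <- function(position, threshold = 0.5) {
  if (length(position) == 0) stop("`position` must have at least one component.")
  stopifnot(is.numeric(position), is.numeric(threshold), length(threshold) == 1)
  mask <- position > threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Clamp a position vector into its bounds
#'
#' Componentwise `min(upper, max(lower, x))`; the boundary policy shared by
#' every optimizer move in the package. Clamping (rather than reflecting or
#' wrapping) is idempotent and keeps the geometry of moves simple.
#'
#' @param position Numeric vector.
#' @param bounds An [fs_bounds()] object (its `d` must match).
#'
#' @return The clamped numeric vector, component order preserved.
#' @examples
#' clip_to_bounds(c(-0.3, 0.5, 1.2), fs_bounds(3))
#' @export
clip_to_bounds <- function(position, bounds) {
  stopifnot(inherits(bounds, "fs_bounds"))
  if (length(position) != bounds$d) {
    stop("`position` has ", length(position), " components but bounds expect ",
         bounds$d, ".")
  }
  pmin(bounds$upper, pmax(bounds$lower, position))
}
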