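#' Regular 2D grid of neuron positions
#'
#' Node coordinates run from 0 to the extent in steps of `spacing` along
#' each axis (x grows away from the body along the sound axis, y across it).
#'
#' @param extent length-2 numeric, cm.
#' @param spacing node spacing, cm.
#' @return list with `x`, `y` axis coordinates, `nx`, `ny`, and matrices
#'   `X`, `Y` of node coordinates (nx x ny).
#' @keywords internal
spatial_grid <- function(extent, spacing) {
  if (any(extent <= 0) || spacing <= 0)
    stop("configuration error: non-positive grid geometry")
  if (spacing > min(extent))
    stop("configuration error: spacing exceeds extent")
  x <- seq(0, extent[1], by = spacing)
  y <- seq(0, extent[2], by = spacing)
  list(x = x, y = y, nx = length(x), ny = length(y),
       X = matrix(x, length(x), length(y)),
       Y = matrix(y, length(x), length(y), byrow = TRUE),
       extent = extent, spacing = spacing)
}

#' Mexican-hat lateral weight at a given distance
#'
#' Difference-of-Gaussians profile `L_ex exp(-d^2/(2 sigma_ex^2)) -
#' L_in exp(-d^2/(2 sigma_in^2))`: net excitation close by, inhibition at
#' intermediate range, vanishing at large distance. The self-connection
#' (d = 0, same neuron) is excluded in the network; this function returns
#' the raw kernel value.
#'
#' @param d distance, cm (>= 0); vectorized.
#' @param k list with `L_ex`, `sigma_ex`, `L_in`, `sigma_in`.
#' @return kernel weight(s).
#' @export
lateral_kernel <- function(d, k) {
  stopifnot(all(d >= 0))
  k$L_ex * exp(-d^2 / (2 * k$sigma_ex^2)) -
    k$L_in * exp(-d^2 / (2 * k$sigma_in^2))
}

#' Distance of a point in the auditory frame from the hand
#'
#' Euclidean distance to the nearest point of the rectangular hand region;
#' for points level with the hand this reduces to `max(0, x - 20)` with the
#' default hand placement.
#'
#' @param x,y coordinates, cm (vectorized).
#' @param hand list with `x`, `y` intervals of the hand region.
#' @param grid_extent optional length-2 extent of the auditory grid; when
#'   given, points outside it raise a domain error.
#' @return distance(s) in cm.
#' @examples
#' hand <- list(x = c(0, 20), y = c(0, 10))
#' distance_from_hand(50, 5, hand)   # 30
#' distance_from_hand(100, 5, hand)  # 80
#' @export
distance_from_hand <- function(x, y, hand, grid_extent = NULL) {
  if (!is.null(grid_extent)) {
    if (any(x < 0 | x > grid_extent[1] | y < 0 | y > grid_extent[2]))
      stop("domain error: point outside the auditory grid")
  }
  dx <- pmax(hand$x[1] - x, 0, x - hand$x[2])
  dy <- pmax(hand$y[1] - y, 0, y - hand$y[2])
  sqrt(dx^2 + dy^2)
}

# dense axis Gaussian (n x n) used for separable lateral convolution
axis_gaussian <- function(coords, sigma) {
  d <- outer(coords, coords, "-")
  exp(-d^2 / (2 * sigma^2))
}
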