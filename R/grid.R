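#' Discrete value grid for interaction parameters
#'
#' Builds the ordered, symmetric set of discrete values \eqn{\Omega} over
#' which edge-parameter marginals are computed. The grid must be symmetric
#' about zero and contain zero exactly once, so that the sparsity prior
#' (an L0 penalty on nonzero values) has a well-defined support point.
#'
#' The default, 11 values on \eqn{[-1, 1]} in steps of 0.2, is the operating
#' grid used for real perturbation data; a coarse 3-value grid
#' \eqn{\{-1, 0, 1\}} encodes inhibition/none/activation, and a 41-value grid
#' on \eqn{[-2, 2]} is used for benchmarks whose generating weights reach 2.
#'
#' @param low lower endpoint (negative).
#' @param high upper endpoint; must equal \code{-low}.
#' @param step positive spacing; \code{(high - low) / step} must be an even
#'   integer so that zero lies on the grid.
#' @return A numeric vector of class \code{"value_grid"} with attribute
#'   \code{step}.
#' @examples
#' length(value_grid(-1, 1, 0.2))  # 11
#' length(value_grid(-2, 2, 0.1))  # 41
#' @export
value_grid <- function(low = -1, high = 1, step = 0.2) {
  stopifnot(is.numeric(low), is.numeric(high), is.numeric(step), step > 0)
  if (!(low < 0 && high > 0))
    stop("value grid must straddle zero: need low < 0 < high")
  if (abs(low + high) > 1e-12)
    stop("value grid must be symmetric about zero (low = -high)")
  n <- (high - low) / step
  if (abs(n - round(n)) > 1e-8)
    stop("(high - low) / step must be an integer")
  n <- round(n)
  if (n %% 2L != 0L)
    stop("grid does not contain zero; (high - low) / step must be even")
  values <- low + step * (0:n)
  values[abs(values) < 1e-12] <- 0  # snap the centre to an exact zero
  structure(values, step = step, class = "value_grid")
}

#' @export
print.value_grid <- function(x, ...) {
  cat(sprintf("Value grid: %d values on [%g, %g], step %g\n",
              length(x), min(x), max(x), attr(x, "step")))
  invisible(x)
}

as_grid <- function(grid) {
  if (inherits(grid, "value_grid")) return(grid)
  g <- as.numeric(grid)
  if (sum(g == 0) != 1L || is.unsorted(g, strictly = TRUE))
    stop("grid must be strictly increasing and contain exactly one zero")
  structure(g, step = if (length(g) > 1) g[2] - g[1] else NA_real_,
            class = "value_grid")
}

#' Order of magnitude of the discrete model search space
#'
#' Number of decimal digits (base-10 order of magnitude) of \eqn{K^{N^2}},
#' the count of distinct discrete interaction matrices for \code{n_nodes}
#' nodes with \code{k} allowed values per parameter. At \eqn{N = 20},
#' \eqn{K = 3} this is of order \eqn{10^{190}}, which is why explicit
#' enumeration is hopeless and message passing is used instead.
#'
#' @param n_nodes number of network nodes.
#' @param k number of discrete parameter values.
#' @return integer order of magnitude.
#' @export
search_space_order <- function(n_nodes, k) {
  stopifnot(n_nodes >= 1, k >= 1)
  floor(n_nodes^2 * log10(k))
}
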