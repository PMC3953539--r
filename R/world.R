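#' Wrap coordinates onto the torus
#'
#' Maps arbitrary coordinates into `[0, side)` with periodic boundaries.
#' Wrapping is idempotent.
#'
#' @param x Numeric vector of coordinates.
#' @param side Side length of the (square) arena.
#' @return Numeric vector of wrapped coordinates in `[0, side)`.
#' @export
wrap_coord <- function(x, side = 500) {
  stopifnot(is.numeric(x), is.numeric(side), side > 0)
  w <- x %% side
  w[w >= side] <- 0 # floating-point guard at the seam
  w
}

#' Toroidal Euclidean distance
#'
#' Distance between points on a square torus of side `side`: the shortest
#' separation on each axis under wraparound, combined Euclidean-wise. The
#' maximum attainable distance is `side * sqrt(2) / 2`.
#'
#' @param a,b Points as length-2 vectors `c(x, y)` or two-column matrices
#'   (rows are points; recycled against each other row-wise).
#' @param side Side length of the arena.
#' @return Numeric vector of distances.
#' @examples
#' torus_distance(c(0, 0), c(499, 0), side = 500) # 1, across the seam
#' @export
torus_distance <- function(a, b, side = 500) {
  a <- as_points(a)
  b <- as_points(b)
  dx <- abs(wrap_coord(a[, 1], side) - wrap_coord(b[, 1], side))
  dy <- abs(wrap_coord(a[, 2], side) - wrap_coord(b[, 2], side))
  dx <- pmin(dx, side - dx)
  dy <- pmin(dy, side - dy)
  sqrt(dx^2 + dy^2)
}

#' Fixed-radius neighbourhood query
#'
#' Indices of the points within `radius` of `center` under toroidal distance.
#' The boundary is inclusive (`distance <= radius`), so a radius of zero
#' still matches coincident points.
#'
#' @param points Two-column matrix of point coordinates.
#' @param center Length-2 numeric vector.
#' @param radius Non-negative search radius.
#' @param side Side length of the arena.
#' @return Integer vector of row indices of `points` (possibly empty), in
#'   input order.
#' @export
neighbors_within <- function(points, center, radius, side = 500) {
  stopifnot(radius >= 0)
  points <- as_points(points)
  if (nrow(points) == 0L) return(integer(0))
  which(torus_distance(points, matrix(center, nrow = 1), side) <= radius)
}

#' Uniform random points in the arena
#'
#' @param n Number of points.
#' @param side Side length of the arena.
#' @return An `n` x 2 matrix of coordinates uniform on `[0, side)^2`.
#' @export
random_point <- function(n = 1, side = 500) {
  matrix(stats::runif(2 * n, 0, side), ncol = 2)
}

# coerce a point or matrix of points to a 2-column matrix
as_points <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2)
    p
  } else {
    stopifnot(is.numeric(p), length(p) == 2)
    matrix(p, ncol = 2)
  }
}

# grid-backed query used inside the engine; exposed for equality tests
# against the linear scan in neighbors_within()
grid_query <- function(points, center, radius, side = 500) {
  cpp_grid_query(as_points(points), center[1], center[2], radius, side)
}
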