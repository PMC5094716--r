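# Small shared helpers: angle arithmetic on the circle, vector norms.

#' Wrap angles into [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap360 <- function(x) {
  x %% 360
}

#' Circular distance between angles
#'
#' Shortest arc between two angles on the 360-degree circle.
#'
#' @param a,b angles in degrees.
#' @return non-negative distance in degrees, at most 180.
#' @export
circular_distance <- function(a, b) {
  d <- abs(wrap360(a) - wrap360(b))
  pmin(d, 360 - d)
}

#' Circular mean of angles
#'
#' @param x angles in degrees.
#' @return mean direction in `[0, 360)`.
#' @export
circular_mean <- function(x) {
  r <- x * pi / 180
  wrap360(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotate coordinates about the z axis
#'
#' @param coords n x 3 matrix.
#' @param deg rotation angle in degrees, counterclockwise viewed from +z.
#' @return rotated n x 3 matrix.
#' @export
rotate_z <- function(coords, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0,
                sin(th), cos(th), 0,
                0, 0, 1), 3, 3)
  coords %*% R
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reassemble a molecule split by periodic wrapping: every bead is moved to
# its minimum image relative to the first bead. Valid for molecules smaller
# than half the box in every direction.
unwrap_molecule <- function(coords, box) {
  ref <- coords[1, , drop = TRUE]
  d <- sweep(coords, 2, ref)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sweep(d, 2, -ref)
}
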