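#' Angle and coordinate conventions
#'
#' All `fibertrace` functions share one convention set:
#'
#' * Images are numeric matrices indexed `[row, col]`, 1-based, with rows
#'   increasing downward (standard raster order).
#' * A *direction* is an angle in degrees in (-180, 180], measured from the
#'   +col axis, positive counter-clockwise on screen; its unit vector is
#'   `(d_row, d_col) = (-sin(phi), cos(phi))`.
#' * An *orientation* is 180-degree periodic and reported in (-90, 90].
#' * Physical lengths use the pixel size in nm/px (default 108).
#'
#' @name angles
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180

#' Direction of the vector from point `a` to point `b`
#'
#' @param a,b numeric `(row, col)` pairs.
#' @return direction in degrees in (-180, 180].
#' @keywords internal
direction_to <- function(a, b) {
  ang <- atan2(-(b[1] - a[1]), b[2] - a[2]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Fold an angular difference into \[0, 180\] degrees
#' @param x angle difference in degrees (any range).
#' @keywords internal
fold180 <- function(x) {
  d <- abs(x) %% 360
  pmin(d, 360 - d)
}

#' Fold an orientation difference into \[0, 90\] degrees
#' @param x orientation difference in degrees.
#' @keywords internal
fold90 <- function(x) {
  d <- abs(x) %% 180
  pmin(d, 180 - d)
}

#' Reverse a direction (rotate by 180 degrees), staying in (-180, 180]
#' @param phi direction in degrees.
#' @keywords internal
reverse_direction <- function(phi) {
  r <- phi + 180
  r - 360 * (r > 180)
}

#' Wrap an orientation into (-90, 90]
#' @param theta orientation in degrees.
#' @keywords internal
wrap_orientation <- function(theta) {
  t <- ((theta + 90) %% 180)
  t[t == 0] <- 180
  t - 90
}

#' Separable Gaussian blur with zero padding
#'
#' Convolves a matrix with an isotropic 2D Gaussian kernel (truncated at
#' 4 sigma, normalized to unit sum), treating everything outside the image
#' as zero. Used to emulate the microscope point-spread function when
#' rendering phantoms.
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), is.numeric(sigma), sigma > 0)
  rad <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    b <- matrix(0, n, n)
    for (off in seq(-rad, rad)) {
      idx <- seq_len(n)
      keep <- idx + off >= 1 & idx + off <= n
      b[cbind(idx[keep], (idx + off)[keep])] <- k[off + rad + 1]
    }
    b
  }
  band(nrow(x)) %*% x %*% band(ncol(x))
}
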