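#' Pixel-grid coordinate supports
#'
#' Maps an \code{H x W} pixel grid onto the continuous domains on which moment
#' kernels are defined.  Two conventions are provided: the symmetric unit
#' square \eqn{[-1,1]^2} used by continuous Cartesian moments (Legendre), and
#' the raw integer lattice \eqn{\{0..W-1\} \times \{0..H-1\}} used by discrete
#' moments (Tchebichef).  Coordinates refer to pixel centers; the double
#' integral defining a moment is approximated by the midpoint rule, so each
#' pixel carries the constant cell area \code{delta}.
#'
#' @param H,W image height and width in pixels.
#' @param domain_tag \code{"symmetric_unit_square"} or \code{"discrete_lattice"}.
#' @return A list of class \code{cartesian_support} with elements \code{x}
#'   (length-\code{W} column coordinates), \code{y} (length-\code{H} row
#'   coordinates), \code{domain_tag} and \code{delta} (cell area; \code{4/(H*W)}
#'   on the unit square, \code{1} on the lattice).
#' @examples
#' s <- cartesian_support(3, 3, "symmetric_unit_square")
#' s$x  # (-2/3, 0, 2/3); the middle pixel sits at the origin
#' @export
cartesian_support <- function(H, W, domain_tag = c("symmetric_unit_square",
                                                   "discrete_lattice")) {
  domain_tag <- match.arg(domain_tag)
  if (!is.numeric(H) || !is.numeric(W) || length(H) != 1L || length(W) != 1L ||
      H < 1 || W < 1 || H != round(H) || W != round(W))
    stop("H and W must be positive integers", call. = FALSE)
  if (domain_tag == "symmetric_unit_square") {
    x <- (2 * seq_len(W) - W - 1) / W   # (2j - W + 1)/W, j 0-based
    y <- (2 * seq_len(H) - H - 1) / H
    delta <- 4 / (H * W)
  } else {
    x <- seq_len(W) - 1
    y <- seq_len(H) - 1
    delta <- 1
  }
  structure(list(x = x, y = y, domain_tag = domain_tag, delta = delta),
            class = "cartesian_support")
}

#' Unit-disk coordinates of a pixel grid
#'
#' Inscribed-disk convention: pixel centers are mapped to the symmetric unit
#' square and the unit disk is the largest disk contained in it; pixels with
#' \eqn{r > 1} are excluded from all circular-moment sums.  Rows are stored
#' top-to-bottom, so the storage y-axis is flipped before computing the angle:
#' \code{theta} follows the mathematical counter-clockwise convention, which
#' the rotation-invariance contracts rely on.
#'
#' @param H,W image height and width (both at least 3).
#' @return A list of class \code{disk_coordinates}: matrices \code{r} and
#'   \code{theta} (\code{H x W}), logical matrix \code{inside} (\code{r <= 1}),
#'   and scalar \code{delta = 4/(H*W)}.
#' @examples
#' d <- map_to_unit_disk(65, 65)
#' d$r[33, 33]            # center pixel, r = 0
#' mean(d$inside)         # close to pi/4
#' @export
map_to_unit_disk <- function(H, W) {
  if (H < 3 || W < 3) stop("H and W must be >= 3", call. = FALSE)
  s <- cartesian_support(H, W, "symmetric_unit_square")
  x <- matrix(s$x, nrow = H, ncol = W, byrow = TRUE)
  y <- matrix(s$y, nrow = H, ncol = W)      # storage y, increasing downward
  r <- sqrt(x^2 + y^2)
  theta <- atan2(-y, x)                     # flip to counter-clockwise
  structure(list(r = r, theta = theta, inside = r <= 1, delta = s$delta),
            class = "disk_coordinates")
}

#' Fractional-order radial substitution
#'
#' Implements the change of variable \eqn{r \leftarrow r^\alpha} that extends
#' a circular moment family to fractional order.  The Jacobian of the
#' substitution is folded into the kernel as the weight
#' \eqn{\alpha r^{2\alpha - 2}} (each of the two kernels in an inner product
#' absorbs its square root), so the substituted radial set stays orthogonal on
#' the disk with weight \eqn{r}.  \code{alpha = 1} is the exact identity.
#'
#' @param r radius values in \code{[0, 1]} (vectorized).
#' @param alpha positive fractional-order parameter.
#' @return list with \code{r_sub = r^alpha} and
#'   \code{weight = alpha * r^(2*alpha - 2)}.
#' @export
fractional_substitution <- function(r, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a positive number", call. = FALSE)
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]", call. = FALSE)
  if (alpha == 1) return(list(r_sub = r, weight = rep(1, length(r))))
  list(r_sub = r^alpha, weight = alpha * r^(2 * alpha - 2))
}

# Validate a grayscale image matrix: finite values in [0,1], at least 3x3.
assert_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop("image must be at least 3 x 3", call. = FALSE)
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop("image values must be finite and within [0, 1]", call. = FALSE)
  invisible(image)
}
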