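# Column-basis matrices for a Cartesian family: list(bx = W x (bound+1),
# by = H x (bound+1), delta).  Columns are the 1-D kernel functions h_p.
cartesian_basis <- function(spec, H, W) {
  bound <- if (spec$family == "LM") spec$n_max + 1L else spec$n_max
  switch(spec$family,
    LM = {
      s <- cartesian_support(H, W, "symmetric_unit_square")
      bx <- sapply(0:bound, function(p) legendre_polynomial(p, s$x))
      by <- sapply(0:bound, function(p) legendre_polynomial(p, s$y))
      list(bx = bx, by = by, delta = s$delta, bound = bound)
    },
    CHM = list(bx = tchebichef_matrix(bound, W),
               by = tchebichef_matrix(bound, H), delta = 1, bound = bound),
    CH2M = {
      # weighted-orthogonality construction: the analysis kernel carries the
      # second-kind weight, the synthesis basis is the bare polynomial set,
      # so discrete orthogonality and polynomial-exact reconstruction both
      # hold.  With Q the l2-orthonormal chebyshev2_matrix and w the weight,
      # analysis = sqrt(w) Q and synthesis = Q / sqrt(w) are biorthogonal.
      Qx <- chebyshev2_matrix(bound, W); Qy <- chebyshev2_matrix(bound, H)
      wx <- sqrt(chebyshev2_weight(W)); wy <- sqrt(chebyshev2_weight(H))
      list(bx = Qx * wx, by = Qy * wy,
           sx = Qx / wx, sy = Qy / wy, delta = 1, bound = bound)
    },
    stop("not a Cartesian family: ", spec$family, call. = FALSE))
}

#' Cartesian orthogonal moments
#'
#' Computes \eqn{M_{pq} = \Delta \sum_{x,y} h_p(x) h_q(y) f(x,y)} for the
#' separable Cartesian families: continuous Legendre moments (LM, with the
#' \eqn{(2p+1)(2q+1)/4} normalization) and the discrete Chebyshev moments of
#' the first (CHM) and second (CH2M) kind.  The index set is triangular,
#' \eqn{p + q \le} order bound: bound 5 gives the reference 21 features for
#' CHM/CH2M, and LM uses bound \code{n_max + 1} to emit its reference 28.
#'
#' @param image numeric matrix with values in \code{[0, 1]}, at least 3 x 3.
#' @param spec a [moment_spec] with a Cartesian \code{family}.
#' @return a \code{feature_vector} with labels \code{"(p=i,q=j)"} in
#'   lexicographic \code{(p, q)} order.
#' @seealso [reconstruct_cartesian] for the inverse transform.
#' @export
compute_cartesian_moments <- function(image, spec) {
  assert_gray_image(image)
  if (!spec$family %in% .CARTESIAN_FAMILIES)
    stop("spec$family must be one of LM, CHM, CH2M", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  b <- cartesian_basis(spec, H, W)
  # full[q+1, p+1] = sum_ij h_q(y_i) h_p(x_j) f[i, j]
  full <- b$delta * crossprod(b$by, image %*% b$bx)
  if (spec$family == "LM") {
    norm <- outer(2 * (0:b$bound) + 1, 2 * (0:b$bound) + 1) / 4  # [q, p]
    full <- full * norm
  }
  idx <- index_set(spec)
  vals <- full[cbind(idx$m + 1L, idx$n + 1L)]   # n = p, m = q
  feature_vector(spec$family,
                 sprintf("(p=%d,q=%d)", idx$n, idx$m), vals)
}

#' Inverse Cartesian moment transform
#'
#' Reconstructs an image from a Cartesian moment vector by summing
#' \eqn{\hat f(x,y) = \sum_{pq} M_{pq} h_p(x) h_q(y)}.  For the discrete
#' families the round trip is exact on images that are polynomials of total
#' degree within the index set; LM is exact up to midpoint-quadrature error.
#'
#' @param fv a \code{feature_vector} from [compute_cartesian_moments].
#' @param spec the [moment_spec] used to compute it.
#' @param H,W output image size.
#' @return numeric \code{H x W} matrix (not clipped to \code{[0, 1]}).
#' @export
reconstruct_cartesian <- function(fv, spec, H, W) {
  stopifnot(inherits(fv, "feature_vector"))
  b <- cartesian_basis(spec, H, W)
  idx <- index_set(spec)
  stopifnot(nrow(idx) == length(fv$values))
  coef <- matrix(0, b$bound + 1L, b$bound + 1L)   # [q+1, p+1]
  coef[cbind(idx$m + 1L, idx$n + 1L)] <- fv$values
  sy <- b$sy %||% b$by; sx <- b$sx %||% b$bx
  sy %*% coef %*% t(sx)
}
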