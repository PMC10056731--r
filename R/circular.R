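# Full disk basis of a circular family, evaluated at the masked pixels of an
# H x W grid.  Returns a complex matrix with one column per (n, m) index,
# column k holding  R_{n_k}(r) exp(i m_k theta) / sqrt(2 pi).
circular_basis_matrix <- function(spec, H, W, disk = NULL) {
  if (is.null(disk)) disk <- map_to_unit_disk(H, W)
  idx <- index_set(spec)
  r <- disk$r[disk$inside]
  theta <- disk$theta[disk$inside]
  fam0 <- base_family(spec$family)
  zernike_like <- fam0 %in% c("ZM", "PZM")
  # radial values are shared across indices with the same radial key
  rkey <- if (zernike_like) paste(idx$n, abs(idx$m)) else as.character(idx$n)
  radials <- new.env(parent = emptyenv())
  angulars <- new.env(parent = emptyenv())
  B <- matrix(0 + 0i, length(r), nrow(idx))
  for (k in seq_len(nrow(idx))) {
    rk <- rkey[k]
    if (is.null(radials[[rk]]))
      radials[[rk]] <- radial_kernel(spec$family, idx$n[k], r, spec, idx$m[k])
    mk <- as.character(idx$m[k])
    if (is.null(angulars[[mk]]))
      angulars[[mk]] <- exp(1i * idx$m[k] * theta)
    B[, k] <- radials[[rk]] * angulars[[mk]] / sqrt(2 * pi)
  }
  B
}

#' Circular orthogonal moments
#'
#' Projects an image onto the disk basis of the requested family:
#' \deqn{M(n,m) = \Delta \sum_{r \le 1} R_n(r)\, e^{-i m \theta}\,
#'   f(\mathrm{pixel}) / \sqrt{2\pi},}
#' summing over the pixels inside the inscribed unit disk.  With the
#' orthonormal kernels used throughout the package, reconstruction is the
#' plain conjugate sum ([reconstruct]) and \eqn{M(0,0)} of the constant image
#' \eqn{f \equiv 1} reproduces the constant.
#'
#' @param image numeric matrix with values in \code{[0, 1]}, at least 3 x 3.
#' @param spec a [moment_spec] with a circular \code{family}.
#' @return an object of class \code{complex_moment_set}: complex vector
#'   \code{entries} indexed by the rows of \code{index} (columns \code{n},
#'   \code{m}), plus \code{spec} and the grid size.
#' @export
compute_circular_moments <- function(image, spec) {
  assert_gray_image(image)
  if (!is_circular_family(spec$family))
    stop(spec$family, " is not a circular family", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  disk <- map_to_unit_disk(H, W)
  B <- circular_basis_matrix(spec, H, W, disk)
  m <- disk$delta * as.vector(crossprod(Conj(B), image[disk$inside]))
  idx <- index_set(spec)
  structure(list(family = spec$family, entries = m, index = idx,
                 spec = spec, H = H, W = W),
            class = "complex_moment_set")
}

#' @export
print.complex_moment_set <- function(x, ...) {
  cat(sprintf("complex_moment_set: %s, %d entries on %dx%d grid\n",
              x$family, length(x$entries), x$H, x$W))
  invisible(x)
}

#' Rotation-invariant moment magnitudes
#'
#' Rotating an image multiplies \eqn{M(n,m)} by the unit-modulus phase
#' \eqn{e^{-i m \phi}}, so the moduli are rotation invariants.  Both signs of
#' \code{m} are kept in the fixed (n ascending, then m ascending) enumeration,
#' matching the reference feature counts (ZM 21, PZM 36, OFMM 66, EFM 121,
#' PST 55, ...).
#'
#' @param moments a \code{complex_moment_set} from [compute_circular_moments].
#' @return a \code{feature_vector} of \eqn{|M(n,m)|} values with labels
#'   \code{"(n=..,m=..)"}.
#' @export
magnitudes <- function(moments) {
  stopifnot(inherits(moments, "complex_moment_set"))
  feature_vector(moments$family,
                 sprintf("(n=%d,m=%d)", moments$index$n, moments$index$m),
                 Mod(moments$entries))
}

#' Reconstruct an image from circular moments
#'
#' Evaluates \eqn{\hat f = \sum_{n,m} M(n,m) R_n(r) e^{i m \theta} /
#' \sqrt{2\pi}} inside the inscribed disk; pixels outside the disk are 0.
#' For a conjugate-symmetric moment set of a real image the imaginary
#' residual is rounding noise and is dropped.
#'
#' @param moments a \code{complex_moment_set}.
#' @param H,W output grid size (defaults to the grid the moments came from).
#' @return numeric \code{H x W} matrix (finite, not clipped to \code{[0, 1]}).
#' @export
reconstruct <- function(moments, H = moments$H, W = moments$W) {
  stopifnot(inherits(moments, "complex_moment_set"))
  disk <- map_to_unit_disk(H, W)
  B <- circular_basis_matrix(moments$spec, H, W, disk)
  vals <- as.vector(B %*% moments$entries)
  out <- matrix(0, H, W)
  out[disk$inside] <- Re(vals)
  out
}
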