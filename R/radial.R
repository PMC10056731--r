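# Radial kernels of the circular moment families.
#
# Every radial function returned here is normalized to be orthonormal on
# [0, 1] with weight r:  integral_0^1 R_n(r) R_k(r) r dr = delta_nk  (for
# Zernike-type families this holds within a fixed repetition |m|).  The full
# 2-D basis is then R_n(r) exp(i m theta) / sqrt(2 pi), orthonormal on the
# unit disk, so moments and reconstruction share one normalization path.

# Zernike radial polynomial R_{n,|m|}(r), classic factorial sum.
zernike_radial <- function(n, m, r) {
  m <- abs(m)
  if (n < m || (n - m) %% 2 != 0)
    stop("Zernike requires n >= |m| with n - |m| even", call. = FALSE)
  out <- numeric(length(r))
  for (s in 0:((n - m) / 2)) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * r^(n - 2 * s)
  }
  sqrt(2 * n + 2) * out
}

# Pseudo-Zernike radial polynomial S_{n,|m|}(r).
pseudo_zernike_radial <- function(n, m, r) {
  m <- abs(m)
  if (n < m) stop("pseudo-Zernike requires n >= |m|", call. = FALSE)
  out <- numeric(length(r))
  for (s in 0:(n - m)) {
    coef <- (-1)^s * factorial(2 * n + 1 - s) /
      (factorial(s) * factorial(n - m - s) * factorial(n + m + 1 - s))
    out <- out + coef * r^(n - s)
  }
  sqrt(2 * n + 2) * out
}

# Generic Jacobi-family radial function with parameters (p, q):
#   J_n(r) = c_n (1-r)^{(p-q)/2} r^{(q-2)/2} P_n^{(p-q, q-1)}(2r - 1),
# orthonormal on [0,1] with weight r.  Specializations: OFMM (p=q=2),
# CHFM (p=2, q=3/2), PJFM (p=4, q=3), JFM (free p > q > 0).
jacobi_radial <- function(n, p, q, r) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  a <- p - q; b <- q - 1
  c_n <- sqrt(exp(lgamma(2 * n + a + b + 2) - lgamma(2 * n + a + b + 1)) *
              exp(lgamma(n + a + b + 1) + lgamma(n + 1) -
                  lgamma(n + a + 1) - lgamma(n + b + 1)))
  out <- c_n * (1 - r)^(a / 2) * r^((q - 2) / 2) *
    jacobi_polynomial(n, a, b, 2 * r - 1)
  out[r == 0 & !is.finite(out)] <- 0   # q < 2 kernels are singular at r = 0
  out
}

# Cache of positive Bessel-function roots, keyed by nu.
.bessel_root_cache <- new.env(parent = emptyenv())

#' Positive roots of a Bessel function of the first kind
#'
#' Finds the first \code{k} positive roots of \eqn{J_\nu} by bracketed
#' root-finding (tolerance 1e-12); results are cached per \code{nu}.
#'
#' @param k number of roots.
#' @param nu Bessel order.
#' @return numeric vector of the first \code{k} positive roots, increasing.
#' @export
bessel_roots <- function(k, nu = 1) {
  key <- sprintf("%.10g", nu)
  cached <- .bessel_root_cache[[key]]
  if (!is.null(cached) && length(cached) >= k) return(cached[seq_len(k)])
  roots <- numeric(k)
  # McMahon approximation locates the j-th root near (j + nu/2 - 1/4) * pi
  for (j in seq_len(k)) {
    guess <- (j + nu / 2 - 1 / 4) * pi
    lo <- guess - pi / 2; hi <- guess + pi / 2
    f <- function(x) besselJ(x, nu)
    while (f(lo) * f(hi) > 0) { lo <- lo - 0.1; hi <- hi + 0.1 }
    roots[j] <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  .bessel_root_cache[[key]] <- roots
  roots
}

# Bessel-Fourier radial: J_nu(lambda_{n+1} r), normalized with the square
# norm J_{nu+1}(lambda)^2 / 2.
bessel_radial <- function(n, nu, r) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  lam <- bessel_roots(n + 1, nu)[n + 1]
  besselJ(lam * r, nu) * sqrt(2) / abs(besselJ(lam, nu + 1))
}

# Radial harmonic Fourier set: 1/sqrt(r), then sqrt(2/r) sin((n+1) pi r) for
# odd n and sqrt(2/r) cos(n pi r) for even n.
rhfm_radial <- function(n, r) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  out <- if (n == 0) 1 / sqrt(r)
  else if (n %% 2 == 1) sqrt(2 / r) * sin((n + 1) * pi * r)
  else sqrt(2 / r) * cos(n * pi * r)
  out[r == 0] <- 0   # measure-zero singular point
  out
}

# Dispatch table for the integer-order radial functions.  `m` only matters
# for the Zernike-type families.
integer_radial <- function(family, n, r, spec, m = 0) {
  switch(family,
    ZM = zernike_radial(n, m, r),
    PZM = pseudo_zernike_radial(n, m, r),
    OFMM = jacobi_radial(n, 2, 2, r),
    CHFM = jacobi_radial(n, 2, 3 / 2, r),
    PJFM = jacobi_radial(n, 4, 3, r),
    JFM = jacobi_radial(n, spec$jacobi_p, spec$jacobi_q, r),
    BFM = bessel_radial(n, spec$bessel_nu, r),
    RHFM = rhfm_radial(n, r),
    EFM = {
      out <- exp(2i * pi * n * r) / sqrt(r)
      out[r == 0] <- 0
      out
    },
    PCET = sqrt(2) * exp(2i * pi * n * r^2),
    PCT = if (n == 0) rep(sqrt(2), length(r)) else 2 * cos(pi * n * r^2),
    PST = {
      if (n < 1) stop("PST requires n >= 1", call. = FALSE)
      2 * sin(pi * n * r^2)
    },
    stop("unknown circular family: ", family, call. = FALSE))
}

#' Radial kernel of a circular moment family
#'
#' Evaluates the radial factor of the family's disk basis function,
#' normalized to be orthonormal on \code{[0, 1]} with weight \code{r}.  For
#' the fractional-order families the substitution \eqn{r \to r^\alpha} is
#' applied together with the square root of its Jacobian weight
#' (see [fractional_substitution]), which preserves orthonormality.
#'
#' @param family a circular family tag (see [moment_spec]).
#' @param n radial order.  ZM requires \code{n >= |m|} with \code{n - |m|}
#'   even; PZM \code{n >= |m|}; PST \code{n >= 1}; EFM/PCET accept any
#'   integer; the remaining families require \code{n >= 0}.
#' @param r radius values in \code{[0, 1]} (vectorized).
#' @param spec a [moment_spec] supplying \code{alpha}, Jacobi and Bessel
#'   parameters.
#' @param m angular repetition (used only by ZM and PZM).
#' @return complex (EFM/PCET) or numeric vector of kernel values; singular
#'   kernels evaluate to 0 at \code{r = 0}.
#' @export
radial_kernel <- function(family, n, r, spec = moment_spec(family), m = 0) {
  if (!is_circular_family(family))
    stop(family, " is not a circular family", call. = FALSE)
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]", call. = FALSE)
  fam0 <- base_family(family)
  alpha <- spec$alpha
  if (!(family %in% .FRACTIONAL_FAMILIES) || alpha == 1)
    return(integer_radial(fam0, n, r, spec, m))
  sub <- fractional_substitution(r, alpha)
  out <- sqrt(sub$weight) * integer_radial(fam0, n, sub$r_sub, spec, m)
  out[r == 0 & !is.finite(out)] <- 0
  out
}
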