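#' Legendre polynomial
#'
#' Evaluates \eqn{P_n(x)} by the standard three-term recurrence
#' \eqn{n P_n = (2n-1) x P_{n-1} - (n-1) P_{n-2}}.  Vectorized over \code{x}.
#'
#' @param n non-negative integer degree.
#' @param x evaluation points in \code{[-1, 1]}.
#' @return numeric vector of \eqn{P_n(x)} values (bounded by 1 in magnitude).
#' @export
legendre_polynomial <- function(n, x) {
  if (length(n) != 1L || n < 0 || n != round(n))
    stop("n must be a non-negative integer", call. = FALSE)
  if (any(abs(x) > 1 + 1e-12)) stop("x must lie in [-1, 1]", call. = FALSE)
  p0 <- rep(1, length(x))
  if (n == 0) return(p0)
  p1 <- x
  if (n == 1) return(p1)
  for (k in 2:n) {
    p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    p0 <- p1; p1 <- p2
  }
  p1
}

# Orthonormal discrete Tchebichef polynomials t~_0..t~_nmax on the lattice
# 0..N-1, as an N x (nmax+1) matrix.  Squared-norm-normalized recurrence so
# the values stay O(1) up to N = 512.
tchebichef_matrix <- function(nmax, N) {
  if (nmax >= N) stop("polynomial degree must be < N", call. = FALSE)
  x <- 0:(N - 1)
  out <- matrix(0, N, nmax + 1L)
  out[, 1L] <- 1 / sqrt(N)
  if (nmax >= 1)
    out[, 2L] <- (2 * x + 1 - N) * sqrt(3 / (N * (N^2 - 1)))
  if (nmax >= 2) {
    for (n in 2:nmax) {
      c1 <- sqrt((4 * n^2 - 1) / (N^2 - n^2))
      a1 <- (2 / n) * c1
      a2 <- ((1 - N) / n) * c1
      a3 <- ((n - 1) / n) * sqrt((2 * n + 1) / (2 * n - 3)) *
        sqrt((N^2 - (n - 1)^2) / (N^2 - n^2))
      out[, n + 1L] <- (a1 * x + a2) * out[, n] - a3 * out[, n - 1L]
    }
  }
  out
}

#' Orthonormal discrete Tchebichef polynomial
#'
#' Value of the orthonormal discrete Chebyshev (Tchebichef) polynomial
#' \eqn{\tilde t_n(x; N)} on the integer lattice, satisfying
#' \eqn{\sum_{x=0}^{N-1} \tilde t_m(x)\tilde t_n(x) = \delta_{mn}}.
#'
#' @param n degree, \code{0 <= n < N}.
#' @param x lattice points in \code{0..N-1} (vectorized).
#' @param N lattice size.
#' @export
tchebichef_polynomial <- function(n, x, N) {
  if (length(n) != 1L || n < 0 || n != round(n) || n >= N)
    stop("need 0 <= n < N", call. = FALSE)
  if (any(x < 0 | x > N - 1 | x != round(x)))
    stop("x must be lattice points in 0..N-1", call. = FALSE)
  tchebichef_matrix(n, N)[x + 1L, n + 1L]
}

# Chebyshev polynomials of the second kind U_0..U_nmax at points t in [-1,1],
# as a length(t) x (nmax+1) matrix.
chebyshev_u_matrix <- function(nmax, t) {
  out <- matrix(0, length(t), nmax + 1L)
  out[, 1L] <- 1
  if (nmax >= 1) out[, 2L] <- 2 * t
  if (nmax >= 2)
    for (n in 2:nmax)
      out[, n + 1L] <- 2 * t * out[, n] - out[, n - 1L]
  out
}

# Lattice-orthonormalized second-kind Chebyshev functions: U_n sampled on the
# lattice mapped to [-1,1], multiplied by the half-power of the second-kind
# weight sqrt(1 - t^2), then QR-orthonormalized (a discrete Gram-Schmidt that
# preserves the degree structure).  Returns an N x (nmax+1) matrix.
chebyshev2_matrix <- function(nmax, N) {
  if (nmax >= N - 1) stop("polynomial degree must be < N - 1", call. = FALSE)
  # pixel-center nodes keep the weight strictly positive on the lattice
  t <- (2 * (0:(N - 1)) + 1 - N) / N
  base <- chebyshev_u_matrix(nmax, t) * (1 - t^2)^(1 / 4)
  qrd <- qr(base)
  q <- qr.Q(qrd)
  # fix signs so the diagonal of R is positive (leading coefficient > 0)
  sgn <- sign(diag(qr.R(qrd)))
  sweep(q, 2L, sgn, `*`)
}

# Second-kind weight sqrt(1 - t^2) at the pixel-center lattice nodes.
chebyshev2_weight <- function(N) {
  t <- (2 * (0:(N - 1)) + 1 - N) / N
  sqrt(1 - t^2)
}

#' Lattice-orthonormal second-kind Chebyshev function
#'
#' The basis behind the "Chebyshev moments of the second kind": \eqn{U_n}
#' sampled on the lattice mapped to \eqn{[-1,1]}, carrying the half-power of
#' the second-kind weight \eqn{\sqrt{1-t^2}}, orthonormalized over the lattice
#' so that \eqn{\sum_x u_m(x) u_n(x) = \delta_{mn}} holds exactly by
#' construction.
#'
#' @inheritParams tchebichef_polynomial
#' @export
chebyshev2_polynomial <- function(n, x, N) {
  if (length(n) != 1L || n < 0 || n != round(n) || n >= N)
    stop("need 0 <= n < N", call. = FALSE)
  if (any(x < 0 | x > N - 1 | x != round(x)))
    stop("x must be lattice points in 0..N-1", call. = FALSE)
  chebyshev2_matrix(n, N)[x + 1L, n + 1L]
}

# Jacobi polynomial P_n^(a,b)(x) by the classical three-term recurrence.
jacobi_polynomial <- function(n, a, b, x) {
  p0 <- rep(1, length(x))
  if (n == 0) return(p0)
  p1 <- (a + 1) + (a + b + 2) * (x - 1) / 2
  if (n == 1) return(p1)
  for (k in 2:n) {
    c1 <- 2 * k * (k + a + b) * (2 * k + a + b - 2)
    c2 <- (2 * k + a + b - 1) * (a^2 - b^2)
    c3 <- (2 * k + a + b - 1) * (2 * k + a + b) * (2 * k + a + b - 2)
    c4 <- 2 * (k + a - 1) * (k + b - 1) * (2 * k + a + b)
    p2 <- ((c2 + c3 * x) * p1 - c4 * p0) / c1
    p0 <- p1; p1 <- p2
  }
  p1
}
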