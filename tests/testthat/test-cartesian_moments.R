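test_that("legendre_polynomial satisfies closed forms and orthogonality", {
  x <- seq(-1, 1, 0.1)
  expect_equal(legendre_polynomial(0, x), rep(1, length(x)))
  expect_equal(legendre_polynomial(2, 0.5), -0.125)
  expect_true(all(abs(legendre_polynomial(7, x)) <= 1 + 1e-12))
  # quadrature oracle: int_-1^1 P_3 P_5 dx = 0
  q <- stats::integrate(function(t)
    legendre_polynomial(3, t) * legendre_polynomial(5, t), -1, 1)
  expect_lt(abs(q$value), 1e-10)
  expect_error(legendre_polynomial(-1, 0), "non-negative")
})

test_that("discrete polynomial bases are orthonormal on the lattice", {
  # Tchebichef, direct-summation oracle at N = 61
  Tm <- sapply(0:5, function(n) tchebichef_polynomial(n, 0:60, 61))
  expect_lt(max(abs(crossprod(Tm) - diag(6))), 1e-10)
  expect_equal(tchebichef_polynomial(0, c(0, 30, 60), 61),
               rep(1 / sqrt(61), 3))
  # t_1 is affine in x and orthogonal to the constant
  t1 <- tchebichef_polynomial(1, 0:60, 61)
  expect_lt(max(abs(diff(diff(t1)))), 1e-12)
  expect_lt(abs(sum(t1)), 1e-12)
  # second-kind variant: orthonormal by construction, degree structure kept
  U <- sapply(0:5, function(n) chebyshev2_polynomial(n, 0:60, 61))
  expect_lt(max(abs(crossprod(U) - diag(6))), 1e-10)
  for (n in 1:5) {
    # leading column is not in the span of the lower-degree ones
    prev <- U[, seq_len(n), drop = FALSE]
    resid <- U[, n + 1] - prev %*% crossprod(prev, U[, n + 1])
    expect_gt(sqrt(sum(resid^2)), 0.9)
  }
  expect_error(tchebichef_polynomial(61, 0, 61), "n < N")
})

test_that("feature counts match the reference size table", {
  expect_equal(feature_count(moment_spec("LM")), 28)
  expect_equal(feature_count(moment_spec("CHM")), 21)
  expect_equal(feature_count(moment_spec("CH2M")), 21)
})

test_that("compute_cartesian_moments handles constants and round trips", {
  img <- matrix(1, 32, 32)
  lm <- compute_cartesian_moments(img, moment_spec("LM"))
  vals <- stats::setNames(lm$values, lm$labels)
  expect_equal(vals[["(p=0,q=0)"]], 1, tolerance = 1e-12)
  # higher moments vanish up to midpoint-quadrature error, which is O(h^2):
  # doubling the grid must shrink the residual by about 4x
  err32 <- max(abs(vals[names(vals) != "(p=0,q=0)"]))
  expect_lt(err32, 0.05)
  lm64 <- compute_cartesian_moments(matrix(1, 64, 64), moment_spec("LM"))
  v64 <- stats::setNames(lm64$values, lm64$labels)
  err64 <- max(abs(v64[names(v64) != "(p=0,q=0)"]))
  expect_lt(err64, err32 / 3)

  # CHM reconstructs a degree-<=5 separable polynomial image exactly
  spec <- moment_spec("CHM")
  x <- seq(0, 1, length.out = 31)
  poly_img <- outer(0.2 + 0.5 * x^2, 0.3 + 0.4 * x^3 + 0.2 * x) / 2
  fv <- compute_cartesian_moments(poly_img, spec)
  rec <- reconstruct_cartesian(fv, spec, 31, 31)
  expect_lt(max(abs(rec - poly_img)), 1e-8)

  # but not an image with degree-6 content
  poly6 <- outer(x^3, x^3)
  fv6 <- compute_cartesian_moments(poly6, spec)
  expect_gt(max(abs(reconstruct_cartesian(fv6, spec, 31, 31) - poly6)), 1e-6)

  expect_error(compute_cartesian_moments(img, moment_spec("ZM")), "LM, CHM")
  expect_error(compute_cartesian_moments(matrix(0.5, 2, 2), spec), "3 x 3")
})

test_that("cartesian moments are linear in the image", {
  set.seed(3)
  f <- random_image(24, 3); g <- random_image(24, 4)
  for (fam in c("LM", "CHM", "CH2M")) {
    spec <- moment_spec(fam)
    mf <- compute_cartesian_moments(f, spec)$values
    mg <- compute_cartesian_moments(g, spec)$values
    mix <- compute_cartesian_moments(0.3 * f + 0.6 * g, spec)$values
    expect_equal(mix, 0.3 * mf + 0.6 * mg, tolerance = 1e-12)
  }
})
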