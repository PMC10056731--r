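test_that("compute_glcm counts co-occurrences correctly", {
  # hand count: [[0,0],[1,1]] at 2 levels, d=1, theta=0 -> two horizontal
  # pairs (0,0) and (1,1); symmetric accumulation keeps the diagonal
  img <- matrix(c(0, 1, 0, 1), 2, 2) * 0.999
  g <- compute_glcm(img, d = 1, theta = 0, L = 2)
  expect_equal(g$matrix, diag(c(0.5, 0.5)))

  img2 <- random_image(16, 2)
  for (th in c(0, 45, 90, 135)) {
    g2 <- compute_glcm(img2, theta = th, L = 8)
    expect_equal(sum(g2$matrix), 1)
    expect_equal(g2$matrix, t(g2$matrix))   # symmetric accumulation
  }

  gc <- compute_glcm(matrix(0.4, 8, 8), theta = 0, L = 8)
  expect_equal(sum(gc$matrix > 0), 1)
  expect_equal(gc$matrix[4, 4], 1)          # level floor(0.4*8) = 3 (1-based 4)

  expect_error(compute_glcm(img2, theta = 30), "theta")
  expect_error(compute_glcm(matrix(0.5, 2, 2), d = 5), "offset")
})

test_that("haralick_features matches hand-computed statistics", {
  f_diag <- haralick_features(diag(c(0.5, 0.5)))
  expect_equal(unname(f_diag["contrast"]), 0)

  uniform <- matrix(0.25, 2, 2)
  expect_equal(unname(haralick_features(uniform)["asm"]), 0.25)

  single <- matrix(0, 2, 2); single[1, 1] <- 1
  expect_equal(unname(haralick_features(single)["entropy"]), 0)

  expect_error(haralick_features(matrix(0.3, 2, 2)), "normalized")
})

test_that("rotation_invariant_haralick emits 52 angle-major values", {
  img <- random_image(24, 7)
  fv <- rotation_invariant_haralick(img)
  expect_length(fv$values, 52)
  expect_match(fv$labels[1], "theta000")
  expect_match(fv$labels[14], "theta045")

  flat <- rotation_invariant_haralick(matrix(0.7, 16, 16))
  expect_true(all(flat$values[grep("contrast", flat$labels)] == 0))

  # 90-degree rotation permutes the four angle blocks: 0<->90, 45<->135
  rot <- rotated_pair(img, 1)
  f1 <- matrix(fv$values, nrow = 13)
  f2 <- matrix(rotation_invariant_haralick(rot)$values, nrow = 13)
  expect_equal(f2[, c(3, 4, 1, 2)], f1, tolerance = 1e-12)
})

test_that("lbp_ri_histogram groups codes into the 36 necklace classes", {
  # brute-force necklace count over all 256 patterns
  tab <- orthim:::lbp_ri_table()
  expect_equal(length(unique(tab)), 36)
  # one-bit rotations collapse: 00000001 and 00000010 share a class
  expect_equal(tab[2 + 1], tab[1 + 1])

  flat <- lbp_ri_histogram(matrix(0.5, 12, 12))
  expect_equal(sum(flat$bins > 0), 1)
  expect_equal(flat$class_codes[which(flat$bins > 0)], 255)  # all-ones code

  img <- random_image(20, 9)
  h <- lbp_ri_histogram(img)
  expect_equal(sum(h$bins), 18 * 18)        # interior-pixel conservation
  expect_identical(h$bins, lbp_ri_histogram(rotated_pair(img, 1))$bins)
  expect_error(lbp_ri_histogram(matrix(0.5, 2, 2)), "3 x 3")
})
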