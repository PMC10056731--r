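#' Gray-level co-occurrence matrix
#'
#' Quantizes intensities uniformly to \code{L} levels and accumulates
#' symmetric co-occurrences for the offset at distance \code{d} and angle
#' \code{theta}; the matrix is normalized to sum 1.  Angles follow the
#' standard image convention: 0 degrees is the horizontal neighbour, 90
#' degrees the vertical one, 45/135 the diagonals (measured counter-clockwise
#' on the displayed image).
#'
#' @param image numeric matrix with values in \code{[0, 1]}.
#' @param d offset distance in pixels (>= 1).
#' @param theta one of 0, 45, 90, 135 (degrees).
#' @param L number of gray levels after quantization (>= 2; default 8).
#' @return list of class \code{glcm} with \code{matrix} (\code{L x L},
#'   summing to 1), \code{levels}, \code{d}, \code{theta}.
#' @export
compute_glcm <- function(image, d = 1, theta = 0, L = 8) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop("image values must be finite and within [0, 1]", call. = FALSE)
  if (d < 1 || d != round(d)) stop("d must be a positive integer", call. = FALSE)
  if (!theta %in% c(0, 45, 90, 135))
    stop("theta must be one of 0, 45, 90, 135", call. = FALSE)
  if (L < 2) stop("L must be >= 2", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  q <- pmin(floor(image * L), L - 1)   # uniform bins over [0, 1]
  off <- switch(as.character(theta),
                "0"   = c(0, d),      # (drow, dcol)
                "45"  = c(-d, d),
                "90"  = c(-d, 0),
                "135" = c(-d, -d))
  rows <- seq_len(H); cols <- seq_len(W)
  r1 <- rows[rows + off[1] >= 1 & rows + off[1] <= H]
  c1 <- cols[cols + off[2] >= 1 & cols + off[2] <= W]
  if (length(r1) == 0 || length(c1) == 0)
    stop("image smaller than the requested offset", call. = FALSE)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  tab <- table(factor(a, levels = 0:(L - 1)), factor(b, levels = 0:(L - 1)))
  m <- unclass(tab) + t(unclass(tab))     # symmetric accumulation
  m <- m / sum(m)
  dimnames(m) <- NULL
  structure(list(matrix = m, levels = L, d = d, theta = theta),
            class = "glcm")
}

#' Haralick texture statistics
#'
#' The thirteen classic co-occurrence statistics, in fixed order: angular
#' second moment (energy), contrast, correlation, variance (sum of squares),
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, and the two information
#' measures of correlation.  Entropies use the natural logarithm with the
#' convention \eqn{0 \log 0 = 0}.
#'
#' @param glcm a \code{glcm} object, or a normalized square matrix.
#' @return named numeric vector of length 13.
#' @export
haralick_features <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$matrix else glcm
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stop("glcm must be a square matrix", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("glcm must be normalized to sum 1", call. = FALSE)
  L <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((1:L) * px); mu_y <- sum((1:L) * py)
  sd_x <- sqrt(sum(((1:L) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:L) - mu_y)^2 * py))
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  pxy_sum <- tapply(as.vector(p), as.vector(i + j), sum)
  pxy_diff <- tapply(as.vector(p), as.vector(abs(i - j)), sum)
  ks <- as.numeric(names(pxy_sum)); kd <- as.numeric(names(pxy_diff))
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sd_x > 0 && sd_y > 0)
    sum((i - mu_x) * (j - mu_y) * p) / (sd_x * sd_y) else 0
  variance <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_avg <- sum(ks * pxy_sum)
  sum_ent <- -sum(xlogx(pxy_sum))
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  entropy <- -sum(xlogx(p))
  diff_avg <- sum(kd * pxy_diff)
  diff_var <- sum((kd - diff_avg)^2 * pxy_diff)
  diff_ent <- -sum(xlogx(pxy_diff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pij_marg <- outer(px, py)
  hxy1 <- -sum(p * ifelse(pij_marg > 0, log(pij_marg), 0))
  hxy2 <- -sum(xlogx(pij_marg))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = diff_var, difference_entropy = diff_ent,
    imc1 = imc1, imc2 = imc2)
}

#' Rotation-invariant Haralick descriptor
#'
#' Computes the 13 Haralick statistics on each of the four \code{d = 1}
#' co-occurrence matrices (angles 0, 45, 90, 135 degrees) and concatenates
#' them angle-major into a 52-value descriptor.  Rotating the image by
#' multiples of 90 degrees permutes the four angle blocks, so
#' order-insensitive learners see a rotation-robust signature.
#'
#' @param image numeric matrix with values in \code{[0, 1]}.
#' @param L gray levels for quantization (default 8).
#' @param d offset distance (default 1).
#' @return a \code{feature_vector} of length 52 named \code{HARri}.
#' @export
rotation_invariant_haralick <- function(image, L = 8, d = 1) {
  angles <- c(0, 45, 90, 135)
  vals <- unlist(lapply(angles, function(a)
    haralick_features(compute_glcm(image, d = d, theta = a, L = L))))
  labels <- as.vector(t(outer(angles, names(haralick_features(
    compute_glcm(image, d = d, theta = 0, L = L))),
    function(a, f) sprintf("theta%03d_%s", a, f))))
  feature_vector("HARri", labels, vals)
}

# Map each 8-bit code to the minimum over its 8 circular bit-rotations.
# There are exactly 36 equivalence classes (binary necklaces of length 8).
lbp_ri_table <- function() {
  codes <- 0:255
  vapply(codes, function(c) {
    min(vapply(0:7, function(s) {
      if (s == 0) return(c)
      bitwAnd(bitwOr(bitwShiftL(c, s), bitwShiftR(c, 8L - s)), 255L)
    }, integer(1)))
  }, integer(1))
}

.lbp_cache <- new.env(parent = emptyenv())

#' Rotation-invariant local binary pattern histogram
#'
#' For every interior pixel, the 8 neighbours on the radius-1 circle (the
#' diagonal sampling points are bilinearly interpolated) are thresholded
#' against the center with the convention neighbour >= center, forming an
#' 8-bit code; each code is replaced by the minimum over its 8 circular
#' bit-rotations.  The 36 rotation-equivalence classes index the histogram.
#'
#' @param image numeric matrix with values in \code{[0, 1]}, at least 3 x 3.
#' @return list of class \code{lbp_histogram}: integer \code{bins} (length
#'   36, named by class code, summing to the interior pixel count) and
#'   \code{neighborhood = c(r = 1, n = 8)}.
#' @export
lbp_ri_histogram <- function(image) {
  assert_gray_image(image)
  H <- nrow(image); W <- ncol(image)
  ri <- rows <- 2:(H - 1); ci <- 2:(W - 1)
  center <- image[ri, ci, drop = FALSE]
  s <- 1 / sqrt(2)
  # bilinear sample at (row + dr, col + dc) for the interior block
  sample_at <- function(dr, dc) {
    blk <- function(a, b) image[ri + a, ci + b, drop = FALSE]
    if (dr == round(dr) && dc == round(dc)) return(blk(dr, dc))
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    (1 - fr) * (1 - fc) * blk(r0, c0) + (1 - fr) * fc * blk(r0, c0 + 1) +
      fr * (1 - fc) * blk(r0 + 1, c0) + fr * fc * blk(r0 + 1, c0 + 1)
  }
  # neighbours counter-clockwise from angle 0: (dc, -dr) = (cos a, sin a)
  angles <- 2 * pi * (0:7) / 8
  code <- matrix(0L, length(ri), length(ci))
  for (k in 0:7) {
    dr <- -sin(angles[k + 1]); dc <- cos(angles[k + 1])
    dr <- round(dr, 12); dc <- round(dc, 12)
    nb <- sample_at(dr, dc)
    code <- code + as.integer(nb >= center - 1e-12) * 2L^k
  }
  tab <- .lbp_cache$table
  if (is.null(tab)) tab <- .lbp_cache$table <- lbp_ri_table()
  classes <- sort(unique(tab))
  mapped <- tab[code + 1L]
  bins <- table(factor(mapped, levels = classes))
  structure(list(bins = as.integer(bins), class_codes = classes,
                 neighborhood = c(r = 1, n = 8)),
            class = "lbp_histogram")
}

# Texture descriptors as feature vectors, used by the benchmark pipeline.
lbp_feature_vector <- function(image) {
  h <- lbp_ri_histogram(image)
  feature_vector("LBPri", sprintf("class%03d", h$class_codes),
                 h$bins / sum(h$bins))
}
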