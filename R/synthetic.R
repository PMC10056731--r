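#' Synthetic labeled texture dataset
#'
#' Generates small single-channel texture patches with class-specific texture
#' statistics, emulating the patch-classification regime of the medical
#' benchmarks (patch sizes from 61 x 61 up to 512 x 512, a few hundred
#' images, 2-4 classes).  Three texture families probe different descriptor
#' strengths:
#' \describe{
#'   \item{oriented_grating}{sinusoidal gratings; classes differ in
#'     orientation and spatial frequency (angular content, circular moments).}
#'   \item{gaussian_random_field}{FFT-smoothed white noise; classes differ in
#'     correlation length (autocorrelation, GLCM).}
#'   \item{blob_mixture}{sums of Gaussian blobs; classes differ in blob count
#'     and width (low-order shape, Cartesian moments).}
#' }
#' Each image draws its own random phase/offset so images within a class
#' differ; pixel values are clipped to \code{[0, 1]}; the output is
#' byte-identical under a fixed seed.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class images per class.
#' @param size image size \code{c(H, W)} (default 64 x 64).
#' @param family texture family (see above).
#' @param noise_sd additive Gaussian noise standard deviation (default 0.05).
#' @param class_params optional list of per-class parameter lists; defaults
#'   to a well-separated schedule.
#' @param seed integer seed.
#' @return list with \code{images} (list of matrices), \code{labels}
#'   (factor \code{class1..classK}) and \code{config}.
#' @export
generate_dataset <- function(n_classes = 3, n_per_class = 20,
                             size = c(64, 64),
                             family = c("oriented_grating",
                                        "gaussian_random_field",
                                        "blob_mixture"),
                             noise_sd = 0.05, class_params = NULL,
                             seed = 1) {
  family <- match.arg(family)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  H <- size[1]; W <- size[2]
  if (H < 8 || W < 8) stop("size must be at least 8 x 8", call. = FALSE)
  if (is.null(class_params))
    class_params <- default_class_params(family, n_classes)
  if (length(class_params) != n_classes)
    stop("class_params must have one entry per class", call. = FALSE)
  set.seed(seed %% .Machine$integer.max)
  images <- vector("list", n_classes * n_per_class)
  labels <- factor(rep(sprintf("class%d", seq_len(n_classes)),
                       each = n_per_class))
  i <- 0L
  for (cl in seq_len(n_classes)) {
    for (rep in seq_len(n_per_class)) {
      i <- i + 1L
      img <- switch(family,
        oriented_grating = grating_patch(H, W, class_params[[cl]]),
        gaussian_random_field = grf_patch(H, W, class_params[[cl]]),
        blob_mixture = blob_patch(H, W, class_params[[cl]]))
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
  }
  list(images = images, labels = labels,
       config = list(n_classes = n_classes, n_per_class = n_per_class,
                     size = c(H, W), family = family, noise_sd = noise_sd,
                     class_params = class_params, seed = seed))
}

default_class_params <- function(family, n_classes) {
  switch(family,
    oriented_grating = lapply(seq_len(n_classes), function(cl)
      list(orientation = (cl - 1) * pi / n_classes,
           frequency = 3 + 2 * (cl - 1))),
    gaussian_random_field = lapply(seq_len(n_classes), function(cl)
      list(corr_length = 1.5 * 2^(cl - 1))),
    blob_mixture = lapply(seq_len(n_classes), function(cl)
      list(n_blobs = 2 * cl, width = 0.25 / cl)))
}

grating_patch <- function(H, W, p) {
  phase <- stats::runif(1, 0, 2 * pi)
  offset <- stats::runif(1, -0.05, 0.05)
  x <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  y <- matrix(seq(-1, 1, length.out = H), H, W)
  u <- cos(p$orientation) * x + sin(p$orientation) * y
  0.5 + offset + 0.4 * sin(2 * pi * p$frequency * u + phase)
}

grf_patch <- function(H, W, p) {
  z <- matrix(stats::rnorm(H * W), H, W)
  fx <- c(0:(floor(W / 2)), -(ceiling(W / 2) - 1):-1) / W
  fy <- c(0:(floor(H / 2)), -(ceiling(H / 2) - 1):-1) / H
  f2 <- outer(fy^2, fx^2, `+`)
  filt <- exp(-2 * (pi * p$corr_length)^2 * f2)   # Gaussian spectrum
  sm <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (H * W)
  sm <- (sm - mean(sm)) / (stats::sd(sm) + 1e-12)
  0.5 + 0.15 * sm
}

blob_patch <- function(H, W, p) {
  x <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  y <- matrix(seq(-1, 1, length.out = H), H, W)
  img <- matrix(0, H, W)
  for (b in seq_len(p$n_blobs)) {
    cx <- stats::runif(1, -0.6, 0.6); cy <- stats::runif(1, -0.6, 0.6)
    img <- img + exp(-((x - cx)^2 + (y - cy)^2) / (2 * p$width^2))
  }
  img / max(img)
}

#' Render a basis function as an image fixture
#'
#' Renders the real part of the family's disk basis function \eqn{R_n(r)
#' e^{i m \theta}} (or the separable Cartesian product) on an \code{H x W}
#' grid, affinely rescaled to \code{[0, 1]}.  The rescale offset and gain are
#' attached as the \code{"rescale"} attribute (\code{c(offset, gain)}, so
#' that \code{raw = offset + gain * image}) so projection tests can undo it.
#'
#' @param family a moment family tag.
#' @param n,m order and repetition.
#' @param H,W output size.
#' @return numeric matrix in \code{[0, 1]} with attribute \code{rescale}.
#' @export
basis_image <- function(family, n, m, H = 64, W = 64) {
  if (is_circular_family(family)) {
    spec <- moment_spec(family)
    disk <- map_to_unit_disk(H, W)
    vals <- matrix(0, H, W)
    rk <- radial_kernel(family, n, disk$r[disk$inside], spec, m)
    vals[disk$inside] <- Re(rk * exp(1i * m * disk$theta[disk$inside]))
  } else {
    spec <- moment_spec(family)
    b <- cartesian_basis(spec, H, W)
    if (n > b$bound || m > b$bound) stop("index out of range", call. = FALSE)
    vals <- outer(b$by[, m + 1L], b$bx[, n + 1L])
  }
  lo <- min(vals); hi <- max(vals)
  gain <- if (hi > lo) hi - lo else 1
  out <- (vals - lo) / gain
  attr(out, "rescale") <- c(offset = lo, gain = gain)
  out
}

#' Exact 90-degree rotations
#'
#' Rotates a square image counter-clockwise by multiples of 90 degrees as an
#' exact pixel permutation (no interpolation), for rotation-invariance
#' testing.
#'
#' @param image square numeric matrix.
#' @param quarter_turns integer number of 90-degree counter-clockwise turns.
#' @return rotated matrix of the same size.
#' @export
rotated_pair <- function(image, quarter_turns = 1) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be square", call. = FALSE)
  q <- ((quarter_turns %% 4) + 4) %% 4
  out <- image
  for (i in seq_len(q)) out <- t(out)[nrow(out):1, , drop = FALSE]
  out
}

#' Bilinear image rotation
#'
#' Rotates an image about its center by an arbitrary angle using bilinear
#' interpolation (pixels mapping outside the source keep the source mean).
#' Used by the interpolated rotation-invariance checks; not an exact
#' permutation.
#'
#' @param image numeric matrix.
#' @param angle rotation angle in radians, counter-clockwise.
#' @return rotated matrix of the same size.
#' @export
rotate_bilinear <- function(image, angle) {
  H <- nrow(image); W <- ncol(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  fill <- mean(image)
  out <- matrix(fill, H, W)
  co <- cos(angle); si <- sin(angle)
  ii <- matrix(seq_len(H), H, W); jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse map; storage y grows downward so the sign of the sine flips
  dx <- jj - cx; dy <- ii - cy
  sx <- co * dx - si * dy + cx
  sy <- si * dx + co * dy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
  idx <- function(r, c) image[cbind(r[ok], c[ok])]
  vals <- (1 - fy[ok]) * (1 - fx[ok]) * idx(y0, x0) +
    (1 - fy[ok]) * fx[ok] * idx(y0, x0 + 1) +
    fy[ok] * (1 - fx[ok]) * idx(y0 + 1, x0) +
    fy[ok] * fx[ok] * idx(y0 + 1, x0 + 1)
  out[ok] <- vals
  out
}
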