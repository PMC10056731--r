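.CARTESIAN_FAMILIES <- c("LM", "CHM", "CH2M")
.CIRCULAR_FAMILIES <- c("ZM", "PZM", "OFMM", "CHFM", "PJFM", "JFM", "FrJFM",
                        "BFM", "RHFM", "EFM", "PCET", "PCT", "PST",
                        "FrRHFM", "FrPCET", "FrPCT", "FrPST")
.ALL_FAMILIES <- c(.CARTESIAN_FAMILIES, .CIRCULAR_FAMILIES)
.FRACTIONAL_FAMILIES <- c("FrJFM", "FrRHFM", "FrPCET", "FrPCT", "FrPST")

#' Moment family specification
#'
#' Bundles a moment family identifier with its order/repetition bounds and
#' family parameters.  The defaults mirror the benchmark configuration:
#' order 5 for all families, fractional parameter \code{alpha = 1.5} for the
#' fractional-order (\code{Fr*}) families and 1 otherwise, Jacobi parameters
#' \code{(p, q) = (3, 2)} for JFM/FrJFM, and Bessel order \code{nu = 1} for
#' BFM.
#'
#' @param family one of \code{"LM"}, \code{"CHM"}, \code{"CH2M"} (Cartesian) or
#'   \code{"ZM"}, \code{"PZM"}, \code{"OFMM"}, \code{"CHFM"}, \code{"PJFM"},
#'   \code{"JFM"}, \code{"FrJFM"}, \code{"BFM"}, \code{"RHFM"}, \code{"EFM"},
#'   \code{"PCET"}, \code{"PCT"}, \code{"PST"}, \code{"FrRHFM"},
#'   \code{"FrPCET"}, \code{"FrPCT"}, \code{"FrPST"} (circular).
#' @param n_max maximum radial order (Cartesian: maximum degree bound).
#' @param m_max maximum absolute angular repetition for circular families
#'   whose repetition is bounded independently of the order.
#' @param alpha fractional-order parameter (> 0); defaults to 1.5 for
#'   \code{Fr*} families and 1 for integer-order families.
#' @param jacobi_p,jacobi_q Jacobi parameters for JFM/FrJFM; must satisfy
#'   \code{p > q > 0}.
#' @param bessel_nu order of the Bessel function of the first kind for BFM.
#' @return an object of class \code{moment_spec}.
#' @examples
#' moment_spec("ZM")
#' moment_spec("FrRHFM", alpha = 1.5)
#' @export
moment_spec <- function(family, n_max = 5, m_max = 5, alpha = NULL,
                        jacobi_p = 3, jacobi_q = 2, bessel_nu = 1) {
  family <- match.arg(family, .ALL_FAMILIES)
  if (n_max < 0 || n_max != round(n_max))
    stop("n_max must be a non-negative integer", call. = FALSE)
  if (m_max < 0 || m_max != round(m_max))
    stop("m_max must be a non-negative integer", call. = FALSE)
  if (is.null(alpha))
    alpha <- if (family %in% .FRACTIONAL_FAMILIES) 1.5 else 1
  if (!is.numeric(alpha) || alpha <= 0)
    stop("alpha must be > 0", call. = FALSE)
  if (family %in% c("JFM", "FrJFM") && !(jacobi_p > jacobi_q && jacobi_q > 0))
    stop("JFM requires jacobi_p > jacobi_q > 0", call. = FALSE)
  structure(list(family = family, n_max = as.integer(n_max),
                 m_max = as.integer(m_max), alpha = alpha,
                 jacobi_p = jacobi_p, jacobi_q = jacobi_q,
                 bessel_nu = bessel_nu),
            class = "moment_spec")
}

#' @export
print.moment_spec <- function(x, ...) {
  cat(sprintf("moment_spec: %s (n_max=%d, m_max=%d, alpha=%g)\n",
              x$family, x$n_max, x$m_max, x$alpha))
  if (x$family %in% c("JFM", "FrJFM"))
    cat(sprintf("  jacobi (p, q) = (%g, %g)\n", x$jacobi_p, x$jacobi_q))
  if (x$family == "BFM") cat(sprintf("  bessel nu = %g\n", x$bessel_nu))
  invisible(x)
}

is_circular_family <- function(family) family %in% .CIRCULAR_FAMILIES

# Integer-order family backing a fractional one ("FrJFM" -> "JFM", ...).
base_family <- function(family) sub("^Fr", "", family)

#' Index set of a moment specification
#'
#' Enumerates the (order, repetition) pairs a family emits at the given
#' bounds.  Both signs of the repetition are kept (moment magnitudes then
#' duplicate for real images), which is what makes the emitted vector lengths
#' match the reference feature counts: at order 5, ZM yields 21 pairs under
#' the parity constraint, PZM 36, EFM/PCET 121, PST 55 and the remaining
#' circular families 66.  For Cartesian families the pairs are the \code{(p,q)}
#' degrees with \code{p + q <= n_max} (\code{n_max + 1} for LM), in
#' lexicographic order.
#'
#' @param spec a [moment_spec].
#' @return data.frame with integer columns \code{n} and \code{m} (for
#'   Cartesian families, \code{n} is p and \code{m} is q).
#' @export
index_set <- function(spec) {
  stopifnot(inherits(spec, "moment_spec"))
  n_max <- spec$n_max; m_max <- spec$m_max
  fam <- spec$family
  if (fam %in% .CARTESIAN_FAMILIES) {
    bound <- if (fam == "LM") n_max + 1L else n_max
    idx <- expand.grid(m = 0:bound, n = 0:bound)  # m varies fastest
    idx <- idx[idx$n + idx$m <= bound, c("n", "m")]
    idx <- idx[order(idx$n, idx$m), ]
    rownames(idx) <- NULL
    return(idx)
  }
  fam0 <- base_family(fam)
  idx <- switch(fam0,
    ZM = {
      pairs <- expand.grid(m = -n_max:n_max, n = 0:n_max)
      pairs[abs(pairs$m) <= pairs$n & (pairs$n - abs(pairs$m)) %% 2 == 0,
            c("n", "m")]
    },
    PZM = {
      pairs <- expand.grid(m = -n_max:n_max, n = 0:n_max)
      pairs[abs(pairs$m) <= pairs$n, c("n", "m")]
    },
    EFM = ,
    PCET = expand.grid(m = -n_max:n_max, n = -n_max:n_max)[, c("n", "m")],
    PST = expand.grid(m = -m_max:m_max, n = 1:n_max)[, c("n", "m")],
    expand.grid(m = -m_max:m_max, n = 0:n_max)[, c("n", "m")]
  )
  idx <- idx[order(idx$n, idx$m), ]
  rownames(idx) <- NULL
  idx
}

#' Feature count of a moment specification
#'
#' @param spec a [moment_spec].
#' @return number of features the descriptor emits (the "size" of the
#'   feature vector).
#' @export
feature_count <- function(spec) nrow(index_set(spec))

# Construct a named feature_vector object.
feature_vector <- function(descriptor_name, labels, values) {
  stopifnot(length(labels) == length(values))
  if (any(!is.finite(values)))
    stop("feature vector contains non-finite values", call. = FALSE)
  structure(list(descriptor_name = descriptor_name,
                 labels = as.character(labels),
                 values = as.numeric(values)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector: %s (%d features)\n", x$descriptor_name,
              length(x$values)))
  print(stats::setNames(x$values, x$labels), ...)
  invisible(x)
}

#' @export
as.numeric.feature_vector <- function(x, ...)
  stats::setNames(x$values, x$labels)

#' @export
length.feature_vector <- function(x) length(x$values)
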