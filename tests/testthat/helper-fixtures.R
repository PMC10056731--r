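# Shared in-code fixtures (no binary files; everything is generated here).

# Smooth band-limited test image: a few low-frequency gratings.
smooth_image <- function(H = 64) {
  x <- matrix(seq(-1, 1, length.out = H), H, H, byrow = TRUE)
  y <- matrix(seq(-1, 1, length.out = H), H, H)
  img <- 0.5 + 0.2 * sin(2 * pi * 1.5 * x) * cos(2 * pi * 1.2 * y) +
    0.15 * cos(2 * pi * 0.8 * (x + y))
  pmin(pmax(img, 0), 1)
}

# Smooth radial image with spectral content spread through radial order ~10,
# so reconstruction-error sweeps have genuine signal at every tested order.
smooth_radial_image <- function(H = 64) {
  r <- map_to_unit_disk(H, H)$r
  img <- 0.5 + 0.18 * cos(12 * r) + 0.17 * sin(9 * r^2)
  pmin(pmax(img, 0), 1)
}

# Random gray image under a fixed seed.
random_image <- function(H = 32, seed = 1) {
  set.seed(seed)
  matrix(runif(H * H), H, H)
}

circular_families <- function() {
  c("ZM", "PZM", "OFMM", "CHFM", "PJFM", "JFM", "FrJFM", "BFM", "RHFM",
    "EFM", "PCET", "PCT", "PST", "FrRHFM", "FrPCET", "FrPCT", "FrPST")
}

# Normalized Gram off-diagonal maximum of a family's discretized basis.
gram_offdiag <- function(family, H, n_max = 5, m_max = 5) {
  sp <- moment_spec(family, n_max = n_max, m_max = m_max)
  disk <- map_to_unit_disk(H, H)
  B <- orthim:::circular_basis_matrix(sp, H, H, disk)
  G <- disk$delta * crossprod(Conj(B), B)
  d <- sqrt(abs(Re(diag(G))))
  Gn <- G / outer(d, d)
  max(abs(Gn[row(Gn) != col(Gn)]))
}
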