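#' Quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-angle spiral) points; adequate both as a quadrature
#' grid for the Bingham convolution and as synthetic diffusion encoding
#' schemes.
#'
#' @param n number of points.
#' @param hemisphere if TRUE, fold all points into the z >= 0 hemisphere
#'   (diffusion encoding is antipodally symmetric).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  if (hemisphere) {
    flip <- pts[, 3] < 0
    pts[flip, ] <- -pts[flip, , drop = FALSE]
  }
  pts
}

# Real even-order spherical harmonic basis evaluated at unit directions.
# Rows: directions; columns: (l, m) pairs for even l = 0..order, m = -l..l.
# Real SH convention: sqrt(2) * Im/Re parts for m<0 / m>0.
sh_basis <- function(dirs, order) {
  dirs <- as.matrix(dirs)
  theta <- acos(pmin(1, pmax(-1, dirs[, 3])))      # polar angle
  phi <- atan2(dirs[, 2], dirs[, 1])               # azimuth
  ct <- cos(theta)
  cols <- list()
  for (l in seq(0, order, by = 2)) {
    # pracma::legendre gives P_l^m(x) for m = 0..l, rows m, unnormalised
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      # orthonormalisation factor for complex SH
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Pl <- P[am + 1, ]
      if (m < 0) {
        cols[[length(cols) + 1]] <- sqrt(2) * N * Pl * sin(am * phi)
      } else if (m == 0) {
        cols[[length(cols) + 1]] <- N * Pl
      } else {
        cols[[length(cols) + 1]] <- sqrt(2) * N * Pl * cos(am * phi)
      }
    }
  }
  do.call(cbind, cols)
}

n_sh_coefs <- function(order) (order + 1) * (order + 2) / 2

# Moore-Penrose pseudoinverse with a relative singular-value cutoff;
# ill-conditioned SH designs (few, clustered directions) stay stable.
pinv_tol <- function(B, rtol = 1e-6) {
  s <- svd(B)
  keep <- s$d > rtol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Largest even SH order whose coefficient count fits n directions, with
# 2x oversampling so the fit averages noise instead of reproducing it.
max_sh_order <- function(n_dirs, requested, oversample = 2) {
  order <- requested
  while (order > 0 && n_sh_coefs(order) * oversample > n_dirs)
    order <- order - 2
  order
}

#' Service-scale neonatal acquisition protocol description
#'
#' The fixed facts of the acquisition this toolkit emulates: 300 volumes
#' (20 b0s; 64/88/128 unique directions at b = 400/1000/2600 s/mm^2)
#' over 4 phase-encode directions; 64 overlapping slices of 3 mm
#' thickness at 1.5 mm spacing (1.5 mm in-plane); minimum 34 volumes at
#' the import gate (the smallest count guaranteeing a reversed-PE b0
#' pair).
#'
#' @return A named list of protocol constants.
#' @export
dhcp_protocol <- function() {
  list(n_volumes = 300L, n_b0 = 20L,
       shells = c(`400` = 64L, `1000` = 88L, `2600` = 128L),
       n_pe = 4L, n_slices = 64L, slice_thickness = 3,
       slice_spacing = 1.5, in_plane = 1.5,
       fov_mm = c(150, 150, 96), import_minimum = 34L)
}

#' dHCP-like multi-shell sampling scheme
#'
#' The neonatal protocol this toolkit emulates: 20 b0 volumes and shells at
#' b = 400, 1000 and 2600 s/mm^2 with 64, 88 and 128 unique directions,
#' interleaved over 4 phase-encode directions (AP, PA, LR, RL), 300 volumes
#' in total. Smaller schemes with the same structure are produced by
#' scaling the per-shell counts.
#'
#' @param n_b0 number of unweighted volumes.
#' @param shells named numeric vector mapping b-value to direction count.
#' @param n_pe number of phase-encode directions (cycled over volumes).
#' @param readout EPI readout time in seconds.
#' @return list(gtab = [gradient_table()], acq = [acq_params()]).
#' @export
dhcp_scheme <- function(n_b0 = 20,
                        shells = c(`400` = 64, `1000` = 88, `2600` = 128),
                        n_pe = 4, readout = 0.05) {
  bvals <- c(rep(0, n_b0),
             rep(as.numeric(names(shells)), times = shells))
  dirs <- lapply(shells, function(n) sphere_points(n, hemisphere = TRUE))
  bvecs <- rbind(matrix(0, n_b0, 3), do.call(rbind, dirs))
  n <- length(bvals)
  # cycling the PE assignment interleaves PE directions within every shell
  # and spreads the b0s evenly over PE rows
  pe <- rep(seq_len(n_pe), length.out = n)
  pe_vecs <- rbind(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0), c(-1, 0, 0))
  acq <- acq_params(pe_vecs[seq_len(n_pe), , drop = FALSE], readout)
  list(gtab = gradient_table(bvals, bvecs, pe_index = pe), acq = acq)
}
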