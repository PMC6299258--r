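# Rigid-body transforms and resampling on regular grids.
#
# Convention used throughout: a motion parameter vector p =
# (tx, ty, tz, rx, ry, rz) — translations in mm, rotations in radians
# applied in x-y-z order about the volume centre — describes how the image
# CONTENT moved. Resampling a volume "by p" moves the content by p;
# correcting motion therefore resamples by the inverse transform.

rot_x <- function(a) rbind(c(1, 0, 0),
                           c(0, cos(a), -sin(a)),
                           c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)),
                           c(0, 1, 0),
                           c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0),
                           c(sin(a), cos(a), 0),
                           c(0, 0, 1))

#' Rotation matrix of a rigid motion parameter vector
#' @param p length-6 numeric (tx, ty, tz, rx, ry, rz); mm and radians.
#' @return 3x3 rotation matrix (z then y then x applied last).
#' @export
rigid_rotation <- function(p) rot_x(p[4]) %*% rot_y(p[5]) %*% rot_z(p[6])

# 4x4 world-space (mm) rigid transform moving content by p, rotating about
# the point `centre` (mm).
rigid_matrix <- function(p, centre = c(0, 0, 0)) {
  R <- rigid_rotation(p)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- p[1:3] + centre - R %*% centre
  M
}

# Invert a rigid parameter vector exactly (via matrices).
rigid_invert <- function(p, centre = c(0, 0, 0)) {
  M <- solve(rigid_matrix(p, centre))
  R <- M[1:3, 1:3]
  # recover Euler angles of R = Rx %*% Ry %*% Rz
  ry <- asin(pmin(1, pmax(-1, R[1, 3])))
  rx <- atan2(-R[2, 3], R[3, 3])
  rz <- atan2(-R[1, 2], R[1, 1])
  tr <- as.numeric(M[1:3, 4] - centre + R %*% centre)
  c(tr, rx, ry, rz)
}

#' Trilinear interpolation of a 3-D volume at continuous voxel coordinates
#'
#' @param vol 3-D array.
#' @param coords n x 3 matrix of 1-based continuous voxel coordinates.
#' @param outside value used outside the grid.
#' @return numeric vector of length n.
#' @export
interp3 <- function(vol, coords, outside = 0) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # clamp corner indices; validity tracked separately
  valid <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  cx0 <- pmin(pmax(x0, 1), d[1]); cx1 <- pmin(pmax(x0 + 1, 1), d[1])
  cy0 <- pmin(pmax(y0, 1), d[2]); cy1 <- pmin(pmax(y0 + 1, 1), d[2])
  cz0 <- pmin(pmax(z0, 1), d[3]); cz1 <- pmin(pmax(z0 + 1, 1), d[3])
  idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v <- (1 - fx) * (1 - fy) * (1 - fz) * vol[idx(cx0, cy0, cz0)] +
       fx * (1 - fy) * (1 - fz) * vol[idx(cx1, cy0, cz0)] +
       (1 - fx) * fy * (1 - fz) * vol[idx(cx0, cy1, cz0)] +
       fx * fy * (1 - fz) * vol[idx(cx1, cy1, cz0)] +
       (1 - fx) * (1 - fy) * fz * vol[idx(cx0, cy0, cz1)] +
       fx * (1 - fy) * fz * vol[idx(cx1, cy0, cz1)] +
       (1 - fx) * fy * fz * vol[idx(cx0, cy1, cz1)] +
       fx * fy * fz * vol[idx(cx1, cy1, cz1)]
  v[!valid] <- outside
  v
}

# Cached 1-based voxel coordinate grid for a given dim.
voxel_grid <- local({
  cache <- list()
  function(d) {
    key <- paste(d, collapse = "x")
    if (is.null(cache[[key]])) {
      g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                 z = seq_len(d[3])))
      cache[[key]] <<- g
    }
    cache[[key]]
  }
})

#' Resample a volume under a rigid content motion
#'
#' Moves the image content by parameter vector `p` (see conventions in the
#' package source): the output at voxel x equals the input sampled at
#' `T(p)^-1 x` in world coordinates, with trilinear interpolation.
#'
#' @param vol 3-D array.
#' @param p length-6 rigid parameters (tx, ty, tz in mm; rx, ry, rz rad).
#' @param voxel length-3 voxel size in mm.
#' @param inverse if TRUE, apply the inverse transform (undo motion p).
#' @return resampled 3-D array.
#' @export
rigid_resample <- function(vol, p, voxel = c(1, 1, 1), inverse = FALSE) {
  d <- dim(vol)
  centre <- (d - 1) / 2 * voxel
  M <- rigid_matrix(p, centre)
  if (!inverse) M <- solve(M)   # content moved by p: sample input at T^-1 x
  g <- voxel_grid(d)
  world <- sweep(g - 1, 2, voxel, `*`)
  src <- world %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], nrow(world), 3, byrow = TRUE)
  src_vox <- sweep(src, 2, voxel, `/`) + 1
  out <- interp3(vol, src_vox)
  dim(out) <- d
  out
}

# Displace a volume along a PE axis by a per-voxel displacement (in mm),
# with linear interpolation and optional Jacobian intensity modulation.
# sign = +1 distorts (content shifted towards +pe axis where d > 0);
# sign = -1 undoes it.
pe_shift <- function(vol, d_mm, axis, voxel_mm, sign = 1,
                     jacobian = TRUE) {
  d <- dim(vol)
  if (!all(dim(d_mm) == d)) stop("field grid mismatch")
  shift_vox <- d_mm / voxel_mm * sign
  out <- array(0, d)
  n_ax <- d[axis]
  # sample input at x - shift (content moved by +shift)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  s <- aperm(shift_vox, perm)
  dd <- dim(v)
  pos <- array(rep(seq_len(n_ax), times = prod(dd[2:3])), dd) - s
  p0 <- floor(pos); f <- pos - p0
  c0 <- pmin(pmax(p0, 1), n_ax); c1 <- pmin(pmax(p0 + 1, 1), n_ax)
  valid <- pos >= 1 & pos <= n_ax
  lin <- function(k) {
    off <- array(rep(seq_len(prod(dd[2:3])) - 1, each = n_ax), dd)
    k + off * n_ax
  }
  res <- (1 - f) * v[lin(c0)] + f * v[lin(c1)]
  res[!valid] <- 0
  if (jacobian) {
    # d(pos)/d(x) = 1 - d(shift)/dx: modulate intensity to conserve flux
    grad <- s
    grad[] <- 0
    grad[2:(n_ax - 1), , ] <- (s[3:n_ax, , ] - s[1:(n_ax - 2), , ]) / 2
    res <- res * pmax(0, 1 - grad)
  }
  res <- array(res, dd)
  inv <- order(perm)
  aperm(res, inv)
}

# Gaussian smoothing (separable) of a 3-D array, sigma in voxels.
smooth3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (ax in 1:3) {
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    v <- aperm(vol, perm)
    d <- dim(v)
    m <- matrix(v, d[1], prod(d[2:3]))
    # pad by edge replication
    pad <- rbind(m[rep(1, r), , drop = FALSE], m,
                 m[rep(d[1], r), , drop = FALSE])
    sm <- apply_kernel(pad, k)
    v <- array(sm, d)
    vol <- aperm(v, order(perm))
  }
  vol
}

apply_kernel <- function(padded, k) {
  r <- (length(k) - 1) / 2
  n <- nrow(padded) - 2 * r
  out <- matrix(0, n, ncol(padded))
  for (i in seq_along(k))
    out <- out + k[i] * padded[i:(i + n - 1), , drop = FALSE]
  out
}

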