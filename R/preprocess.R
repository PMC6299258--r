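#' Select the best b0 pair per phase-encode direction
#'
#' b0 volumes of each PE direction are rigidly pre-aligned, then scored by
#' their mean Pearson correlation (within the mask) to all other b0s of the
#' same PE direction; the two best-correlating volumes per PE are selected
#' as the ones least affected by intra-volume motion. The volume with the
#' highest mean correlation to all other b0s becomes the global reference.
#'
#' @param ds a [dwi_dataset()].
#' @param mask 3-D logical array (correlation support); default whole grid.
#' @param align if TRUE (default), rigidly align b0s before scoring.
#' @return object of class `b0_selection`: list with `pairs` (named list,
#'   per PE row, of 2 volume indices), `reference` (volume index), and
#'   `scores` (per-b0 mean correlation). Ties break to the lowest index.
#' @export
select_b0_pairs <- function(ds, mask = NULL, align = TRUE) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (is.null(mask)) mask <- array(TRUE, dim(ds$data)[1:3])
  b0s <- which(ds$gtab$b0)
  if (length(b0s) < 2) stop("at least two b0 volumes are required")
  vols <- ds$data[, , , b0s, drop = FALSE]
  if (align && length(b0s) > 1) {
    vox <- voxel_size(ds$affine)
    for (i in seq_along(b0s)[-1]) {
      p <- estimate_rigid(vols[, , , i], vols[, , , 1], vox, mask)
      vols[, , , i] <- rigid_resample(vols[, , , i], p, vox, inverse = TRUE)
    }
  }
  m <- matrix(vols, ncol = length(b0s))[as.logical(mask), , drop = FALSE]
  cc <- suppressWarnings(stats::cor(m))
  cc[!is.finite(cc)] <- 0
  pe <- ds$gtab$pe_index[b0s]
  pairs <- list()
  for (row in sort(unique(pe))) {
    ii <- which(pe == row)
    if (length(ii) < 2) {
      warning("PE row ", row, " has fewer than two b0s; skipped")
      next
    }
    sub <- cc[ii, ii, drop = FALSE]
    score <- (rowSums(sub) - 1) / (length(ii) - 1)
    best <- ii[order(-score, ii)][1:2]
    pairs[[as.character(row)]] <- b0s[best]
  }
  if (!length(pairs))
    stop("no PE direction has two b0 volumes; field estimation impossible")
  gscore <- (rowSums(cc) - 1) / (length(b0s) - 1)
  chosen <- match(unlist(pairs), b0s)
  ref_local <- chosen[order(-gscore[chosen], chosen)][1]
  structure(list(pairs = pairs, reference = b0s[ref_local],
                 scores = stats::setNames(gscore, b0s)),
            class = "b0_selection")
}

#' @export
print.b0_selection <- function(x, ...) {
  cat("b0 selection: reference volume", x$reference, "\n")
  for (row in names(x$pairs))
    cat("  PE row ", row, ": volumes ",
        paste(x$pairs[[row]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Trilinear hat basis along one axis: n positions, control points every
# `spacing` voxels (endpoints included). Rows sum to 1.
hat_basis <- function(n, spacing) {
  ncp <- max(3, ceiling((n - 1) / spacing) + 1)
  cp <- seq(1, n, length.out = ncp)
  dx <- cp[2] - cp[1]
  B <- outer(seq_len(n), cp, function(x, c) pmax(0, 1 - abs(x - c) / dx))
  B / rowSums(B)
}

# Smoothness penalty on control coefficients along each axis of a
# (cx, cy, cz) control grid: second differences plus a small
# first-difference term, so the only unpenalised field is a constant
# (the infinite-regularisation limit).
coef_penalty <- function(cdims) {
  D2 <- function(k) {
    if (k < 3) return(matrix(0, 1, k))
    D <- matrix(0, k - 2, k)
    for (i in seq_len(k - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
    D
  }
  D1 <- function(k) {
    D <- matrix(0, k - 1, k)
    for (i in seq_len(k - 1)) D[i, i:(i + 1)] <- c(-1, 1)
    D
  }
  I1 <- diag(cdims[1]); I2 <- diag(cdims[2]); I3 <- diag(cdims[3])
  crossprod(I3 %x% I2 %x% D2(cdims[1])) +
    crossprod(I3 %x% D2(cdims[2]) %x% I1) +
    crossprod(D2(cdims[3]) %x% I2 %x% I1) +
    0.02 * (crossprod(I3 %x% I2 %x% D1(cdims[1])) +
              crossprod(I3 %x% D1(cdims[2]) %x% I1) +
              crossprod(D1(cdims[3]) %x% I2 %x% I1))
}

#' Estimate the susceptibility displacement field from a reversed-PE pair
#'
#' Two b0 images acquired with opposite phase-encode polarity carry equal
#' and opposite geometric distortion along the PE axis. The displacement
#' field d (mm) is parameterised on a coarse trilinear control grid and
#' estimated by Gauss-Newton minimisation of the squared difference
#' between the up-image unwarped by +d and the down-image unwarped by -d
#' (both with Jacobian intensity modulation), over a ladder of image
#' smoothing levels (multiscale), with a second-difference penalty of
#' weight `lambda_reg` on the control coefficients.
#'
#' @param b0_up,b0_down 3-D arrays with opposite PE polarity.
#' @param acq an [acq_params()] table.
#' @param rows length-2 integer: the acqparams rows of `b0_up`, `b0_down`
#'   (must be opposite vectors).
#' @param mask 3-D logical array; the returned field is zero outside it.
#' @param lambda_reg smoothness penalty weight (default 0.03; larger
#'   values pull the field towards a constant).
#' @param voxel voxel size (mm) along the PE axis.
#' @param control_spacing control-point spacing in voxels (default 4).
#' @param smooth_levels image smoothing sigmas (voxels), coarse to fine.
#' @param n_iter Gauss-Newton iterations per smoothing level.
#' @return object of class `pe_field`: the displacement array in mm
#'   (positive = shift towards the +PE axis of the "up" row), with the PE
#'   axis stored as attribute `axis`.
#' @export
estimate_pe_field <- function(b0_up, b0_down, acq, rows, mask = NULL,
                              lambda_reg = 0.03, voxel = 1.5,
                              control_spacing = 4,
                              smooth_levels = c(2, 1, 0.5), n_iter = 15) {
  p1 <- pe_axis(acq, rows[1]); p2 <- pe_axis(acq, rows[2])
  if (p1$axis != p2$axis || p1$sign != -p2$sign)
    stop("the two rows do not have opposite phase-encode vectors")
  ax <- p1$axis
  d <- dim(b0_up)
  if (is.null(mask)) mask <- array(TRUE, d)
  sc <- mean(c(b0_up[mask], b0_down[mask]))
  up0 <- b0_up / sc; down0 <- b0_down / sc
  Bx <- hat_basis(d[1], control_spacing)
  By <- hat_basis(d[2], control_spacing)
  Bz <- hat_basis(d[3], control_spacing)
  B <- Bz %x% By %x% Bx                    # nvox x ncoef
  cdims <- c(ncol(Bx), ncol(By), ncol(Bz))
  Pen <- coef_penalty(cdims) + 1e-8 * diag(prod(cdims))
  theta <- numeric(prod(cdims))
  mvec <- as.numeric(mask)
  for (sg in smooth_levels) {
    u <- smooth3(up0, sg); v <- smooth3(down0, sg)
    field_of <- function(th) array(B %*% th, d)
    obj <- function(th) {
      f <- field_of(th)
      U <- pe_shift(u, f, ax, voxel, sign = -1, jacobian = TRUE)
      V <- pe_shift(v, f, ax, voxel, sign = +1, jacobian = TRUE)
      sum(((U - V) * mvec)^2) + lambda_reg * sum(th * (Pen %*% th))
    }
    ss_cur <- obj(theta)
    for (it in seq_len(n_iter)) {
      f <- field_of(theta)
      U <- pe_shift(u, f, ax, voxel, sign = -1, jacobian = TRUE)
      V <- pe_shift(v, f, ax, voxel, sign = +1, jacobian = TRUE)
      r <- as.numeric((U - V) * mvec)
      J <- as.numeric(axis_gradient(U, ax) + axis_gradient(V, ax)) /
        voxel * mvec
      G <- B * J
      A <- crossprod(G) + lambda_reg * Pen
      rhs <- -crossprod(G, r) - lambda_reg * (Pen %*% theta)
      step <- tryCatch(as.numeric(solve(A, rhs)), error = function(e) NULL)
      if (is.null(step)) break
      ok <- FALSE
      fac <- 1
      for (bt in 1:6) {
        th_new <- theta + fac * step
        ss_new <- obj(th_new)
        if (is.finite(ss_new) && ss_new < ss_cur) {
          theta <- th_new; ss_cur <- ss_new; ok <- TRUE; break
        }
        fac <- fac / 2
      }
      if (!ok) break
    }
  }
  field <- field_of(theta)
  field[!mask] <- 0
  structure(field, axis = ax, voxel = voxel, class = "pe_field")
}

axis_gradient <- function(vol, ax) {
  d <- dim(vol)
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  n <- dim(v)[1]
  g <- v * 0
  g[2:(n - 1), , ] <- (v[3:n, , ] - v[1:(n - 2), , ]) / 2
  aperm(g, order(perm))
}

#' Unwarp a volume through an estimated PE displacement field
#'
#' Exactly inverts the 1-D distortion model along each phase-encode line:
#' the forward distortion maps true position xi to observed position x
#' with xi = x - d(x) and modulates intensity by the Jacobian; the unwarp
#' inverts that monotone map by interpolation and divides the Jacobian
#' back out. Linear interpolation throughout.
#'
#' @param volume 3-D array.
#' @param field a [estimate_pe_field()] result on the same grid.
#' @param acq an [acq_params()] table.
#' @param row the acqparams row of this volume (its sign flips the
#'   displacement).
#' @param voxel voxel size in mm along the PE axis.
#' @return unwarped 3-D array.
#' @export
apply_pe_unwarp <- function(volume, field, acq, row,
                            voxel = attr(field, "voxel")) {
  ax <- attr(field, "axis")
  p <- pe_axis(acq, row)
  if (p$axis != ax)
    stop("volume PE axis does not match the field's axis")
  if (!all(dim(volume) == dim(field))) stop("field grid mismatch")
  s <- unclass(field) * p$sign / voxel      # displacement in voxels
  d <- dim(volume)
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(volume, perm)
  sv <- aperm(s, perm)
  dd <- dim(v)
  n <- dd[1]
  vm <- matrix(v, n, prod(dd[2:3]))
  sm <- matrix(sv, n, prod(dd[2:3]))
  out <- vm
  xi <- seq_len(n)
  for (j in seq_len(ncol(vm))) {
    sj <- sm[, j]
    if (all(sj == 0)) next
    h <- xi - sj
    # enforce monotonicity (fold-over would make the model non-invertible)
    h <- cummax(h)
    xstar <- stats::approx(h, xi, xout = xi, rule = 2)$y
    hp <- c(diff(h), h[n] - h[n - 1])
    hps <- stats::approx(xi, pmax(hp, 0.05), xout = xstar, rule = 2)$y
    Dx <- stats::approx(xi, vm[, j], xout = xstar, rule = 2)$y
    out[, j] <- Dx / hps
  }
  aperm(array(out, dd), order(perm))
}

# Multiscale rigid registration of one volume to a reference.
# Returns the content-motion parameter vector p such that resampling
# `vol` by the inverse of p best matches `ref`. The correlation cost is
# evaluated at a subsample of mask voxels, not by resampling the grid.
estimate_rigid <- function(vol, ref, voxel, mask = NULL, p0 = rep(0, 6),
                           max_points = 4000, coarse = TRUE) {
  d <- dim(vol)
  if (is.null(mask)) mask <- array(TRUE, d)
  centre <- (d - 1) / 2 * voxel
  pts <- which(as.logical(mask))
  if (length(pts) < 30) pts <- seq_len(prod(d))
  if (length(pts) > max_points)
    pts <- pts[round(seq(1, length(pts), length.out = max_points))]
  g <- voxel_grid(d)[pts, , drop = FALSE]
  world <- sweep(g - 1, 2, voxel, `*`)
  # The cost interpolates the TARGET at inversely transformed positions
  # and compares with the raw moving volume. Never resampling the moving
  # volume avoids the interpolation-blur local minima that otherwise
  # appear at whole-voxel shifts.
  make_cost <- function(image, smooth_sigma) {
    movv <- if (smooth_sigma > 0) smooth3(image, smooth_sigma)[pts] else
      image[pts]
    tgt <- if (smooth_sigma > 0) smooth3(ref, smooth_sigma) else ref
    function(p) {
      Mi <- solve(rigid_matrix(p, centre))
      src <- world %*% t(Mi[1:3, 1:3]) +
        matrix(Mi[1:3, 4], nrow(world), 3, byrow = TRUE)
      v <- interp3(tgt, sweep(src, 2, voxel, `/`) + 1)
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) return(1)
      # tie-break penalty against implausibly large rotations (the
      # near-symmetric phantom otherwise admits a 180-degree alias)
      pen <- 0.1 * sum(pmax(0, abs(p[4:6]) - 0.5)^2)
      1 - stats::cor(v, movv) + pen
    }
  }
  sc_par <- c(2, 2, 2, 0.1, 0.1, 0.1)
  p_start <- p0
  if (coarse) {
    o1 <- stats::optim(p0, make_cost(vol, 1), method = "Nelder-Mead",
                       control = list(parscale = sc_par, maxit = 300,
                                      abstol = 1e-12, reltol = 1e-10))
    p_start <- o1$par
  }
  cost_f <- make_cost(vol, 0)
  o2 <- stats::optim(p_start, cost_f, method = "Nelder-Mead",
                     control = list(parscale = sc_par / 8, maxit = 200,
                                    abstol = 1e-12, reltol = 1e-10))
  # fresh simplex restart polishes premature Nelder-Mead contraction
  o3 <- stats::optim(o2$par, cost_f, method = "Nelder-Mead",
                     control = list(parscale = sc_par / 32, maxit = 150,
                                    abstol = 1e-12, reltol = 1e-10))
  o3$par
}

#' Rigidly realign all volumes to a reference and rotate b-vectors
#'
#' Estimates a 6-parameter rigid content-motion per volume by maximising
#' the normalised correlation to the reference volume over two scales,
#' resamples each volume by the inverse motion, and rotates its b-vector
#' by the rotation part of the estimated motion.
#'
#' @param ds a [dwi_dataset()].
#' @param reference_index volume index used as registration target.
#' @param mask optional 3-D logical array limiting the cost support.
#' @return list(ds = realigned dataset, trace = `motion_trace`): the trace
#'   is an n x 6 matrix (tx, ty, tz mm; rx, ry, rz rad) of content motion
#'   relative to the reference (all-zero row at the reference).
#' @export
realign_volumes <- function(ds, reference_index = NULL, mask = NULL) {
  stopifnot(inherits(ds, "dwi_dataset"))
  nvol <- dim(ds$data)[4]
  if (is.null(reference_index)) {
    b0s <- which(ds$gtab$b0)
    reference_index <- if (length(b0s)) b0s[1] else 1L
  }
  if (reference_index < 1 || reference_index > nvol)
    stop("reference volume does not exist")
  vox <- voxel_size(ds$affine)
  # Pass 1 registers each volume to a contrast-matched crude target (the
  # reference b0 for b0 volumes, the shell mean for weighted shells) to
  # remove gross motion. Pass 2 mirrors the predictor-based scheme used at
  # service scale: each volume is registered to its own spherical-harmonic
  # signal prediction, which carries the volume's direction-specific
  # contrast and therefore makes rotations observable.
  trace <- matrix(0, nvol, 6,
                  dimnames = list(NULL, c("tx", "ty", "tz",
                                          "rx", "ry", "rz")))
  ref_b0 <- ds$data[, , , reference_index]
  orig <- ds$data
  shells <- shell_indices(ds$gtab)
  register_all <- function(ds, target_of, coarse = TRUE) {
    for (v in seq_len(nvol)) {
      if (v == reference_index) next
      p <- tryCatch(
        estimate_rigid(orig[, , , v], target_of(v), vox, mask,
                       p0 = trace[v, ], coarse = coarse),
        error = function(e) {
          warning("registration failed for volume ", v,
                  "; identity used (", conditionMessage(e), ")")
          trace[v, ]
        })
      trace[v, ] <<- p
      ds$data[, , , v] <- rigid_resample(orig[, , , v], p, vox,
                                         inverse = TRUE)
    }
    ds
  }
  shell_mean <- lapply(shells, function(ii) volume_mean(ds$data, ii))
  shell_key <- as.character(ds$gtab$shell)
  ds <- register_all(ds, function(v)
    if (ds$gtab$b0[v]) ref_b0 else shell_mean[[shell_key[v]]])
  # full-grid predictions: a mask-limited target has an artificial
  # zero boundary that biases the correlation cost near the brain edge
  pred <- predict_signal(ds, NULL, sh_order = 4)
  ds <- register_all(ds, function(v) pred[, , , v])
  rots <- lapply(seq_len(nvol), function(v) rigid_rotation(trace[v, ]))
  ds$gtab <- rotate_bvecs(ds$gtab, rots)
  structure_trace <- structure(trace, reference = reference_index,
                               class = "motion_trace")
  list(ds = ds, trace = structure_trace)
}

# Mean across a subset of volumes of a 4-D array, as a 3-D array.
volume_mean <- function(data, ii) {
  d <- dim(data)
  m <- matrix(data[, , , ii, drop = FALSE], prod(d[1:3]), length(ii))
  array(rowMeans(m), d[1:3])
}

# Compose two content motions (apply p_inner first, then p_outer).
compose_rigid <- function(p_outer, p_inner, centre = c(0, 0, 0)) {
  M <- rigid_matrix(p_outer, centre) %*% rigid_matrix(p_inner, centre)
  R <- M[1:3, 1:3]
  ry <- asin(pmin(1, pmax(-1, R[1, 3])))
  rx <- atan2(-R[2, 3], R[3, 3])
  rz <- atan2(-R[1, 2], R[1, 1])
  tr <- as.numeric(M[1:3, 4] - centre + R %*% centre)
  c(tr, rx, ry, rz)
}

#' @export
print.motion_trace <- function(x, ...) {
  tr <- sqrt(rowSums(x[, 1:3, drop = FALSE]^2))
  cat("motion_trace:", nrow(x), "volumes, reference",
      attr(x, "reference"), "\n")
  cat("  translation magnitude (mm): mean", signif(mean(tr), 3),
      "max", signif(max(tr), 3), "\n")
  invisible(x)
}

#' Predict the diffusion signal with per-shell spherical-harmonic fits
#'
#' For every voxel and shell, fits a real even-order spherical-harmonic
#' series to the measured directions by least squares and evaluates it at
#' those same directions; the b0 prediction is the mean of the b0 volumes.
#' Serves as the reference signal for outlier detection and for the
#' prediction-based CNR/SNR quality metrics.
#'
#' @param ds a [dwi_dataset()].
#' @param mask 3-D logical array; voxels outside are returned as zero.
#' @param sh_order maximum even SH order (lowered per shell when a shell
#'   has too few directions; reported via message).
#' @param exclude optional logical matrix (volumes x slices) marking
#'   measurements to leave out of the fit (outlier refits).
#' @param loo if TRUE (default) each volume's prediction excludes that
#'   volume's own measurement (leave-one-out via the hat-matrix
#'   diagonal), so a corrupted or misaligned volume cannot anchor its own
#'   reference.
#' @return 4-D array of predictions, same dim as `ds$data`.
#' @export
predict_signal <- function(ds, mask = NULL, sh_order = 4, exclude = NULL,
                           loo = TRUE) {
  stopifnot(inherits(ds, "dwi_dataset"))
  d <- dim(ds$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mvec <- as.logical(mask)
  pred <- array(0, d)
  dat <- matrix(ds$data, prod(d[1:3]), d[4])
  shells <- shell_indices(ds$gtab)
  nz <- d[3]
  slice_of <- rep(seq_len(nz), each = d[1] * d[2])
  for (sh in names(shells)) {
    ii <- shells[[sh]]
    if (sh == "0") {
      p <- rowMeans(dat[, ii, drop = FALSE])
      nb <- length(ii)
      for (v in ii) {
        pv <- if (loo && nb > 1) (p * nb - dat[, v]) / (nb - 1) else p
        pred[, , , v][array(mvec, d[1:3])] <- pv[mvec]
      }
      next
    }
    ord <- max_sh_order(length(ii), sh_order)
    if (ord < sh_order)
      message("shell b=", sh, ": SH order lowered to ", ord,
              " (", length(ii), " directions)")
    B <- sh_basis(ds$gtab$bvecs[ii, , drop = FALSE], ord)
    H <- B %*% pinv_tol(B)
    if (is.null(exclude)) {
      S <- dat[mvec, ii, drop = FALSE]
      P <- S %*% t(H)
      if (loo) {
        h <- pmin(diag(H), 0.95)
        P <- sweep(P - sweep(S, 2, h, `*`), 2, 1 - h, `/`)
      }
      for (k in seq_along(ii))
        pred[, , , ii[k]][array(mvec, d[1:3])] <- P[, k]
    } else {
      # per-slice exclusion pattern: refit each slice without the
      # excluded measurements; predictions stay leave-one-out for the
      # kept volumes so no volume anchors its own reference
      for (z in seq_len(nz)) {
        rows <- mvec & slice_of == z
        if (!any(rows)) next
        keep <- !exclude[ii, z]
        if (sum(keep) < ncol(B)) keep <- keep | TRUE  # too few: keep all
        S <- dat[rows, ii, drop = FALSE]
        kept_idx <- which(keep)
        Bk <- B[kept_idx, , drop = FALSE]
        Hk <- B %*% pinv_tol(Bk)
        P <- S[, kept_idx, drop = FALSE] %*% t(Hk)
        if (loo) {
          for (k in seq_along(kept_idx)) {
            sub <- kept_idx[-k]
            hrow <- B[kept_idx[k], , drop = FALSE] %*%
              pinv_tol(B[sub, , drop = FALSE])
            P[, kept_idx[k]] <- S[, sub, drop = FALSE] %*% t(hrow)
          }
        }
        for (k in seq_along(ii))
          pred[, , , ii[k]][array(rows, d[1:3])] <- P[, k]
      }
    }
  }
  pred
}

#' Detect and replace outlier slices against a signal prediction
#'
#' For each slice of every diffusion-weighted volume the in-mask mean
#' residual (observed minus predicted) is standardised per shell with
#' robust statistics; slices below `-z_thresh` standard deviations
#' (dropout; optionally two-sided to also catch spin-history
#' hyper-intensities) are flagged and their in-mask voxels replaced by a
#' prediction refitted without the flagged slices (one refinement pass).
#'
#' @param ds a [dwi_dataset()].
#' @param predictions 4-D array from [predict_signal()].
#' @param mask 3-D logical array.
#' @param z_thresh flagging threshold in robust standard deviations
#'   (default 4).
#' @param two_sided if TRUE also flag positive deviations.
#' @param replace if TRUE (default) replace flagged slices.
#' @param sh_order SH order for the replacement refit.
#' @return list(ds = dataset with replacements, table = `outlier_table`
#'   data.frame(volume, slice, z, flagged, replaced), unusable = volume
#'   indices with more than half their slices flagged (left untouched)).
#' @export
detect_replace_outliers <- function(ds, predictions, mask = NULL,
                                    z_thresh = 4, two_sided = FALSE,
                                    replace = TRUE, sh_order = 4) {
  stopifnot(inherits(ds, "dwi_dataset"))
  d <- dim(ds$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  nz <- d[3]
  dwi <- which(!ds$gtab$b0)
  slice_mask_n <- vapply(seq_len(nz), function(z) sum(mask[, , z]),
                         numeric(1))
  scored <- expand.grid(slice = seq_len(nz), volume = dwi)
  scored <- scored[slice_mask_n[scored$slice] >= 10, c("volume", "slice")]
  shell_of <- ds$gtab$shell[scored$volume]
  score <- function(preds) {
    res_mean <- mapply(function(v, z) {
      m <- mask[, , z]
      mean(ds$data[, , z, v][m] - preds[, , z, v][m])
    }, scored$volume, scored$slice)
    # a slice mean over n voxels has variance ~ 1/n: scale by sqrt(n) so
    # small edge slices are not spuriously extreme
    res_norm <- res_mean * sqrt(slice_mask_n[scored$slice])
    zsc <- res_norm
    for (sh in unique(shell_of)) {
      jj <- shell_of == sh
      med <- stats::median(res_norm[jj])
      sdr <- stats::mad(res_norm[jj])
      if (sdr == 0) sdr <- stats::sd(res_norm[jj])
      if (!is.finite(sdr) || sdr == 0) sdr <- Inf
      zsc[jj] <- (res_norm[jj] - med) / sdr
    }
    zsc
  }
  flags_of <- function(zsc)
    if (two_sided) abs(zsc) > z_thresh else zsc < -z_thresh
  excl_of <- function(flags) {
    e <- matrix(FALSE, d[4], nz)
    e[cbind(scored$volume[flags], scored$slice[flags])] <- TRUE
    e
  }
  zsc <- score(predictions)
  flagged <- flags_of(zsc)
  # refinement passes: an outlier slice contaminates the (signed)
  # hat-matrix predictions of other volumes at the same slice, so
  # re-score against predictions refitted without the flagged slices,
  # until the flag set is stable
  for (pass in 1:3) {
    if (!any(flagged)) break
    refit <- predict_signal(ds, mask, sh_order = sh_order,
                            exclude = excl_of(flagged))
    zsc <- score(refit)
    new_flags <- flags_of(zsc)
    stable <- identical(new_flags, flagged)
    flagged <- new_flags
    if (stable) break
  }
  tab <- data.frame(volume = scored$volume, slice = scored$slice,
                    z = zsc, flagged = flagged, replaced = FALSE)
  # volumes with > 50% flagged slices are unusable, not replaced
  frac <- tapply(tab$flagged, tab$volume, mean)
  unusable <- as.integer(names(frac)[frac > 0.5])
  if (replace && any(tab$flagged)) {
    excl <- matrix(FALSE, d[4], nz)
    sel <- tab$flagged & !(tab$volume %in% unusable)
    excl[cbind(tab$volume[sel], tab$slice[sel])] <- TRUE
    refit <- predict_signal(ds, mask, sh_order = sh_order, exclude = excl)
    for (i in which(sel)) {
      v <- tab$volume[i]; z <- tab$slice[i]
      m <- mask[, , z]
      sl <- ds$data[, , z, v]
      sl[m] <- pmax(0, refit[, , z, v][m])
      ds$data[, , z, v] <- sl
      tab$replaced[i] <- TRUE
    }
  }
  structure(list(ds = ds,
                 table = structure(tab, class = c("outlier_table",
                                                  "data.frame")),
                 unusable = unusable),
            class = "outlier_result")
}

#' Super-resolve thick overlapping slices to an isotropic grid
#'
#' Inverts the thick-slice forward model of [sample_thick_slices()] by
#' Tikhonov-regularised least squares along each through-plane column:
#' the normal matrix (forward matrix from the slice profile plus a
#' second-difference regulariser of weight `lambda_reg`) is factorised
#' once and applied to every column of every volume independently.
#'
#' @param stacks 3-D or 4-D array of thick-slice data (slices along the
#'   third axis, centred every `spacing` mm).
#' @param thickness slice thickness in mm.
#' @param spacing slice spacing in mm (also the target resolution).
#' @param profile slice profile, as in [sample_thick_slices()].
#' @param lambda_reg regularisation weight (default 0.05).
#' @return array of the same shape on the isotropic grid.
#' @export
superresolve <- function(stacks, thickness, spacing, profile = "boxcar",
                         lambda_reg = 0.05) {
  d <- dim(stacks)
  is4d <- length(d) == 4L
  nz <- if (is4d) d[3] else d[3]
  A <- slice_forward_matrix(nz, spacing, thickness, spacing, profile)
  k <- ncol(A)
  D2 <- matrix(0, max(0, k - 2), k)
  for (i in seq_len(max(0, k - 2))) D2[i, i:(i + 2)] <- c(1, -2, 1)
  M <- crossprod(A) + lambda_reg * crossprod(D2)
  Mc <- chol(M)
  solve_cols <- function(vol) {
    m <- matrix(aperm(vol, c(3, 1, 2)), nz, d[1] * d[2])
    x <- backsolve(Mc, backsolve(Mc, crossprod(A, m), transpose = TRUE))
    aperm(array(x, c(k, d[1], d[2])), c(2, 3, 1))
  }
  if (!is4d) return(solve_cols(stacks))
  out <- array(0, c(d[1], d[2], k, d[4]))
  for (v in seq_len(d[4])) out[, , , v] <- solve_cols(stacks[, , , v])
  out
}
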