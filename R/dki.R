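#' Fit the kurtosis-augmented diffusion tensor model
#'
#' Weighted linear least squares on
#' \deqn{\ln S = \ln S_0 - b\,g^T D g + \tfrac{b^2}{6}\,(g^T D g)^2\,\bar K,}
#' a second-order expansion of the log-attenuation in powers of b with a
#' single mean-kurtosis parameter. The quadratic term uses the directional
#' apparent diffusivity squared, which keeps the model a per-direction
#' Taylor series; `kurtosis_scale = "md2"` instead scales the kurtosis term
#' by the squared mean diffusivity. The fit is iterated once with signal
#' weights (WLS) after an unweighted pass, and once more to refresh the
#' directional diffusivity in the kurtosis regressor.
#'
#' @param ds a [dwi_dataset()] with at least two shells plus b0s.
#' @param mask 3-D logical array of voxels to fit.
#' @param kurtosis_scale "adc2" (default) or "md2".
#' @param mk_bounds mean-kurtosis clamp bounds (default c(-1, 5)).
#' @param rician_correct if TRUE (default) apply a per-voxel moment
#'   correction `S = sqrt(max(M^2 - 2 sigma^2, 0))` before the log, with
#'   sigma estimated from the b0 repeats; the Rician noise floor otherwise
#'   inflates kurtosis at the strongly attenuated outer shell.
#' @return object of class `dki_fit`: per-voxel `S0`, tensor elements
#'   `D` (n x 6: dxx, dyy, dzz, dxy, dxz, dyz in mm^2/s), mean kurtosis
#'   `MK`, residual variance `rss`, logical `clamped` (negative
#'   eigenvalues clamped to 1e-6), plus the mask and grid geometry.
#' @export
fit_dki <- function(ds, mask = NULL, kurtosis_scale = c("adc2", "md2"),
                    mk_bounds = c(-1, 5), rician_correct = TRUE) {
  stopifnot(inherits(ds, "dwi_dataset"))
  kurtosis_scale <- match.arg(kurtosis_scale)
  shells <- setdiff(unique(ds$gtab$shell), 0)
  if (length(shells) < 2)
    stop("kurtosis fitting needs at least two non-zero shells")
  if (!any(ds$gtab$b0)) stop("no b0 volumes present")
  d <- dim(ds$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mvec <- which(as.logical(mask))
  dat <- matrix(ds$data, prod(d[1:3]), d[4])[mvec, , drop = FALSE]
  b <- ds$gtab$bvals
  g <- ds$gtab$bvecs
  # design for the tensor part: ln S = X %*% (ln S0, D6)
  G6 <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
              2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
              2 * g[, 2] * g[, 3])
  X <- cbind(1, -b * G6)
  eps <- 1e-3
  raw <- dat
  sigma <- rep(0, nrow(dat))
  if (rician_correct && sum(ds$gtab$b0) >= 2) {
    sigma <- apply(dat[, ds$gtab$b0, drop = FALSE], 1, stats::sd)
    sigma[!is.finite(sigma)] <- 0
    # moment correction for the log-domain initialiser only; the
    # Gauss-Newton stage models the Rician mean explicitly
    dat <- sqrt(pmax(dat^2 - 2 * sigma^2, 0))
  }
  logS <- log(pmax(dat, eps))
  n <- nrow(dat)
  beta <- matrix(0, n, 8)
  rss <- numeric(n)
  ok <- rowSums(dat) > 0
  fit_rows <- function(Xk, Y, W = NULL) {
    # per-voxel weighted LS with common design: loop over voxels
    out <- matrix(0, nrow(Y), ncol(Xk) + 1)
    XtX <- crossprod(Xk)
    Xt <- t(Xk)
    if (is.null(W)) {
      cf <- t(solve(XtX, Xt %*% t(Y)))
      res <- Y - cf %*% Xt
      return(list(coef = cf, rss = rowSums(res^2)))
    }
    cf <- matrix(0, nrow(Y), ncol(Xk))
    rs <- numeric(nrow(Y))
    for (i in seq_len(nrow(Y))) {
      w <- W[i, ]
      Xw <- Xk * w
      fitc <- tryCatch(solve(crossprod(Xw, Xk), crossprod(Xw, Y[i, ])),
                       error = function(e) rep(NA_real_, ncol(Xk)))
      cf[i, ] <- fitc
      rs[i] <- sum(w * (Y[i, ] - Xk %*% fitc)^2) / mean(w)
    }
    list(coef = cf, rss = rs)
  }
  # pass 1: plain DTI (no kurtosis) to get directional ADC
  f1 <- fit_rows(X, logS[ok, , drop = FALSE])
  D1 <- f1$coef[, 2:7, drop = FALSE]
  adc <- D1 %*% t(G6)                       # n_ok x nvol
  if (kurtosis_scale == "md2") {
    md <- (D1[, 1] + D1[, 2] + D1[, 3]) / 3
    adc_k <- matrix(md, nrow(adc), ncol(adc))
  } else adc_k <- adc
  # pass 2: one weighted log-domain pass with the kurtosis column, as the
  # initialiser for the signal-domain refinement
  kcol <- t(t(adc_k^2) * b^2) / 6
  Y <- logS[ok, , drop = FALSE]
  W <- pmax(dat[ok, , drop = FALSE], eps)^2  # WLS weights ~ S^2
  n_ok <- sum(ok)
  cf <- matrix(0, n_ok, 8)
  rs <- numeric(n_ok)
  for (i in seq_len(n_ok)) {
    Xi <- cbind(X, kcol[i, ])
    w <- W[i, ]
    Xw <- Xi * w
    ci <- tryCatch(solve(crossprod(Xw, Xi), crossprod(Xw, Y[i, ])),
                   error = function(e) rep(NA_real_, 8))
    cf[i, ] <- ci
    rs[i] <- mean((Y[i, ] - Xi %*% ifelse(is.na(ci), 0, ci))^2)
  }
  # pass 3: Levenberg-damped Gauss-Newton in the signal domain. The
  # log-domain fit is distorted where measurements approach the noise
  # floor (strongly attenuated directions on the outer shell), which
  # inflates the curvature term; the signal-domain residual is not.
  md2 <- kurtosis_scale == "md2"
  rawok <- raw[ok, , drop = FALSE]
  sigok <- sigma[ok]
  for (i in seq_len(n_ok)) {
    th <- cf[i, ]
    if (anyNA(th)) next
    y <- rawok[i, ]
    sg <- sigok[i]
    lam <- 1e-4
    pred_fun <- function(th) {
      adc_i <- as.numeric(G6 %*% th[2:7])
      a_k <- if (md2) mean(th[c(2, 3, 4)]) else adc_i
      S <- exp(pmin(th[1] - b * adc_i + b^2 / 6 * a_k^2 * th[8], 700))
      list(S = S, m = rician_mean(S, sg), adc = adc_i, a_k = a_k)
    }
    pf <- pred_fun(th)
    rcur <- sum((y - pf$m)^2)
    for (gn in 1:12) {
      S <- pf$S; a_k <- pf$a_k
      # Jacobian of S, scaled by d E[M]/dS of the Rician mean
      dD <- S * (-b + if (md2) 0 else b^2 / 3 * a_k * th[8])
      J <- cbind(S, dD * G6, S * b^2 / 6 * a_k^2)
      if (md2) J[, 2:4] <- J[, 2:4] + (S * b^2 / 3 * a_k * th[8] / 3) *
          matrix(1, length(b), 3)
      if (sg > 0) J <- J * rician_mean_deriv(S, sg)
      r <- y - pf$m
      A <- crossprod(J) + lam * diag(8)
      step <- tryCatch(solve(A, crossprod(J, r)), error = function(e) NULL)
      if (is.null(step)) break
      th_new <- th + as.numeric(step)
      pf_new <- pred_fun(th_new)
      rnew <- sum((y - pf_new$m)^2)
      if (is.finite(rnew) && rnew < rcur) {
        th <- th_new; pf <- pf_new
        if (rcur - rnew < 1e-10 * rcur) { rcur <- rnew; break }
        rcur <- rnew
        lam <- lam / 3
      } else lam <- lam * 10
      if (lam > 1e6) break
    }
    cf[i, ] <- th
    rs[i] <- rcur / length(b)
  }
  beta[ok, ] <- cf
  rss[ok] <- rs
  beta[!ok, ] <- NA
  rss[!ok] <- NA
  S0 <- exp(beta[, 1])
  D <- beta[, 2:7, drop = FALSE]
  # MK = K * MD^2 / adc^2 folded in already; the fitted coefficient IS MK
  MK <- pmin(pmax(beta[, 8], mk_bounds[1]), mk_bounds[2])
  # clamp negative eigenvalues
  clamped <- logical(n)
  for (i in seq_len(n)) {
    if (!ok[i] || anyNA(D[i, ])) next
    T6 <- tensor_matrix(D[i, ])
    ev <- eigen(T6, symmetric = TRUE)
    if (any(ev$values < 0)) {
      ev$values <- pmax(ev$values, 1e-6 * 1e-3)
      T6 <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
      D[i, ] <- T6[c(1, 5, 9, 2, 3, 6)]
      clamped[i] <- TRUE
    }
  }
  structure(list(S0 = S0, D = D, MK = MK, rss = rss, clamped = clamped,
                 mask = mask, voxel_index = mvec, dim = d[1:3],
                 affine = ds$affine, kurtosis_scale = kurtosis_scale),
            class = "dki_fit")
}

# Mean of a Rician variate with true amplitude S and noise sigma:
# sigma sqrt(pi/2) L_{1/2}(-S^2 / 2 sigma^2), via exponentially scaled
# Bessel functions for stability at high SNR.
rician_mean <- function(S, sigma) {
  if (sigma <= 0) return(S)
  S <- pmin(S, 1e12)          # keep degenerate fits finite
  x <- S^2 / (2 * sigma^2)
  i0 <- besselI(x / 2, 0, expon.scaled = TRUE)
  i1 <- besselI(x / 2, 1, expon.scaled = TRUE)
  m <- sigma * sqrt(pi / 2) * ((1 + x) * i0 + x * i1)
  # large-SNR asymptote to avoid overflow of the Laguerre form
  hi <- !is.finite(m) | x > 350
  if (any(hi)) m[hi] <- sqrt(S[hi]^2 + sigma^2)
  m
}

rician_mean_deriv <- function(S, sigma, rel = 1e-4) {
  h <- pmax(S * rel, sigma * 1e-4)
  (rician_mean(S + h, sigma) - rician_mean(pmax(S - h, 0), sigma)) /
    (h + pmin(S, h))
}

tensor_matrix <- function(d6) {
  rbind(c(d6[1], d6[4], d6[5]),
        c(d6[4], d6[2], d6[6]),
        c(d6[5], d6[6], d6[3]))
}

#' @export
print.dki_fit <- function(x, ...) {
  md <- (x$D[, 1] + x$D[, 2] + x$D[, 3]) / 3 * 1e3
  cat("dki_fit:", length(x$S0), "voxels\n")
  cat("  median MD:", signif(stats::median(md, na.rm = TRUE), 3),
      "um^2/ms  median MK:", signif(stats::median(x$MK, na.rm = TRUE), 3),
      "\n")
  invisible(x)
}

#' @export
coef.dki_fit <- function(object, ...) {
  cbind(S0 = object$S0, object$D, MK = object$MK)
}

#' Scalar maps derived from a tensor fit
#'
#' Eigendecomposition of the fitted tensor per voxel: fractional
#' anisotropy by the standard formula, axial diffusivity (largest
#' eigenvalue), radial diffusivity (mean of the two smaller), mean
#' diffusivity (trace/3), mean kurtosis passthrough, and the principal
#' eigenvector field. Diffusivities are reported in um^2/ms.
#'
#' @param fit a [fit_dki()] result.
#' @return object of class `scalar_maps`: 3-D arrays FA, MD, AD, RD, MK
#'   and a 4-D (x,y,z,3) principal eigenvector array V1. Voxels outside
#'   the fit mask are NA.
#' @export
tensor_derived_maps <- function(fit) {
  stopifnot(inherits(fit, "dki_fit"))
  n <- nrow(fit$D)
  FA <- MD <- AD <- RD <- rep(NA_real_, n)
  V <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (anyNA(fit$D[i, ])) next
    ev <- eigen(tensor_matrix(fit$D[i, ]), symmetric = TRUE)
    l <- sort(ev$values, decreasing = TRUE)
    AD[i] <- l[1]; RD[i] <- (l[2] + l[3]) / 2; MD[i] <- mean(l)
    mb <- mean(l)
    denom <- sqrt(l[1]^2 + l[2]^2 + l[3]^2)
    FA[i] <- if (denom > 0)
      sqrt(3 / 2) * sqrt(sum((l - mb)^2)) / denom else 0
    V[i, ] <- ev$vectors[, which.max(ev$values)]
  }
  to_map <- function(v) {
    a <- array(NA_real_, fit$dim)
    a[fit$voxel_index] <- v
    a
  }
  V1 <- array(NA_real_, c(fit$dim, 3))
  for (k in 1:3) V1[, , , k] <- to_map(V[, k])
  structure(list(FA = to_map(FA), MD = to_map(MD * 1e3),
                 AD = to_map(AD * 1e3), RD = to_map(RD * 1e3),
                 MK = to_map(fit$MK), V1 = V1,
                 affine = fit$affine),
            class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat("scalar_maps:", paste(dim(x$FA), collapse = " x "), "grid\n")
  for (nm in c("FA", "MD", "AD", "RD", "MK"))
    cat(sprintf("  %-3s median %.3f\n", nm,
                stats::median(x[[nm]], na.rm = TRUE)))
  invisible(x)
}
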