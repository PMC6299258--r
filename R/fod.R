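#' Estimate the Gaussian prior on the deconvolution kernel width
#'
#' The single-fibre response kernel is an axially symmetric tensor whose
#' width lambda_R (minor/major axis ratio) varies across the brain. Its
#' Gaussian prior is estimated from data: within a coherent single-fibre
#' region (a corpus-callosum mask at service scale; the phantom's bundle
#' core here), the 50% of voxels with highest FA are retained, lambda_R
#' is computed per voxel as ((lambda2 + lambda3)/2) / lambda1, and the
#' prior mean/sd are the mean and sd of per-subject means across subjects
#' (across voxels for a single subject).
#'
#' @param fits a [fit_dki()] result, or a list of them (one per subject).
#' @param cc_mask 3-D logical array of the coherent single-fibre region.
#'   When NULL, the neonatal cohort default prior (mean 0.3, sd 0.08) is
#'   returned.
#' @return object of class `kernel_prior`: list(mean, sd), mean in (0, 1).
#' @export
estimate_kernel_prior <- function(fits = NULL, cc_mask = NULL) {
  if (is.null(fits)) {
    return(structure(list(mean = 0.3, sd = 0.08, n_subjects = 0L),
                     class = "kernel_prior"))
  }
  if (inherits(fits, "dki_fit")) fits <- list(fits)
  per_subject <- vapply(fits, function(fit) {
    maps <- tensor_derived_maps(fit)
    m <- as.logical(cc_mask)
    fa <- maps$FA[m]
    ok <- is.finite(fa)
    if (!any(ok)) stop("empty mask after FA filter")
    thr <- stats::median(fa[ok])
    keep <- which(m)[ok & fa >= thr]
    if (!length(keep)) stop("empty mask after FA filter")
    lam_r <- (maps$RD[keep]) / (maps$AD[keep])
    mean(lam_r[is.finite(lam_r)])
  }, numeric(1))
  if (length(per_subject) == 1) {
    # single subject: spread taken across its voxels
    fit <- fits[[1]]
    maps <- tensor_derived_maps(fit)
    m <- as.logical(cc_mask)
    fa <- maps$FA[m]
    ok <- is.finite(fa)
    thr <- stats::median(fa[ok])
    keep <- which(m)[ok & fa >= thr]
    lam_r <- (maps$RD[keep]) / (maps$AD[keep])
    lam_r <- lam_r[is.finite(lam_r)]
    pm <- mean(lam_r); ps <- stats::sd(lam_r)
  } else {
    pm <- mean(per_subject); ps <- stats::sd(per_subject)
  }
  if (!is.finite(ps) || ps <= 0) ps <- 1e-3
  structure(list(mean = min(max(pm, 1e-3), 1 - 1e-3), sd = ps,
                 n_subjects = length(per_subject)),
            class = "kernel_prior")
}

#' @export
print.kernel_prior <- function(x, ...) {
  cat("kernel_prior: lambda_R ~ N(", signif(x$mean, 3), ", ",
      signif(x$sd, 3), "^2), truncated to (0, 1)\n", sep = "")
  invisible(x)
}

# Deconvolution signal model: S/S0 = f_iso e^(-b d_iso) +
# sum_i f_i e^(-b lpar (lR + (1 - lR)(g.v_i)^2)), remaining fraction
# hindered-isotropic at the kernel's mean diffusivity.
fod_predict <- function(state, b, g, d_iso) {
  att <- state$f_iso * exp(-b * d_iso)
  f_sum <- state$f_iso
  lpar <- state$lpar; lR <- state$lR
  for (k in seq_along(state$f)) {
    gd2 <- as.numeric((g %*% state$v[[k]])^2)
    att <- att + state$f[k] * exp(-b * lpar * (lR + (1 - lR) * gd2))
    f_sum <- f_sum + state$f[k]
  }
  att <- att + (1 - f_sum) * exp(-b * lpar * (1 + 2 * lR) / 3)
  state$S0 * att
}

# Rician log-likelihood (sigma fixed per voxel).
rician_loglik <- function(y, mu, sigma) {
  mu <- pmax(mu, 1e-9)
  x <- y * mu / sigma^2
  sum(log(y / sigma^2) - (y^2 + mu^2) / (2 * sigma^2) +
        x + log(besselI(x, 0, expon.scaled = TRUE)))
}

#' Fit fibre orientations by Bayesian parametric deconvolution
#'
#' Per voxel, Metropolis-Hastings sampling of \{S0, lambda_par, lambda_R,
#' f_iso, (f_i, v_i)\} under a Rician likelihood. The FOD is a sum of up
#' to `n_fibres` delta functions convolved with an axially symmetric
#' tensor kernel whose width lambda_R carries the Gaussian prior
#' (truncated to (0, 1)) from [estimate_kernel_prior()]. Automatic
#' relevance determination (a 1/(f + f0) shrinkage prior) on the second
#' and later fibre fractions prunes compartments the data do not support;
#' a fibre "exists" when its posterior mean fraction reaches
#' `survival_threshold` (0.05).
#'
#' @param ds a [dwi_dataset()].
#' @param mask 3-D logical array of voxels to fit.
#' @param prior a `kernel_prior` (default: the neonatal cohort prior).
#' @param n_fibres maximum fibre compartments (default 3).
#' @param n_burn,n_keep,thin MCMC schedule: burn-in iterations, kept
#'   iterations, thinning (defaults 1000 / 1250 / 25).
#' @param d_iso free-water diffusivity (mm^2/s).
#' @param survival_threshold posterior-mean fraction above which a fibre
#'   is reported (default 0.05).
#' @param seed RNG seed (sampling is deterministic given it).
#' @return object of class `fod_fit`: per voxel a list with posterior
#'   mean fractions `f` (sorted decreasing), mean orientations `v`
#'   (antipodally canonicalised unit vectors), `f_iso`, `lambda_R`
#'   posterior mean, `lambda_par`, orientation samples per surviving
#'   fibre, acceptance rate and a `mixed` flag; plus mask geometry and
#'   the survival threshold.
#' @export
fit_fod <- function(ds, mask = NULL, prior = estimate_kernel_prior(),
                    n_fibres = 3, n_burn = 1000, n_keep = 1250, thin = 25,
                    d_iso = 3.0e-3, survival_threshold = 0.05,
                    seed = 1L) {
  stopifnot(inherits(ds, "dwi_dataset"), inherits(prior, "kernel_prior"))
  d <- dim(ds$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mvec <- which(as.logical(mask))
  dat <- matrix(ds$data, prod(d[1:3]), d[4])[mvec, , drop = FALSE]
  b <- ds$gtab$bvals
  g <- ds$gtab$bvecs
  b0s <- ds$gtab$b0
  set.seed(seed)
  voxels <- vector("list", length(mvec))
  for (i in seq_along(mvec)) {
    y <- dat[i, ]
    if (all(y <= 0)) next
    voxels[[i]] <- fod_sample_voxel(y, b, g, b0s, prior, n_fibres,
                                    n_burn, n_keep, thin, d_iso)
  }
  structure(list(voxels = voxels, mask = mask, voxel_index = mvec,
                 dim = d[1:3], prior = prior,
                 survival_threshold = survival_threshold,
                 affine = ds$affine, voxel_size = voxel_size(ds$affine)),
            class = "fod_fit")
}

# MCMC for one voxel. Returns posterior summaries + orientation samples.
fod_sample_voxel <- function(y, b, g, b0s, prior, n_fibres,
                             n_burn, n_keep, thin, d_iso,
                             ard_f0 = 1e-3, ard_weight = 2) {
  S0_init <- max(mean(y[b0s]), 1)
  sigma <- stats::sd(y[b0s])
  if (!is.finite(sigma) || sigma < 1e-3 * S0_init)
    sigma <- max(0.05 * S0_init, 1e-6)
  # init from the spherical mean profile and the strongest direction
  dwi <- !b0s
  v0 <- g[dwi, , drop = FALSE][which.min(y[dwi]), ]
  if (sum(v0^2) == 0) v0 <- c(0, 0, 1)
  v0 <- v0 / sqrt(sum(v0^2))
  state <- list(S0 = S0_init, lpar = 1.5e-3, lR = prior$mean,
                f_iso = 0.1, f = rep(0.2, n_fibres),
                v = lapply(seq_len(n_fibres), function(k)
                  if (k == 1) v0 else sphere_points(n_fibres + 1)[k, ]))
  log_prior <- function(st) {
    if (st$f_iso < 0 || st$f_iso > 1 || any(st$f < 0) ||
        st$f_iso + sum(st$f) > 1 || st$lR <= 0 || st$lR >= 1 ||
        st$lpar <= 0 || st$S0 <= 0) return(-Inf)
    lp <- stats::dnorm(st$lR, prior$mean, prior$sd, log = TRUE)
    # weakly-informative log-normal prior on lambda_par
    lp <- lp + stats::dlnorm(st$lpar, log(1.5e-3), 0.5, log = TRUE)
    # ARD shrinkage on all fibre fractions: unsupported compartments
    # (including a lone fibre in free water) are driven to zero, while a
    # data-supported fraction overwhelms the mild log penalty
    lp <- lp - ard_weight * sum(log(st$f + ard_f0))
    lp
  }
  log_post <- function(st) {
    lp <- log_prior(st)
    if (!is.finite(lp)) return(-Inf)
    lp + rician_loglik(y, fod_predict(st, b, g, d_iso), sigma)
  }
  cur_lp <- log_post(state)
  n_iter <- n_burn + n_keep
  kept <- seq(n_burn + 1, n_iter, by = max(1, thin))
  sum_f <- numeric(n_fibres); sum_fiso <- 0; sum_lR <- 0; sum_lpar <- 0
  sum_S0 <- 0
  v_samples <- lapply(seq_len(n_fibres), function(k)
    matrix(0, length(kept), 3))
  n_sample <- 0
  accept <- 0; proposals <- 0
  # proposal scales, adapted during burn-in
  sc <- list(S0 = 0.02 * S0_init, lpar = 1.5e-4, lR = 0.05, f = 0.05,
             v = 0.15)
  for (it in seq_len(n_iter)) {
    # scalar parameters
    for (nm in c("S0", "lpar", "lR", "f_iso")) {
      cand <- state
      if (nm == "f_iso") cand$f_iso <- state$f_iso + stats::rnorm(1, 0, sc$f)
      else cand[[nm]] <- state[[nm]] + stats::rnorm(1, 0, sc[[nm]])
      lp <- log_post(cand)
      proposals <- proposals + 1
      if (is.finite(lp) && log(stats::runif(1)) < lp - cur_lp) {
        state <- cand; cur_lp <- lp; accept <- accept + 1
      }
    }
    # fibre fractions and orientations
    for (k in seq_len(n_fibres)) {
      cand <- state
      cand$f[k] <- state$f[k] + stats::rnorm(1, 0, sc$f)
      lp <- log_post(cand)
      proposals <- proposals + 1
      if (is.finite(lp) && log(stats::runif(1)) < lp - cur_lp) {
        state <- cand; cur_lp <- lp; accept <- accept + 1
      }
      cand <- state
      vv <- state$v[[k]] + stats::rnorm(3, 0, sc$v)
      cand$v[[k]] <- vv / sqrt(sum(vv^2))
      lp <- log_post(cand)
      proposals <- proposals + 1
      if (is.finite(lp) && log(stats::runif(1)) < lp - cur_lp) {
        state <- cand; cur_lp <- lp; accept <- accept + 1
      }
    }
    if (it <= n_burn && it %% 100 == 0) {
      rate <- accept / proposals
      adj <- if (rate < 0.2) 0.7 else if (rate > 0.5) 1.4 else 1
      sc <- lapply(sc, `*`, adj)
      accept <- 0; proposals <- 0
    }
    if (it == n_burn) { accept <- 0; proposals <- 0 }
    if (it %in% kept) {
      n_sample <- n_sample + 1
      sum_f <- sum_f + state$f
      sum_fiso <- sum_fiso + state$f_iso
      sum_lR <- sum_lR + state$lR
      sum_lpar <- sum_lpar + state$lpar
      sum_S0 <- sum_S0 + state$S0
      for (k in seq_len(n_fibres)) {
        v <- state$v[[k]]
        if (v[3] < 0 || (v[3] == 0 && v[1] < 0)) v <- -v
        v_samples[[k]][n_sample, ] <- v
      }
    }
  }
  mean_f <- sum_f / n_sample
  # mean orientation via the principal axis of the sample outer products
  mean_v <- lapply(v_samples, function(vs) {
    vs <- vs[seq_len(n_sample), , drop = FALSE]
    M <- crossprod(vs) / nrow(vs)
    e <- eigen(M, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (v[3] < 0) -v else v
  })
  ord <- order(mean_f, decreasing = TRUE)
  mean_f <- mean_f[ord]
  mean_v <- mean_v[ord]
  v_samples <- lapply(v_samples[ord], function(vs)
    vs[seq_len(n_sample), , drop = FALSE])
  # merge near-parallel compartments: the sampler occasionally splits one
  # fibre population over two delta functions
  k <- 1
  while (k < length(mean_f)) {
    j <- k + 1
    while (j <= length(mean_f)) {
      if (abs(sum(mean_v[[k]] * mean_v[[j]])) > cos(20 * pi / 180)) {
        mean_f[k] <- mean_f[k] + mean_f[j]
        mean_f <- mean_f[-j]
        mean_v <- mean_v[-j]
        v_samples <- v_samples[-j]
      } else j <- j + 1
    }
    k <- k + 1
  }
  ord <- order(mean_f, decreasing = TRUE)
  rate <- accept / max(proposals, 1)
  list(f = mean_f[ord], v = mean_v[ord],
       v_samples = v_samples[ord],
       f_iso = sum_fiso / n_sample, lambda_R = sum_lR / n_sample,
       lambda_par = sum_lpar / n_sample, S0 = sum_S0 / n_sample,
       sigma = sigma,
       accept_rate = rate,
       mixed = rate >= 0.01)
}

#' Surviving fibres of a FOD fit
#'
#' @param fit a [fit_fod()] result.
#' @param voxel index into the fitted voxel list.
#' @return list(f, v, v_samples) restricted to fibres whose posterior mean
#'   fraction reaches the survival threshold (possibly none).
#' @export
surviving_fibres <- function(fit, voxel) {
  vx <- fit$voxels[[voxel]]
  if (is.null(vx)) return(list(f = numeric(0), v = list(),
                               v_samples = list()))
  keep <- vx$f >= fit$survival_threshold
  list(f = vx$f[keep], v = vx$v[keep], v_samples = vx$v_samples[keep])
}

#' @export
print.fod_fit <- function(x, ...) {
  fitted <- !vapply(x$voxels, is.null, logical(1))
  nf <- vapply(which(fitted), function(i)
    sum(x$voxels[[i]]$f >= x$survival_threshold), numeric(1))
  cat("fod_fit:", sum(fitted), "voxels;",
      "surviving fibre count:", paste(names(table(nf)), "=",
                                      table(nf), collapse = ", "), "\n")
  cat("  posterior mean lambda_R:",
      signif(mean(vapply(which(fitted), function(i)
        x$voxels[[i]]$lambda_R, numeric(1))), 3), "\n")
  invisible(x)
}

#' Build a FOD fit object from known fibre configurations
#'
#' Constructs a `fod_fit` directly from given per-voxel orientations and
#' fractions (for instance the phantom's ground truth), with orientation
#' uncertainty emulated by an angular jitter. This provides tractography
#' with an exactly known orientation field, decoupling its tests from the
#' MCMC estimator.
#'
#' @param orientations 4-D array (x, y, z, 3) of primary fibre
#'   orientations (zero where no fibre).
#' @param fractions 3-D array of primary fibre fractions.
#' @param affine voxel-to-world matrix.
#' @param secondary optional list(orientations, fractions) for a second
#'   fibre population.
#' @param angle_sd angular jitter (radians) used when tracking samples
#'   orientations (default 0.05).
#' @param n_samples number of stored orientation samples per fibre.
#' @param seed RNG seed for the jitter.
#' @return a `fod_fit` object.
#' @export
fod_from_truth <- function(orientations, fractions, affine,
                           secondary = NULL, angle_sd = 0.05,
                           n_samples = 50, seed = 1L) {
  d <- dim(fractions)
  mask <- fractions > 0
  mvec <- which(mask)
  set.seed(seed)
  jitter_samples <- function(v) {
    vs <- matrix(rep(v, each = n_samples), n_samples, 3) +
      matrix(stats::rnorm(3 * n_samples, 0, angle_sd), n_samples, 3)
    vs <- vs / sqrt(rowSums(vs^2))
    flip <- vs[, 3] < 0
    vs[flip, ] <- -vs[flip, , drop = FALSE]
    vs
  }
  voxels <- vector("list", length(mvec))
  om <- matrix(orientations, prod(d), 3)
  for (j in seq_along(mvec)) {
    i <- mvec[j]
    v1 <- om[i, ]
    v1 <- v1 / sqrt(sum(v1^2))
    f <- fractions[i]
    vs <- list(jitter_samples(v1))
    vv <- list(v1)
    ff <- f
    if (!is.null(secondary) && secondary$fractions[i] > 0) {
      v2 <- matrix(secondary$orientations, prod(d), 3)[i, ]
      v2 <- v2 / sqrt(sum(v2^2))
      ff <- c(ff, secondary$fractions[i])
      vv <- c(vv, list(v2))
      vs <- c(vs, list(jitter_samples(v2)))
    }
    voxels[[j]] <- list(f = ff, v = vv, v_samples = vs,
                        f_iso = max(0, 1 - sum(ff)), lambda_R = 0.3,
                        lambda_par = 1.5e-3, S0 = 1, sigma = 0,
                        accept_rate = NA_real_, mixed = TRUE)
  }
  structure(list(voxels = voxels, mask = mask, voxel_index = mvec,
                 dim = d, prior = estimate_kernel_prior(),
                 survival_threshold = 0.05, affine = affine,
                 voxel_size = voxel_size(affine)),
            class = "fod_fit")
}
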