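#' Specification of a synthetic neonatal diffusion phantom
#'
#' Describes the digital phantom the generator builds: grid geometry, a
#' simple neonatal head layout (CSF rim and central ventricle, cortical
#' grey-matter ribbon, white-matter interior crossed by one or two fibre
#' bundles), per-tissue signal parameters and the sampling scheme. The
#' defaults emulate the neonatal protocol this toolkit targets: low
#' white-matter anisotropy (radial/axial ratio 0.3), high free-water
#' content, an elevated isotropic fraction in a periventricular region, and
#' a multi-shell scheme at b = 400/1000/2600 s/mm^2 spread over 4 phase
#' encode directions.
#'
#' @param shape length-3 integer grid size.
#' @param voxel isotropic voxel size in mm.
#' @param scheme sampling scheme as returned by [dhcp_scheme()].
#' @param S0 named numeric: non-diffusion-weighted signal per tissue.
#' @param d_iso free-water diffusivity, mm^2/s.
#' @param d_gm grey-matter diffusivity, mm^2/s.
#' @param lambda_par white-matter axial diffusivity, mm^2/s.
#' @param lambda_ratio white-matter radial/axial diffusivity ratio
#'   (kernel width lambda_R; 0.3 is a neonatal cohort-level value).
#' @param kurtosis named numeric: mean kurtosis per tissue (WM, GM).
#' @param f_iso_wm isotropic (free-water) volume fraction inside
#'   white matter; `f_iso_pv` applies in the periventricular region.
#' @param f_iso_pv periventricular isotropic fraction (elevated, as in the
#'   neonatal brain).
#' @param f_iso_gm isotropic fraction in grey matter.
#' @param crossing if TRUE, add a second bundle perpendicular to the first
#'   through the centrum-semiovale-like core.
#' @param sigma Rician noise level (same units as S0); 0 for noise-free.
#' @param slice_thickness excited slice thickness in mm.
#' @param seed RNG seed making the phantom fully reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 20), voxel = 1.5,
                         scheme = dhcp_scheme(),
                         S0 = c(wm = 700, gm = 800, csf = 1000),
                         d_iso = 3.0e-3, d_gm = 1.1e-3,
                         lambda_par = 1.5e-3, lambda_ratio = 0.3,
                         kurtosis = c(wm = 0.6, gm = 0.4),
                         f_iso_wm = 0.2, f_iso_pv = 0.45, f_iso_gm = 0.1,
                         crossing = FALSE, sigma = 35,
                         slice_thickness = 2 * voxel, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 8), voxel > 0,
            d_iso > 0, d_gm > 0, lambda_par > 0,
            lambda_ratio > 0, lambda_ratio < 1, sigma >= 0)
  fr <- c(f_iso_wm, f_iso_pv, f_iso_gm)
  if (any(fr < 0 | fr > 1)) stop("volume fractions must lie in [0, 1]")
  structure(list(shape = as.integer(shape), voxel = voxel, scheme = scheme,
                 S0 = S0, d_iso = d_iso, d_gm = d_gm,
                 lambda_par = lambda_par, lambda_ratio = lambda_ratio,
                 kurtosis = kurtosis, f_iso_wm = f_iso_wm,
                 f_iso_pv = f_iso_pv, f_iso_gm = f_iso_gm,
                 crossing = crossing, sigma = sigma,
                 slice_thickness = slice_thickness, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Tissue layout: 0 background, 1 CSF, 2 GM, 3 WM. Returns the label array
# plus bundle masks/orientations and the periventricular region.
phantom_layout <- function(spec) {
  d <- spec$shape
  g <- voxel_grid(d)
  c0 <- (d + 1) / 2
  # head: ellipsoid filling ~90% of the grid
  r <- (d / 2 - 1)
  e <- ((g[, 1] - c0[1]) / r[1])^2 + ((g[, 2] - c0[2]) / r[2])^2 +
    ((g[, 3] - c0[3]) / r[3])^2
  head <- e <= 1
  gm <- e <= 0.85 & e > 0.62       # cortical ribbon under a CSF rim
  wm <- e <= 0.62
  tissue <- integer(prod(d))
  tissue[head] <- 1L               # CSF rim by default
  tissue[gm] <- 2L
  tissue[wm] <- 3L
  # ventricle: CSF box near the centre, offset laterally so the head is
  # not rotationally symmetric (as a real brain is not)
  vy <- c0[2] + max(2, round(d[2] / 8))
  vent <- abs(g[, 1] - c0[1]) <= max(1, d[1] / 16) &
    abs(g[, 2] - vy) <= max(1, d[2] / 16) &
    abs(g[, 3] - c0[3]) <= max(1, d[3] / 10)
  tissue[vent & wm] <- 1L
  # periventricular shell around the ventricle, inside WM
  pv <- abs(g[, 1] - c0[1]) <= max(2, d[1] / 8) &
    abs(g[, 2] - vy) <= max(2, d[2] / 8) &
    abs(g[, 3] - c0[3]) <= max(2, d[3] / 6) &
    tissue == 3L
  # bundles: constant-section cylinders through the deep WM, placed below
  # the ventricle so their lanes are uninterrupted; lengths capped so the
  # full cross-section stays inside the WM ellipsoid
  zb <- floor(c0[3]) - max(3, round(d[3] / 6))
  half_y <- max(2, round(d[2] / 16))
  half_z <- 1
  len1 <- max(4, round(d[1] / 4))
  len2 <- max(4, round(d[2] / 4))
  b1 <- tissue == 3L & abs(g[, 2] - c0[2]) <= half_y &
    abs(g[, 3] - zb) <= half_z & abs(g[, 1] - c0[1]) <= len1
  # bundle 2 (optional crossing): along y at the same depth
  b2 <- tissue == 3L & abs(g[, 1] - c0[1]) <= half_y &
    abs(g[, 3] - zb) <= half_z & abs(g[, 2] - c0[2]) <= len2
  dim(tissue) <- d
  list(tissue = tissue,
       pv = array(pv, d),
       bundle1 = array(b1, d),
       bundle2 = array(b2, d),
       orient1 = c(1, 0, 0), orient2 = c(0, 1, 0))
}

# Attenuation of an axially symmetric tensor compartment with optional
# kurtosis: exp(-b * adc + b^2/6 * adc^2 * K), adc = l_perp +
# (l_par - l_perp) (g.v)^2.
atten_tensor <- function(b, gdotv2, l_par, l_perp, K = 0) {
  adc <- l_perp + (l_par - l_perp) * gdotv2
  exp(-b * adc + b^2 / 6 * adc^2 * K)
}

atten_iso <- function(b, d, K = 0) exp(-b * d + b^2 / 6 * d^2 * K)

#' Build the synthetic phantom dataset and its ground truth
#'
#' Computes noise-free multi-compartment signals voxel by voxel (isotropic
#' ball + axially symmetric tensor per bundle, with a per-tissue kurtosis
#' term), then applies Rician noise at `spec$sigma`. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list(ds = [dwi_dataset()], truth = `phantom_truth` object). The
#'   truth records the tissue map, bundle masks and orientations, the
#'   clean (noise-free) data, per-tissue parameters, and empty artefact
#'   records (filled by [inject_artifacts()]).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- phantom_layout(spec)
  d <- spec$shape
  gtab <- spec$scheme$gtab
  nvol <- length(gtab$bvals)
  b <- gtab$bvals
  gv <- gtab$bvecs
  l_par <- spec$lambda_par
  l_perp <- spec$lambda_ratio * l_par
  Kwm <- spec$kurtosis[["wm"]]; Kgm <- spec$kurtosis[["gm"]]

  tissue <- lay$tissue
  f_iso <- array(0, d)
  f_iso[tissue == 1L] <- 1
  f_iso[tissue == 2L] <- spec$f_iso_gm
  f_iso[tissue == 3L] <- spec$f_iso_wm
  f_iso[lay$pv] <- spec$f_iso_pv
  S0map <- array(0, d)
  S0map[tissue == 1L] <- spec$S0[["csf"]]
  S0map[tissue == 2L] <- spec$S0[["gm"]]
  S0map[tissue == 3L] <- spec$S0[["wm"]]

  in_b1 <- lay$bundle1
  in_b2 <- if (spec$crossing) lay$bundle2 else array(FALSE, d)
  both <- in_b1 & in_b2
  # per-volume attenuation profiles of each compartment type
  a_csf <- atten_iso(b, spec$d_iso)
  a_gm <- atten_iso(b, spec$d_gm, Kgm)
  gdv1 <- (gv %*% lay$orient1)^2
  gdv2 <- (gv %*% lay$orient2)^2
  a_b1 <- atten_tensor(b, gdv1[, 1], l_par, l_perp, Kwm)
  a_b2 <- atten_tensor(b, gdv2[, 1], l_par, l_perp, Kwm)
  # diffuse WM outside the bundles: mildly anisotropic along z
  gdvz <- gv[, 3]^2
  a_wm0 <- atten_tensor(b, gdvz, l_par * 0.85, l_perp * 1.4, Kwm)

  nvox <- prod(d)
  clean <- matrix(0, nvox, nvol)
  ti <- as.integer(tissue)
  fi <- as.numeric(f_iso)
  # anisotropic part per voxel: pick the right compartment mix
  aniso <- matrix(0, nvox, nvol)
  idx_b1 <- which(as.logical(in_b1) & !as.logical(both))
  idx_b2 <- which(as.logical(in_b2) & !as.logical(both))
  idx_bo <- which(as.logical(both))
  idx_wm0 <- which(ti == 3L & !as.logical(in_b1) & !as.logical(in_b2))
  idx_gm <- which(ti == 2L)
  if (length(idx_b1)) aniso[idx_b1, ] <- matrix(a_b1, length(idx_b1), nvol,
                                                byrow = TRUE)
  if (length(idx_b2)) aniso[idx_b2, ] <- matrix(a_b2, length(idx_b2), nvol,
                                                byrow = TRUE)
  if (length(idx_bo)) aniso[idx_bo, ] <- matrix((a_b1 + a_b2) / 2,
                                                length(idx_bo), nvol,
                                                byrow = TRUE)
  if (length(idx_wm0)) aniso[idx_wm0, ] <- matrix(a_wm0, length(idx_wm0),
                                                  nvol, byrow = TRUE)
  if (length(idx_gm)) aniso[idx_gm, ] <- matrix(a_gm, length(idx_gm), nvol,
                                                byrow = TRUE)
  iso_part <- outer(fi, a_csf)
  csf_only <- ti == 1L
  iso_part[csf_only, ] <- outer(rep(1, sum(csf_only)), a_csf)
  sig <- (iso_part + (1 - fi) * aniso) * as.numeric(S0map)
  sig[ti == 0L, ] <- 0
  clean <- sig

  noisy <- clean
  if (spec$sigma > 0) {
    set.seed(spec$seed)
    n1 <- matrix(stats::rnorm(nvox * nvol, sd = spec$sigma), nvox, nvol)
    n2 <- matrix(stats::rnorm(nvox * nvol, sd = spec$sigma), nvox, nvol)
    noisy <- sqrt((clean + n1)^2 + n2^2)
  }
  arr <- array(noisy, c(d, nvol))
  affine <- diag(c(rep(spec$voxel, 3), 1))
  affine[1:3, 4] <- -(d - 1) / 2 * spec$voxel
  ds <- dwi_dataset(arr, affine, gtab, spec$scheme$acq,
                    slice_spacing = spec$voxel,
                    slice_thickness = spec$slice_thickness)
  orient <- array(0, c(d, 3))
  for (k in 1:3) {
    o <- array(0, d)
    o[in_b1] <- lay$orient1[k]
    o[in_b2 & !in_b1] <- lay$orient2[k]
    orient[, , , k] <- o
  }
  truth <- structure(list(
    spec = spec, tissue = tissue, f_iso = f_iso, S0 = S0map,
    bundle1 = in_b1, bundle2 = in_b2, orient1 = lay$orient1,
    orient2 = lay$orient2, orientation = orient, periventricular = lay$pv,
    brain_mask = tissue > 0L, wm_mask = tissue == 3L,
    gm_mask = tissue == 2L, csf_mask = tissue == 1L,
    clean = array(clean, c(d, nvol)),
    lambda_par = l_par, lambda_perp = l_perp,
    motion = matrix(0, nvol, 6,
                    dimnames = list(NULL, c("tx", "ty", "tz",
                                            "rx", "ry", "rz"))),
    dropout = data.frame(volume = integer(), slice = integer(),
                         factor = numeric()),
    spin_history = data.frame(volume = integer(), slice = integer(),
                              gain = numeric()),
    pe_field = array(0, d)
  ), class = "phantom_truth")
  list(ds = ds, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", paste(dim(x$tissue), collapse = " x "), "grid;",
      sum(x$wm_mask), "WM /", sum(x$gm_mask), "GM /", sum(x$csf_mask),
      "CSF voxels\n")
  cat("  artefacts: ", sum(rowSums(abs(x$motion)) > 0), " moved volumes, ",
      nrow(x$dropout), " dropout slices, ", nrow(x$spin_history),
      " spin-history slices\n", sep = "")
  invisible(x)
}

#' Inject scanner-realistic artefacts into a phantom dataset
#'
#' Applies, in order: per-volume rigid motion (resampling), phase-encode
#' displacement (translation along each volume's PE axis scaled by a
#' displacement field), multiplicative signal dropout (factor < 1) and
#' spin-history gain (factor > 1) on listed slices. Every injected artefact
#' is recorded in the returned truth.
#'
#' @param ds a [dwi_dataset()] from [build_phantom()].
#' @param truth the matching `phantom_truth`.
#' @param motion data.frame(volume, tx, ty, tz, rx, ry, rz); mm / radians.
#' @param dropout data.frame(volume, slice, factor), factor in (0, 1].
#' @param spin_history data.frame(volume, slice, gain), gain >= 1.
#' @param pe_field 3-D displacement field in mm applied along each
#'   volume's PE axis (sign follows the PE row's sign), or NULL.
#' @return list(ds, truth) with artefacts applied and recorded.
#' @export
inject_artifacts <- function(ds, truth, motion = NULL, dropout = NULL,
                             spin_history = NULL, pe_field = NULL) {
  stopifnot(inherits(ds, "dwi_dataset"), inherits(truth, "phantom_truth"))
  d <- dim(ds$data)[1:3]
  vox <- voxel_size(ds$affine)
  if (!is.null(motion) && nrow(motion)) {
    for (i in seq_len(nrow(motion))) {
      v <- motion$volume[i]
      p <- as.numeric(motion[i, c("tx", "ty", "tz", "rx", "ry", "rz")])
      ds$data[, , , v] <- rigid_resample(ds$data[, , , v], p, vox)
      truth$motion[v, ] <- truth$motion[v, ] + p
    }
  }
  if (!is.null(pe_field)) {
    if (!all(dim(pe_field) == d)) stop("pe_field grid mismatch")
    for (v in seq_len(dim(ds$data)[4])) {
      ax <- pe_axis(ds$acq, ds$gtab$pe_index[v])
      ds$data[, , , v] <- pe_shift(ds$data[, , , v], pe_field, ax$axis,
                                   vox[ax$axis], sign = ax$sign)
    }
    truth$pe_field <- pe_field
  }
  if (!is.null(dropout) && nrow(dropout)) {
    if (any(dropout$factor <= 0 | dropout$factor > 1))
      stop("dropout factors must lie in (0, 1]")
    for (i in seq_len(nrow(dropout)))
      ds$data[, , dropout$slice[i], dropout$volume[i]] <-
        ds$data[, , dropout$slice[i], dropout$volume[i]] * dropout$factor[i]
    truth$dropout <- rbind(truth$dropout, dropout)
  }
  if (!is.null(spin_history) && nrow(spin_history)) {
    if (any(spin_history$gain < 1))
      stop("spin-history gains must be >= 1")
    for (i in seq_len(nrow(spin_history)))
      ds$data[, , spin_history$slice[i], spin_history$volume[i]] <-
        ds$data[, , spin_history$slice[i], spin_history$volume[i]] *
        spin_history$gain[i]
    truth$spin_history <- rbind(truth$spin_history, spin_history)
  }
  list(ds = ds, truth = truth)
}

#' Simulate single voxels from a chosen microstructure forward model
#'
#' Generates an n-voxel dataset (n x 1 x 1 grid) from one of the signal
#' models the fitting modules estimate, with Rician noise at a given SNR
#' (defined as S0 / sigma). Used for parameter-recovery testing where the
#' generating model must match the fitted one.
#'
#' @param n number of voxels.
#' @param model "dki" (axially symmetric tensor + mean kurtosis), "noddi"
#'   (Bingham-dispersed sticks + tortuosity extra-neurite + free water) or
#'   "fibres" (ball + up to 3 sticks-with-kernel compartments, the
#'   deconvolution model).
#' @param params named list of model parameters; see Details.
#' @param scheme sampling scheme from [dhcp_scheme()].
#' @param snr S0-to-sigma ratio; Inf for noise-free.
#' @param S0 unweighted signal level.
#' @param seed RNG seed.
#' @details For "dki": `md` (mm^2/s), `fa_ratio` (lambda_perp/lambda_par),
#'   `K` (mean kurtosis), `dir` (fibre direction). For "noddi": `f_in`,
#'   `f_iso`, `odi` (or `kappa1`/`kappa2`), `mu`, `d_par`, `d_iso`. For
#'   "fibres": `fractions`, `dirs` (list of unit vectors), `f_iso`,
#'   `lambda_par`, `lambda_ratio`, `d_iso`.
#' @return list(ds = [dwi_dataset()], truth = list of the generating
#'   parameters, clean = clean signal matrix n x nvol).
#' @export
simulate_voxels <- function(n, model = c("dki", "noddi", "fibres"),
                            params = list(), scheme = dhcp_scheme(),
                            snr = 20, S0 = 1000, seed = 1L) {
  model <- match.arg(model)
  gtab <- scheme$gtab
  b <- gtab$bvals
  g <- gtab$bvecs
  nvol <- length(b)
  if (model == "dki") {
    p <- utils::modifyList(list(md = 1.0e-3, fa_ratio = 0.3, K = 0.6,
                                dir = c(1, 0, 0)), params)
    # md = (l_par + 2 l_perp)/3 with l_perp = ratio * l_par
    l_par <- 3 * p$md / (1 + 2 * p$fa_ratio)
    l_perp <- p$fa_ratio * l_par
    gd2 <- as.numeric((g %*% (p$dir / sqrt(sum(p$dir^2))))^2)
    sig <- S0 * atten_tensor(b, gd2, l_par, l_perp, p$K)
  } else if (model == "noddi") {
    p <- utils::modifyList(list(f_in = 0.5, f_iso = 0.1, odi = 0.2,
                                mu = c(1, 0, 0), d_par = 1.7e-3,
                                d_iso = 3.0e-3, grid_n = 500), params)
    if (is.null(p$kappa1)) p$kappa1 <- kappa_from_odi(p$odi)
    if (is.null(p$kappa2)) p$kappa2 <- p$kappa1
    grid <- sphere_points(p$grid_n)
    w <- bingham_weights(grid, p$mu, p$kappa1, p$kappa2)
    stick <- exp(-(b * p$d_par) * (g %*% t(grid))^2)
    intra <- as.numeric(stick %*% w)
    d_perp <- p$d_par * (1 - p$f_in)
    gd2 <- as.numeric((g %*% (p$mu / sqrt(sum(p$mu^2))))^2)
    extra <- exp(-b * (d_perp + (p$d_par - d_perp) * gd2))
    iso <- exp(-b * p$d_iso)
    sig <- S0 * (p$f_iso * iso +
                   (1 - p$f_iso) * (p$f_in * intra + (1 - p$f_in) * extra))
  } else {
    p <- list(fractions = 0.6, dirs = list(c(1, 0, 0)),
              f_iso = 0.1, lambda_par = 1.5e-3,
              lambda_ratio = 0.3, d_iso = 3.0e-3)
    p[names(params)] <- params
    if (!is.list(p$dirs)) p$dirs <- list(p$dirs)
    if (length(p$fractions) != length(p$dirs))
      stop("fractions and dirs lengths differ")
    if (p$f_iso + sum(p$fractions) > 1 + 1e-9)
      stop("compartment fractions exceed 1")
    l_par <- p$lambda_par
    l_perp <- p$lambda_ratio * l_par
    att <- p$f_iso * exp(-b * p$d_iso) +
      (1 - p$f_iso - sum(p$fractions)) * exp(-b * (l_par + 2 * l_perp) / 3)
    for (k in seq_along(p$dirs)) {
      v <- p$dirs[[k]] / sqrt(sum(p$dirs[[k]]^2))
      gd2 <- as.numeric((g %*% v)^2)
      att <- att + p$fractions[k] *
        exp(-b * l_par * (p$lambda_ratio + (1 - p$lambda_ratio) * gd2))
    }
    sig <- S0 * att
  }
  clean <- matrix(sig, n, nvol, byrow = TRUE)
  noisy <- clean
  if (is.finite(snr)) {
    sigma <- S0 / snr
    set.seed(seed)
    n1 <- matrix(stats::rnorm(n * nvol, sd = sigma), n, nvol)
    n2 <- matrix(stats::rnorm(n * nvol, sd = sigma), n, nvol)
    noisy <- sqrt((clean + n1)^2 + n2^2)
  }
  affine <- diag(c(2, 2, 2, 1))
  ds <- dwi_dataset(array(noisy, c(n, 1, 1, nvol)), affine, gtab,
                    scheme$acq)
  list(ds = ds, truth = p, clean = clean)
}

# Discrete slice-profile forward matrix mapping a high-resolution stack of
# n_high slices (spacing `voxel` mm) to thick slices of width `thickness`
# centred every `spacing` mm on the same origin. Rows are normalised so a
# constant volume is preserved.
slice_forward_matrix <- function(n_high, voxel, thickness, spacing,
                                 profile = "boxcar") {
  centres_out <- (seq_len(ceiling((n_high - 1) * voxel / spacing) + 1) - 1) *
    spacing
  centres_out <- centres_out[centres_out <= (n_high - 1) * voxel + 1e-9]
  z_high <- (seq_len(n_high) - 1) * voxel
  A <- matrix(0, length(centres_out), n_high)
  if (is.numeric(profile)) {
    if (abs(sum(profile) - 1) > 1e-6)
      stop("numeric slice profile must be normalised to sum 1")
    half <- (length(profile) - 1) / 2
    if (half != floor(half)) stop("numeric profile must have odd length")
    for (k in seq_along(centres_out)) {
      j0 <- round(centres_out[k] / voxel) + 1
      for (o in seq_along(profile)) {
        j <- j0 + o - 1 - half
        if (j >= 1 && j <= n_high) A[k, j] <- A[k, j] + profile[o]
      }
    }
  } else if (profile == "delta") {
    for (k in seq_along(centres_out))
      A[k, round(centres_out[k] / voxel) + 1] <- 1
  } else if (profile == "boxcar") {
    for (k in seq_along(centres_out)) {
      lo <- centres_out[k] - thickness / 2
      hi <- centres_out[k] + thickness / 2
      ov <- pmax(0, pmin(hi, z_high + voxel / 2) - pmax(lo, z_high - voxel / 2))
      A[k, ] <- ov
    }
  } else if (profile == "gaussian") {
    sdv <- thickness / (2 * sqrt(2 * log(2)))  # FWHM = thickness
    for (k in seq_along(centres_out))
      A[k, ] <- stats::dnorm(z_high, centres_out[k], sdv)
  } else stop("unknown slice profile: ", profile)
  sums <- rowSums(A)
  A / sums
}

#' Sample thick overlapping slices from a high-resolution volume
#'
#' The forward model of the super-resolution problem: each output slice is
#' the profile-weighted integral of the high-resolution volume along z,
#' centred every `spacing` mm. With `thickness = spacing` and a delta
#' profile this is the identity.
#'
#' @param highres 3-D array on an isotropic grid.
#' @param thickness slice thickness in mm (boxcar width / Gaussian FWHM).
#' @param spacing slice spacing in mm.
#' @param profile "boxcar" (default), "gaussian", "delta", or a normalised
#'   numeric kernel over neighbouring high-resolution slices.
#' @param voxel through-plane voxel size of `highres` in mm.
#' @return 3-D array of thick slices (same in-plane grid).
#' @export
sample_thick_slices <- function(highres, thickness, spacing,
                                profile = "boxcar", voxel = spacing) {
  stopifnot(thickness >= spacing)
  d <- dim(highres)
  A <- slice_forward_matrix(d[3], voxel, thickness, spacing, profile)
  m <- matrix(aperm(highres, c(3, 1, 2)), d[3], d[1] * d[2])
  out <- A %*% m
  aperm(array(out, c(nrow(A), d[1], d[2])), c(2, 3, 1))
}
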