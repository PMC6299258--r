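#' Warp a mask through a dense displacement field
#'
#' Nearest-neighbour resampling of a binary mask through a displacement
#' field: the output at voxel x takes the mask value at `x - w(x)` (the
#' field moves template content by +w, in mm).
#'
#' @param mask logical 3-D array on the template grid.
#' @param warp 4-D array (x, y, z, 3) of displacements in mm, on the same
#'   grid.
#' @param voxel voxel size (mm, length 3 or scalar).
#' @return logical 3-D array.
#' @export
warp_mask <- function(mask, warp, voxel = c(1.5, 1.5, 1.5)) {
  d <- dim(mask)
  if (!all(dim(warp)[1:3] == d) || dim(warp)[4] != 3)
    stop("warp grid does not match the mask grid")
  voxel <- rep_len(voxel, 3)
  g <- voxel_grid(d)
  w <- matrix(warp, prod(d), 3)
  src <- g - sweep(w, 2, voxel, `/`)
  src <- round(src)
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] &
    src[, 2] >= 1 & src[, 2] <= d[2] &
    src[, 3] >= 1 & src[, 3] <= d[3]
  out <- rep(FALSE, prod(d))
  idx <- ((src[ok, 3] - 1) * d[2] + (src[ok, 2] - 1)) * d[1] + src[ok, 1]
  out[ok] <- mask[idx]
  array(out, d)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the inverse of a smooth displacement field
#' under the backward-sampling convention of [warp_mask()]
#' (`out(x) = in(x - w(x))`): the inverse satisfies
#' `w_inv(x) = -w(x - w_inv(x))`.
#'
#' @param warp 4-D displacement array (mm).
#' @param voxel voxel size in mm.
#' @param n_iter fixed-point iterations (default 20).
#' @return 4-D displacement array of the inverse.
#' @export
warp_invert <- function(warp, voxel = c(1.5, 1.5, 1.5), n_iter = 20) {
  d <- dim(warp)[1:3]
  voxel <- rep_len(voxel, 3)
  g <- voxel_grid(d)
  inv <- array(0, dim(warp))
  wm <- lapply(1:3, function(k) warp[, , , k])
  im <- matrix(0, prod(d), 3)
  for (it in seq_len(n_iter)) {
    pos <- g - sweep(im, 2, voxel, `/`)
    for (k in 1:3) im[, k] <- -interp3(wm[[k]], pos)
  }
  for (k in 1:3) inv[, , , k] <- array(im[, k], d)
  inv
}

#' Probabilistic tractography under a tract protocol
#'
#' Launches `n_samples` bidirectional streamlines from every seed voxel.
#' At each step a fibre compartment is drawn among the surviving fibres of
#' the current voxel (probability proportional to posterior mean
#' fraction), an orientation sample of that fibre is drawn, and the
#' streamline advances by `step_mm`. A streamline terminates on leaving
#' the fitted mask or grid, on curvature above the threshold, on entering
#' a stop mask, or at `max_steps`. It is successful iff it visits every
#' waypoint mask and never enters an exclusion mask; visitation counts
#' accumulate only for successful streamlines.
#'
#' @param fodfit a [fit_fod()] / [fod_from_truth()] object in subject
#'   space.
#' @param protocol a `tract_protocol` (single-hemisphere mask set) whose
#'   masks are already in subject space ([warp_mask()]).
#' @param n_samples streamlines per seed voxel (default 1000).
#' @param step_mm step length in mm (default 0.75).
#' @param cos_thresh curvature threshold: minimum cosine between
#'   successive steps (default 0.2).
#' @param max_steps per half-streamline step cap (default 2000).
#' @param seed RNG seed; tracking is deterministic given it.
#' @return object of class `tract_map`: `counts` (visitation volume over
#'   successful streamlines), `seeded`, `successful`, `prob`
#'   (counts / successful), the protocol name and tracking parameters.
#' @export
track <- function(fodfit, protocol, n_samples = 1000, step_mm = 0.75,
                  cos_thresh = 0.2, max_steps = 2000, seed = 1L) {
  stopifnot(inherits(fodfit, "fod_fit"))
  masks <- if (!is.null(protocol$masks)) protocol$masks else
    stop("protocol '", protocol$name,
         "' is bilateral; track each hemisphere mask set separately")
  d <- fodfit$dim
  if (!all(dim(masks$seed) == d)) stop("mask grid mismatch")
  seeds <- which(masks$seed)
  if (!length(seeds))
    stop("empty (warped) seed mask for tract '", protocol$name, "'")
  voxel <- rep_len(fodfit$voxel_size, 3)
  idx_map <- array(0L, d)
  idx_map[fodfit$voxel_index] <- seq_along(fodfit$voxel_index)
  thr <- fodfit$survival_threshold
  # precompute surviving fibres per fitted voxel
  fibres <- lapply(fodfit$voxels, function(vx) {
    if (is.null(vx)) return(NULL)
    keep <- which(vx$f >= thr)
    if (!length(keep)) return(NULL)
    list(f = vx$f[keep],
         samples = lapply(keep, function(k) vx$v_samples[[k]]))
  })
  n_way <- length(masks$waypoint)
  counts <- array(0, d)
  set.seed(seed)
  seeded <- 0L; successful <- 0L
  seed_ijk <- arrayInd(seeds, d)
  vstep <- step_mm / voxel
  for (si in seq_len(nrow(seed_ijk))) {
    for (s in seq_len(n_samples)) {
      seeded <- seeded + 1L
      p0 <- seed_ijk[si, ] + stats::runif(3, -0.5, 0.5)
      v0 <- round(p0)
      if (masks$exclusion[v0[1], v0[2], v0[3]]) next
      visited <- matrix(0L, 2 * max_steps + 1, 3)
      visited[1, ] <- v0
      n_vis <- 1L
      way_hit <- logical(n_way)
      for (w in seq_len(n_way))
        if (masks$waypoint[[w]][v0[1], v0[2], v0[3]]) way_hit[w] <- TRUE
      rejected <- FALSE
      if (!masks$stop[v0[1], v0[2], v0[3]]) {
        fid0 <- idx_map[v0[1], v0[2], v0[3]]
        fb0 <- if (fid0 > 0) fibres[[fid0]] else NULL
        if (!is.null(fb0)) {
          k0 <- if (length(fb0$f) == 1) 1L else
            sample.int(length(fb0$f), 1, prob = fb0$f)
          vs <- fb0$samples[[k0]]
          dir0 <- vs[sample.int(nrow(vs), 1), ]
          for (sgn in c(1, -1)) {
            pos <- p0
            dir <- dir0 * sgn
            for (st in seq_len(max_steps)) {
              pos <- pos + dir * vstep
              vv <- round(pos)
              if (any(vv < 1) || any(vv > d)) break
              if (masks$exclusion[vv[1], vv[2], vv[3]]) {
                rejected <- TRUE
                break
              }
              n_vis <- n_vis + 1L
              visited[n_vis, ] <- vv
              for (w in seq_len(n_way))
                if (!way_hit[w] &&
                    masks$waypoint[[w]][vv[1], vv[2], vv[3]])
                  way_hit[w] <- TRUE
              if (masks$stop[vv[1], vv[2], vv[3]]) break
              fid <- idx_map[vv[1], vv[2], vv[3]]
              if (fid == 0 || is.null(fibres[[fid]])) break
              fb <- fibres[[fid]]
              # draw a compartment aligned with the incoming direction
              k <- if (length(fb$f) == 1) 1L else
                sample.int(length(fb$f), 1, prob = fb$f)
              vs <- fb$samples[[k]]
              nd <- vs[sample.int(nrow(vs), 1), ]
              if (sum(nd * dir) < 0) nd <- -nd
              if (sum(nd * dir) < cos_thresh) break
              dir <- nd
            }
            if (rejected) break
          }
        }
      }
      if (!rejected && all(way_hit)) {
        successful <- successful + 1L
        uv <- unique(visited[seq_len(n_vis), , drop = FALSE])
        counts[uv] <- counts[uv] + 1
      }
    }
  }
  prob <- if (successful > 0) counts / successful else counts
  structure(list(counts = counts, seeded = seeded,
                 successful = successful, prob = prob,
                 name = protocol$name,
                 params = list(n_samples = n_samples, step_mm = step_mm,
                               cos_thresh = cos_thresh,
                               max_steps = max_steps, seed = seed)),
            class = "tract_map")
}

#' @export
print.tract_map <- function(x, ...) {
  cat("tract_map '", x$name, "': ", x$successful, "/", x$seeded,
      " successful streamlines, support ",
      sum(x$counts > 0), " voxels\n", sep = "")
  invisible(x)
}

#' Normalise and threshold a tract visitation map
#'
#' @param tmap a [track()] result.
#' @param thresholds probability thresholds for display maps
#'   (default c(0.005, 0.05)).
#' @param binarise_at threshold for the binary tract mask used in metric
#'   extraction (default 0.01).
#' @return list(prob, thresholded = named list of probability maps with
#'   sub-threshold voxels zeroed, mask = binary array at `binarise_at`).
#'   With zero successful streamlines all outputs are empty (warning).
#' @export
normalise_threshold <- function(tmap, thresholds = c(0.005, 0.05),
                                binarise_at = 0.01) {
  stopifnot(inherits(tmap, "tract_map"))
  if (tmap$successful == 0) {
    warning("tract '", tmap$name, "': no successful streamlines")
    z <- tmap$counts * 0
    return(list(prob = z,
                thresholded = stats::setNames(
                  rep(list(z), length(thresholds)),
                  paste0("thr_", thresholds)),
                mask = z > 0))
  }
  prob <- tmap$counts / tmap$successful
  th <- lapply(thresholds, function(t) prob * (prob >= t))
  list(prob = prob,
       thresholded = stats::setNames(th, paste0("thr_", thresholds)),
       mask = prob >= binarise_at)
}

#' Voxel-wise average of tract probability maps
#'
#' @param maps list of probability arrays on a common (template) grid.
#' @return the arithmetic-mean array.
#' @export
group_average <- function(maps) {
  d <- dim(maps[[1]])
  for (m in maps) if (!all(dim(m) == d)) stop("grid mismatch")
  Reduce(`+`, maps) / length(maps)
}

#' Tract-wise regression of microstructural metrics on age
#'
#' Per tract: the mean scalar metric within the binarised tract mask is
#' computed per subject and regressed on de-meaned age at scan with
#' de-meaned total brain volume as a covariate (ordinary least squares).
#' The age slope is normalised by the tract-averaged metric across
#' subjects; the intercept is the predicted metric at the mean age.
#' p-values for the age effect are Bonferroni-corrected across tracts.
#'
#' @param metric_maps list (per subject) of 3-D scalar arrays on the
#'   template grid.
#' @param tract_masks named list of logical tract masks on the same grid.
#' @param ages numeric vector of ages at scan (weeks), one per subject.
#' @param brain_volumes numeric vector of total brain volumes.
#' @param alpha significance level after correction (default 0.05).
#' @return data.frame with one row per tract: `tract`, `mean_metric`,
#'   `beta_age` (raw slope per week), `beta_age_norm` (slope / mean
#'   metric), `beta0` (value at mean age), `p`, `p_corrected`,
#'   `significant`.
#' @export
tract_metric_regression <- function(metric_maps, tract_masks, ages,
                                    brain_volumes, alpha = 0.05) {
  n <- length(metric_maps)
  if (n < 3) stop("need at least 3 subjects")
  stopifnot(length(ages) == n, length(brain_volumes) == n)
  age_c <- ages - mean(ages)
  vol_c <- brain_volumes - mean(brain_volumes)
  X <- cbind(1, age_c, vol_c)
  if (qr(X)$rank < 3) stop("rank-deficient design (collinear covariates)")
  rows <- lapply(names(tract_masks), function(tn) {
    m <- tract_masks[[tn]]
    y <- vapply(metric_maps, function(mm) mean(mm[m], na.rm = TRUE),
                numeric(1))
    fit <- stats::lm(y ~ age_c + vol_c)
    sm <- summary(fit)$coefficients
    data.frame(tract = tn, mean_metric = mean(y),
               beta_age = unname(stats::coef(fit)["age_c"]),
               beta_age_norm = unname(stats::coef(fit)["age_c"]) / mean(y),
               beta0 = unname(stats::coef(fit)["(Intercept)"]),
               p = sm["age_c", "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- stats::p.adjust(out$p, method = "bonferroni")
  out$significant <- out$p_corrected < alpha
  out
}
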