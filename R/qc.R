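#' Data-import gate
#'
#' A session is processed only when at least `minimum` of the
#' `protocol_total` expected volumes were acquired (34 of 300, i.e.
#' 11.3%): that is the smallest count guaranteeing a reversed-PE b0 pair
#' for field estimation.
#'
#' @param n_acquired number of acquired volumes.
#' @param protocol_total expected volume count (default 300).
#' @param minimum minimum acceptable count (default 34).
#' @return list(pass, pct, n_acquired, minimum).
#' @export
import_gate <- function(n_acquired, protocol_total = 300, minimum = 34) {
  stopifnot(n_acquired >= 0)
  list(pass = n_acquired >= minimum,
       pct = 100 * n_acquired / protocol_total,
       n_acquired = as.integer(n_acquired),
       minimum = as.integer(minimum))
}

#' Absolute and relative motion summaries from a motion trace
#'
#' Per volume, displacement is the RMS over in-mask voxel centres of the
#' distance each voxel moves under the volume's rigid transform —
#' relative to the reference volume (absolute motion) or to the previous
#' volume (relative motion). The reported values are averages over
#' volumes (the reference's zero row included).
#'
#' @param trace a `motion_trace` from [realign_volumes()].
#' @param mask 3-D logical array defining the voxel support.
#' @param voxel voxel size in mm.
#' @return list(abs_motion, rel_motion, per_volume = data.frame).
#' @export
motion_metrics <- function(trace, mask, voxel = c(1.5, 1.5, 1.5)) {
  stopifnot(inherits(trace, "motion_trace"))
  if (is.null(attr(trace, "reference")))
    stop("trace has no reference volume")
  d <- dim(mask)
  voxel <- rep_len(voxel, 3)
  centre <- (d - 1) / 2 * voxel
  pts <- voxel_grid(d)[as.logical(mask), , drop = FALSE]
  pts <- sweep(pts - 1, 2, voxel, `*`)
  n <- nrow(trace)
  rms_disp <- function(p_from, p_to) {
    # displacement field of going from transform p_from to p_to
    M <- rigid_matrix(p_to, centre) %*% solve(rigid_matrix(p_from, centre))
    moved <- pts %*% t(M[1:3, 1:3]) +
      matrix(M[1:3, 4], nrow(pts), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - pts)^2)))
  }
  zero <- rep(0, 6)
  abs_v <- vapply(seq_len(n), function(v)
    rms_disp(zero, as.numeric(trace[v, ])), numeric(1))
  rel_v <- c(0, vapply(seq_len(n)[-1], function(v)
    rms_disp(as.numeric(trace[v - 1, ]), as.numeric(trace[v, ])),
    numeric(1)))
  list(abs_motion = mean(abs_v), rel_motion = mean(rel_v),
       per_volume = data.frame(volume = seq_len(n), abs_mm = abs_v,
                               rel_mm = rel_v))
}

#' Outlier-slice percentages, stratified
#'
#' Total percentage of flagged slices among scored slices, the same ratio
#' within each b-shell, PE direction and volume, and a per-slice-position
#' flag count (to reveal stationary spatial inconsistencies).
#'
#' @param table an `outlier_table` from [detect_replace_outliers()].
#' @param gtab the dataset's [gradient_table()].
#' @return list(total_pct, per_shell_pct, per_pe_pct, per_volume_pct,
#'   per_slice_count, n_scored, n_flagged).
#' @export
outlier_stats <- function(table, gtab) {
  stopifnot(inherits(table, "outlier_table"))
  n_scored <- nrow(table)
  n_flagged <- sum(table$flagged)
  shell <- gtab$shell[table$volume]
  pe <- gtab$pe_index[table$volume]
  pct <- function(f) 100 * vapply(split(table$flagged, f), mean,
                                  numeric(1))
  per_slice <- vapply(split(table$flagged, table$slice), sum, numeric(1))
  list(total_pct = 100 * n_flagged / n_scored,
       per_shell_pct = pct(shell),
       per_pe_pct = pct(pe),
       per_volume_pct = pct(table$volume),
       per_slice_count = per_slice,
       n_scored = n_scored, n_flagged = n_flagged)
}

#' Prediction-based CNR and SNR
#'
#' Per shell, voxel-wise CNR is the standard deviation of the predicted
#' signals across that shell's volumes divided by the standard deviation
#' of the residuals (observed minus predicted); SNR uses only the b0
#' volumes as mean predicted over residual standard deviation. Voxel
#' values are averaged within the white-matter mask (CNR, SNR) and the
#' grey-matter mask (SNR). Degenerate denominators yield NULL entries
#' with a reason rather than infinities.
#'
#' @param predictions 4-D array from [predict_signal()].
#' @param data the observed 4-D array (same dims).
#' @param wm_mask,gm_mask logical 3-D arrays.
#' @param gtab the [gradient_table()].
#' @return list(cnr_wm = named per-shell averages, snr_wm, snr_gm,
#'   wm_sq_residuals, nulls = named character vector of reasons for any
#'   missing metric).
#' @export
cnr_snr <- function(predictions, data, wm_mask, gm_mask, gtab) {
  stopifnot(all(dim(predictions) == dim(data)))
  d <- dim(data)
  nvox <- prod(d[1:3])
  pm <- matrix(predictions, nvox, d[4])
  dm <- matrix(data, nvox, d[4])
  wm <- as.logical(wm_mask); gm <- as.logical(gm_mask)
  nulls <- character(0)
  shells <- shell_indices(gtab)
  row_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(pmax(rowMeans(m^2) - mu^2, 0) * ncol(m) / max(1, ncol(m) - 1))
  }
  cnr_wm <- list()
  for (sh in setdiff(names(shells), "0")) {
    ii <- shells[[sh]]
    sd_pred <- row_sd(pm[, ii, drop = FALSE])
    sd_res <- row_sd(dm[, ii, drop = FALSE] - pm[, ii, drop = FALSE])
    bad <- sd_res == 0
    if (all(bad[wm])) {
      cnr_wm[[sh]] <- NULL
      nulls[paste0("cnr_wm_b", sh)] <- "zero residual sd"
      next
    }
    v <- sd_pred / sd_res
    cnr_wm[[sh]] <- mean(v[wm & !bad])
  }
  b0s <- shells[["0"]]
  snr_wm <- snr_gm <- NULL
  if (is.null(b0s) || length(b0s) < 2) {
    nulls["snr"] <- "fewer than two b0 volumes"
  } else {
    mu_pred <- rowMeans(pm[, b0s, drop = FALSE])
    sd_res <- row_sd(dm[, b0s, drop = FALSE] - pm[, b0s, drop = FALSE])
    bad <- sd_res == 0
    if (all(bad[wm | gm])) {
      nulls["snr"] <- "zero residual sd"
    } else {
      snr <- mu_pred / sd_res
      snr_wm <- mean(snr[wm & !bad])
      snr_gm <- mean(snr[gm & !bad])
    }
  }
  res_wm <- mean((dm[wm, , drop = FALSE] - pm[wm, , drop = FALSE])^2)
  list(cnr_wm = cnr_wm, snr_wm = snr_wm, snr_gm = snr_gm,
       wm_sq_residuals = res_wm, nulls = nulls)
}

#' Registration quality: b0-to-anatomy correlation
#'
#' Pearson correlation within the brain mask between the (registered)
#' mean b0 volume and a T2-weighted anatomical volume on the same grid.
#'
#' @param mean_b0,t2_volume 3-D arrays on a common grid.
#' @param mask logical 3-D array.
#' @return correlation value, or NULL (with attribute "reason") when an
#'   input is constant within the mask.
#' @export
registration_qc <- function(mean_b0, t2_volume, mask) {
  stopifnot(all(dim(mean_b0) == dim(t2_volume)))
  a <- mean_b0[as.logical(mask)]
  b <- t2_volume[as.logical(mask)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(list(NULL), reason = "constant image")[[1]])
  stats::cor(a, b)
}

#' Assemble the quality-control report
#'
#' Collects the import gate, motion, outlier, CNR/SNR and registration
#' metrics into a single machine-readable report, serialisable to JSON;
#' optionally writes the two image-type summary entries (per-shell mean
#' signal, WM/GM boundary overlay) as PNGs next to it. Missing stages are
#' recorded as null with a reason, so a report is always produced.
#'
#' @param gate [import_gate()] output.
#' @param motion [motion_metrics()] output or NULL.
#' @param outliers [outlier_stats()] output or NULL.
#' @param cnr [cnr_snr()] output or NULL.
#' @param t2_correlation [registration_qc()] output or NULL.
#' @param provenance named list (seeds, versions, config hashes).
#' @param ds optional [dwi_dataset()] for the per-shell mean-signal image.
#' @param wm_mask,gm_mask optional masks for the boundary image.
#' @param out_dir if non-NULL, write `qc_report.json` and PNGs there.
#' @return object of class `qc_report` (a named list).
#' @export
assemble_report <- function(gate, motion = NULL, outliers = NULL,
                            cnr = NULL, t2_correlation = NULL,
                            provenance = list(), ds = NULL,
                            wm_mask = NULL, gm_mask = NULL,
                            out_dir = NULL) {
  null_reason <- function(x, reason) {
    if (is.null(x)) list(value = NULL, reason = reason) else x
  }
  rep <- list(
    schema_version = "1.0",
    acquired_volumes_pct = gate$pct,
    import_gate_pass = gate$pass,
    abs_motion_mm = if (is.null(motion)) NULL else motion$abs_motion,
    rel_motion_mm = if (is.null(motion)) NULL else motion$rel_motion,
    outlier_pct = if (is.null(outliers)) NULL else list(
      total = outliers$total_pct,
      per_shell = as.list(outliers$per_shell_pct),
      per_pe = as.list(outliers$per_pe_pct),
      per_volume = as.list(outliers$per_volume_pct),
      per_slice_count = as.list(outliers$per_slice_count)),
    cnr_wm = if (is.null(cnr)) NULL else cnr$cnr_wm,
    snr_wm = if (is.null(cnr)) NULL else cnr$snr_wm,
    snr_gm = if (is.null(cnr)) NULL else cnr$snr_gm,
    wm_sq_residuals = if (is.null(cnr)) NULL else cnr$wm_sq_residuals,
    t2_b0_correlation = t2_correlation,
    nulls = c(
      if (!gate$pass) c(stage = "import gate failed; later stages skipped"),
      if (is.null(motion)) c(motion = "stage not run"),
      if (is.null(outliers)) c(outliers = "stage not run"),
      if (is.null(cnr)) c(cnr_snr = "stage not run") else cnr$nulls,
      if (is.null(t2_correlation)) c(registration = "stage not run")),
    provenance = provenance)
  # NaN -> null with reason, keeps the report machine-comparable
  scrub <- function(x) {
    if (is.list(x)) return(lapply(x, scrub))
    if (is.numeric(x) && length(x) == 1 && !is.finite(x)) return(NULL)
    x
  }
  rep <- scrub(rep)
  rep <- structure(rep, class = "qc_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(rep),
                         file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    if (!is.null(ds)) qc_images(ds, wm_mask, gm_mask, out_dir)
  }
  rep
}

# The two image-type report entries: per-shell mean signal profile and a
# WM/GM boundary overlay on the mean b0.
qc_images <- function(ds, wm_mask, gm_mask, out_dir) {
  shells <- shell_indices(ds$gtab)
  grDevices::png(file.path(out_dir, "shell_mean_signal.png"),
                 width = 250 * length(shells), height = 300)
  graphics::par(mfrow = c(1, length(shells)), mar = c(1, 1, 2, 1))
  zmid <- ceiling(dim(ds$data)[3] / 2)
  for (sh in names(shells)) {
    m <- volume_mean(ds$data, shells[[sh]])
    graphics::image(m[, , zmid], col = grDevices::gray.colors(128),
                    axes = FALSE, main = paste0("b=", sh))
  }
  grDevices::dev.off()
  if (!is.null(wm_mask) && !is.null(gm_mask)) {
    grDevices::png(file.path(out_dir, "wm_gm_boundary.png"),
                   width = 300, height = 300)
    graphics::par(mar = c(1, 1, 2, 1))
    b0 <- volume_mean(ds$data, which(ds$gtab$b0))
    graphics::image(b0[, , zmid], col = grDevices::gray.colors(128),
                    axes = FALSE, main = "WM/GM boundary")
    graphics::contour(wm_mask[, , zmid] * 1, levels = 0.5, add = TRUE,
                      col = "green", drawlabels = FALSE)
    graphics::contour(gm_mask[, , zmid] * 1, levels = 0.5, add = TRUE,
                      col = "cyan", drawlabels = FALSE)
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: acquired", signif(x$acquired_volumes_pct, 4),
      "% — gate", if (isTRUE(x$import_gate_pass)) "PASS" else "FAIL", "\n")
  if (!is.null(x$abs_motion_mm))
    cat("  motion: abs", signif(x$abs_motion_mm, 3), "mm, rel",
        signif(x$rel_motion_mm, 3), "mm\n")
  if (!is.null(x$outlier_pct))
    cat("  outliers:", signif(x$outlier_pct$total, 3), "% total\n")
  if (!is.null(x$snr_wm))
    cat("  SNR (WM):", signif(x$snr_wm, 3),
        " SNR (GM):", signif(x$snr_gm, 3), "\n")
  invisible(x)
}
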