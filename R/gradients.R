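#' Gradient table for a multi-shell diffusion acquisition
#'
#' Bundles the per-volume diffusion weighting (b-value), unit encoding
#' direction (image-axis frame, FSL convention) and the phase-encode row
#' index into the acquisition-parameter table. Volumes with
#' `b <= b0_threshold` are treated as unweighted (b0) references and their
#' direction is stored as the zero vector.
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs numeric matrix, `length(bvals)` rows by 3 columns, of
#'   diffusion encoding directions. Rows for b0 volumes may be zero; all
#'   other rows are normalised to unit length (an error is raised if a
#'   weighted row is further than `tol` from unit norm).
#' @param pe_index integer vector of 1-based row indices into the
#'   acquisition-parameter table, one per volume.
#' @param b0_threshold b-values at or below this are flagged b0
#'   (default 50 s/mm^2, conventional).
#' @param tol tolerance on the norm of a weighted b-vector before it is
#'   rejected rather than renormalised.
#' @return An object of class `gradient_table`: a list with elements
#'   `bvals`, `bvecs`, `pe_index`, `b0` (logical), `shell` (nominal
#'   b-value per volume, 0 for b0s).
#' @export
gradient_table <- function(bvals, bvecs, pe_index = rep(1L, length(bvals)),
                           b0_threshold = 50, tol = 1e-2) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns (one direction per row)")
  if (nrow(bvecs) != length(bvals))
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") describe different numbers of volumes")
  if (length(pe_index) != length(bvals))
    stop("pe_index length does not match the number of volumes")
  if (any(bvals < 0)) stop("negative b-values are not physical")
  is_b0 <- bvals <= b0_threshold
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- !is_b0 & abs(nrm - 1) > tol & nrm > 0
  if (any(bad))
    stop("non-unit b-vector (|g| = ", signif(nrm[which(bad)[1]], 4),
         ") on weighted volume ", which(bad)[1])
  zero_dwi <- !is_b0 & nrm == 0
  if (any(zero_dwi))
    stop("zero b-vector on weighted volume ", which(zero_dwi)[1])
  bvecs[!is_b0, ] <- bvecs[!is_b0, , drop = FALSE] / nrm[!is_b0]
  bvecs[is_b0, ] <- 0
  structure(list(
    bvals = bvals,
    bvecs = unname(bvecs),
    pe_index = as.integer(pe_index),
    b0 = is_b0,
    b0_threshold = b0_threshold,
    shell = nominal_shells(bvals, is_b0)
  ), class = "gradient_table")
}

# Nominal shell per volume: b0s get 0; weighted b-values are grouped by
# rounding to the nearest 50 s/mm^2 so that small per-volume deviations
# still land on the intended shell.
nominal_shells <- function(bvals, is_b0) {
  shell <- round(bvals / 50) * 50
  shell[is_b0] <- 0
  shell
}

#' Group the volumes of a gradient table by shell
#'
#' @param gtab a `gradient_table`.
#' @return Named list of integer volume-index vectors, one per nominal
#'   b-value ("0" holds the b0 volumes). The groups partition the volumes.
#' @export
shell_indices <- function(gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  split(seq_along(gtab$bvals), gtab$shell)
}

#' @export
print.gradient_table <- function(x, ...) {
  sh <- table(x$shell)
  cat("Gradient table:", length(x$bvals), "volumes,",
      sum(x$b0), "b0s\n")
  cat("  shells (s/mm^2):",
      paste(sprintf("b=%s n=%d", names(sh), as.integer(sh)),
            collapse = ", "), "\n")
  cat("  PE rows used:", paste(sort(unique(x$pe_index)), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Rotate the b-vectors of a gradient table
#'
#' Applies a rotation per volume (e.g. the rotation component of an
#' estimated rigid-body motion correction) to the stored encoding
#' directions. b0 rows are left as zero vectors. Rotation preserves vector
#' norms, so b-values are untouched.
#'
#' @param gtab a `gradient_table`.
#' @param rotations either a single 3x3 rotation matrix applied to every
#'   volume, or a list of per-volume 3x3 matrices.
#' @return The rotated `gradient_table`.
#' @export
rotate_bvecs <- function(gtab, rotations) {
  stopifnot(inherits(gtab, "gradient_table"))
  n <- length(gtab$bvals)
  if (is.matrix(rotations)) rotations <- rep(list(rotations), n)
  if (length(rotations) != n)
    stop("need one rotation per volume")
  for (i in seq_len(n)) {
    if (!gtab$b0[i])
      gtab$bvecs[i, ] <- as.numeric(rotations[[i]] %*% gtab$bvecs[i, ])
  }
  gtab
}

#' Acquisition-parameter table for phase-encoding rows
#'
#' Each row gives the signed phase-encode axis and the EPI readout time for
#' one acquisition configuration; volumes reference rows through
#' `pe_index` of the gradient table.
#'
#' @param pe_vectors numeric matrix, rows of signed unit axis vectors
#'   (each must be plus or minus a coordinate axis).
#' @param readout_times positive readout times in seconds (recycled).
#' @return data.frame of class `acq_params` with columns pe_x, pe_y, pe_z,
#'   readout.
#' @export
acq_params <- function(pe_vectors, readout_times = 0.05) {
  pe_vectors <- as.matrix(pe_vectors)
  if (ncol(pe_vectors) != 3L) stop("pe_vectors must have 3 columns")
  ok <- apply(pe_vectors, 1, function(v)
    sum(abs(v) > 0) == 1 && all(abs(v[abs(v) > 0]) == 1))
  if (!all(ok))
    stop("phase-encode vector in row ", which(!ok)[1],
         " is not a signed coordinate axis")
  readout_times <- rep_len(as.numeric(readout_times), nrow(pe_vectors))
  if (any(readout_times <= 0)) stop("readout times must be positive")
  structure(data.frame(pe_x = pe_vectors[, 1], pe_y = pe_vectors[, 2],
                       pe_z = pe_vectors[, 3], readout = readout_times),
            class = c("acq_params", "data.frame"))
}

# The PE axis (1, 2 or 3) and sign of one acqparams row.
pe_axis <- function(acq, row) {
  v <- as.numeric(acq[row, c("pe_x", "pe_y", "pe_z")])
  ax <- which(abs(v) > 0)
  list(axis = ax, sign = sign(v[ax]), vector = v)
}
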