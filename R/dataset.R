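#' A 4-D diffusion MRI dataset
#'
#' The container every pipeline stage consumes and produces: the intensity
#' grid, the voxel-to-world affine, the gradient table, the
#' acquisition-parameter table and the slice geometry of the acquisition.
#'
#' @param data 4-D numeric array (x, y, z, volume), non-negative.
#' @param affine 4x4 voxel-to-world (mm) matrix. Voxel indices are 0-based
#'   in the affine convention (NIfTI); R arrays are accessed 1-based.
#' @param gtab a [gradient_table()] whose length matches `dim(data)[4]`.
#' @param acq an [acq_params()] table; every `pe_index` of `gtab` must
#'   reference one of its rows.
#' @param slice_spacing through-plane slice spacing in mm.
#' @param slice_thickness excited slice thickness in mm (>= spacing;
#'   overlapping slices when strictly greater).
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(data, affine, gtab, acq,
                        slice_spacing = NULL, slice_thickness = NULL) {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 4-D array")
  if (min(data) < 0) stop("negative intensities in data")
  stopifnot(inherits(gtab, "gradient_table"), inherits(acq, "acq_params"))
  if (dim(data)[4] != length(gtab$bvals))
    stop("grid has ", dim(data)[4], " volumes but gradient table describes ",
         length(gtab$bvals))
  if (any(gtab$pe_index < 1L | gtab$pe_index > nrow(acq)))
    stop("pe_index references a row outside the acquisition-parameter table")
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  vox <- voxel_size(affine)
  if (is.null(slice_spacing)) slice_spacing <- vox[3]
  if (is.null(slice_thickness)) slice_thickness <- slice_spacing
  if (slice_thickness < slice_spacing)
    stop("slice thickness (", slice_thickness,
         " mm) below slice spacing (", slice_spacing, " mm)")
  structure(list(data = data, affine = unname(affine), gtab = gtab,
                 acq = acq, slice_spacing = slice_spacing,
                 slice_thickness = slice_thickness),
            class = "dwi_dataset")
}

voxel_size <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("dwi_dataset:", paste(d[1:3], collapse = " x "), "grid,",
      d[4], "volumes\n")
  cat("  voxel size (mm):",
      paste(signif(voxel_size(x$affine), 4), collapse = " x "),
      " slices:", x$slice_thickness, "mm thick /",
      x$slice_spacing, "mm spacing\n")
  print(x$gtab)
  invisible(x)
}

#' @export
dim.dwi_dataset <- function(x) dim(x$data)

#' Read a diffusion dataset from NIfTI + FSL-style side files
#'
#' Reads a 4-D NIfTI-1 image together with `bval`/`bvec` files (whitespace
#' separated; bvecs as 3 rows by N columns), an `acqparams` file (4 columns:
#' signed PE axis vector and readout time in seconds) and an `index` file
#' (one 1-based acqparams row per volume).
#'
#' @param image_path path to the 4-D NIfTI image.
#' @param bval_path,bvec_path paths to the b-value / b-vector files.
#' @param acqparams_path path to the acquisition-parameter table.
#' @param index_path path to the volume-to-row index file.
#' @param slice_spacing,slice_thickness slice geometry in mm; default is
#'   the through-plane voxel size (no overlap).
#' @return A validated [dwi_dataset()]; weighted b-vectors are normalised
#'   and volumes with b <= 50 s/mm^2 flagged as b0.
#' @export
read_dataset <- function(image_path, bval_path, bvec_path,
                         acqparams_path, index_path,
                         slice_spacing = NULL, slice_thickness = NULL) {
  for (p in c(image_path, bval_path, bvec_path, acqparams_path, index_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(image_path)
  arr <- array(as.vector(img), dim(img))   # plain array, no image attrs
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  nvol <- dim(arr)[4]
  bvals <- scan(bval_path, quiet = TRUE)
  if (length(bvals) != nvol)
    stop("format error in ", bval_path, ": ", length(bvals),
         " b-values for ", nvol, " volumes")
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
  if (nrow(bv) != nvol || ncol(bv) != 3L)
    stop("format error in ", bvec_path, ": expected 3 x ", nvol, " entries")
  idx <- scan(index_path, quiet = TRUE)
  if (length(idx) != nvol)
    stop("format error in ", index_path, ": ", length(idx),
         " entries for ", nvol, " volumes")
  ap <- as.matrix(utils::read.table(acqparams_path))
  if (ncol(ap) != 4L)
    stop("format error in ", acqparams_path, ": expected 4 columns")
  gtab <- gradient_table(bvals, bv, pe_index = as.integer(idx))
  acq <- acq_params(ap[, 1:3, drop = FALSE], ap[, 4])
  dwi_dataset(arr, xform_matrix(img), gtab, acq,
              slice_spacing = slice_spacing,
              slice_thickness = slice_thickness)
}

xform_matrix <- function(img) {
  m <- RNifti::xform(img)
  unname(rbind(m, c(0, 0, 0, 1))[1:4, 1:4])
}

#' Write a diffusion dataset as NIfTI + FSL-style side files
#'
#' Inverse of [read_dataset()]: writes `<prefix>.nii.gz`, `<prefix>.bval`,
#' `<prefix>.bvec` (FSL dialect, 3 rows by N columns),
#' `<prefix>_acqparams.txt` and `<prefix>_index.txt` so that reading the
#' file set back reproduces the dataset up to float storage tolerance.
#'
#' @param ds a [dwi_dataset()].
#' @param out_prefix path prefix for the output files.
#' @return Invisibly, the named character vector of written paths.
#' @export
write_dataset <- function(ds, out_prefix) {
  stopifnot(inherits(ds, "dwi_dataset"))
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = paste0(out_prefix, ".nii.gz"),
             bval = paste0(out_prefix, ".bval"),
             bvec = paste0(out_prefix, ".bvec"),
             acqparams = paste0(out_prefix, "_acqparams.txt"),
             index = paste0(out_prefix, "_index.txt"))
  img <- RNifti::asNifti(ds$data)
  RNifti::pixdim(img) <- c(voxel_size(ds$affine), 1)
  aff <- structure(ds$affine, code = 2L)
  img <- RNifti::`sform<-`(img, value = aff)
  img <- RNifti::`qform<-`(img, value = aff)
  img <- RNifti::asNifti(img, datatype = "double")
  RNifti::writeNifti(img, paths["image"])
  writeLines(paste(format(ds$gtab$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), paths["bval"])
  bv <- t(ds$gtab$bvecs)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")), paths["bvec"])
  utils::write.table(
    cbind(ds$acq$pe_x, ds$acq$pe_y, ds$acq$pe_z, ds$acq$readout),
    paths["acqparams"], row.names = FALSE, col.names = FALSE)
  writeLines(paste(ds$gtab$pe_index, collapse = " "), paths["index"])
  invisible(paths)
}

#' Write a 3-D volume as NIfTI with a given affine
#' @param vol 3-D array. @param affine 4x4 voxel-to-world matrix.
#' @param path output path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, affine, path) {
  vol <- as.array(vol)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(voxel_size(affine), 1)[seq_len(length(dim(vol)) + 1)]
  aff <- structure(as.matrix(affine), code = 2L)
  img <- RNifti::`sform<-`(img, value = aff)
  img <- RNifti::`qform<-`(img, value = aff)
  img <- RNifti::asNifti(img, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D volume and its affine
#' @param path NIfTI path.
#' @return list(data = array, affine = 4x4 matrix).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.vector(img), dim(img)),
       affine = xform_matrix(img))
}
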