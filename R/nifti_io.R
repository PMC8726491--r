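# NIfTI and DICOM I/O. Internally everything is LPS; NIfTI affines are RAS,
# so rows 1-2 of the affine are negated at the boundary. DICOM geometry is
# already LPS.

RAS_FLIP <- diag(c(-1, -1, 1))

#' Read a CT volume
#'
#' Reads a NIfTI file or a DICOM series directory into a [ct_volume()]. DICOM
#' stored values are mapped to HU with the per-file rescale slope/intercept,
#' slices are sorted ascending along the slice normal, and inconsistent
#' geometry (orientation or spacing mismatch, missing slices, non-CT
#' modality) raises an error naming the offending attribute.
#'
#' @param path File path (NIfTI) or directory (DICOM series).
#' @param format One of `"nifti"`, `"dicom_series"`. Default guesses from
#'   `path`: directories are treated as DICOM series.
#' @return A [ct_volume()] (or [mask_volume()] via [read_mask()]).
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  switch(format,
    nifti = read_nifti_volume(path),
    dicom_series = read_dicom_series(path)
  )
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)           # RAS, voxel->world, 0-based
  if (length(dim(img)) != 3L) stopf("expected a 3D NIfTI image")
  vals <- array(as.numeric(img), dim = dim(img))  # strip RNifti attributes
  lps <- RAS_FLIP %*% aff[1:3, , drop = FALSE]
  dircos_scaled <- lps[, 1:3]
  spacing <- sqrt(colSums(dircos_scaled^2))
  orientation <- sweep(dircos_scaled, 2, spacing, "/")
  ct_volume(vals, spacing = spacing, origin = lps[, 4],
            orientation = orientation)
}

#' Write a CT volume or mask as NIfTI
#'
#' Values, spacing, origin and orientation round-trip losslessly through
#' [read_volume()] / [read_mask()] (float32 storage is not used; data are
#' written as float64 for HU, uint8 for masks).
#'
#' @param volume A [ct_volume()] or [mask_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param format Only `"nifti"` is supported (DICOM writing is out of scope).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = "nifti") {
  if (!identical(format, "nifti")) stopf("only NIfTI writing is supported")
  is_mask <- inherits(volume, "mask_volume")
  if (!is_mask && !inherits(volume, "ct_volume")) {
    stopf("`volume` must be a ct_volume or mask_volume")
  }
  vals <- if (is_mask) array(as.integer(volume$values), dim(volume$values)) else volume$values
  img <- RNifti::asNifti(vals, datatype = if (is_mask) "uint8" else "double")
  img$pixdim <- c(1, volume$spacing, 0, 0, 0, 0)
  lps <- cbind(volume$orientation %*% diag(volume$spacing), volume$origin)
  aff <- rbind(RAS_FLIP %*% lps, c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (!all(vals %in% c(0, 1))) stopf("mask file contains values other than 0/1")
  v <- read_nifti_volume_geometry(path)
  mask_volume(array(vals != 0, dim(vals)), spacing = v$spacing,
              origin = v$origin, orientation = v$orientation)
}

read_nifti_volume_geometry <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  lps <- RAS_FLIP %*% aff[1:3, , drop = FALSE]
  spacing <- sqrt(colSums(lps[, 1:3]^2))
  list(spacing = spacing,
       orientation = sweep(lps[, 1:3], 2, spacing, "/"),
       origin = lps[, 4])
}
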