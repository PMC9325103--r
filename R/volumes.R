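#' Coronal CT volume container
#'
#' A stack of coronal slices in Hounsfield units together with the grid
#' metadata needed for physical measurements. Voxels are stored as a 3D array
#' with dimensions (row, col, slice); slices are ordered anterior to
#' posterior. `pixel_spacing` is the in-plane (row mm, col mm) pair and
#' `slice_spacing` the distance between consecutive coronal slices in mm.
#'
#' @param voxels numeric 3D array (row, col, slice) of HU values
#' @param pixel_spacing numeric length-2, mm per pixel (row, col), > 0
#' @param slice_spacing mm between slices, > 0
#' @param source_id study identifier string
#' @return an object of class `ct_volume`
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_spacing, source_id = "unknown") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array (row, col, slice)")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two strictly positive finite values")
  if (!is.finite(slice_spacing) || slice_spacing <= 0)
    stop("slice_spacing must be strictly positive")
  if (any(!is.finite(voxels))) stop("HU values must be finite")
  structure(list(voxels = voxels, pixel_spacing = pixel_spacing,
                 slice_spacing = as.numeric(slice_spacing),
                 source_id = as.character(source_id)),
            class = "ct_volume")
}

#' Label volume aligned with a CT volume
#'
#' Integer class labels (0..8 per [class_scheme()]) voxel-aligned with a
#' companion [ct_volume()]. Same array layout and spacing conventions.
#'
#' @param labels integer 3D array (row, col, slice), values in 0..8
#' @param pixel_spacing,slice_spacing,source_id as in [ct_volume()]
#' @return an object of class `label_volume`
#' @export
label_volume <- function(labels, pixel_spacing, slice_spacing, source_id = "unknown") {
  labels <- as.array(labels)
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array (row, col, slice)")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:8)) stop("labels must take values in 0..8")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two strictly positive values")
  structure(list(labels = labels, pixel_spacing = pixel_spacing,
                 slice_spacing = as.numeric(slice_spacing),
                 source_id = as.character(source_id)),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume '%s': %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
              x$source_id, d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_spacing, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume '%s': %d x %d x %d voxels, classes present: %s\n",
              x$source_id, d[1], d[2], d[3],
              paste(sort(unique(as.vector(x$labels))), collapse = " ")))
  invisible(x)
}

## ---- NIfTI IO -------------------------------------------------------------
## Internal (row, col, slice) maps directly onto NIfTI (i, j, k) with
## pixdim = (row mm, col mm, slice mm). The phantom writer and the readers
## below share this convention, so write/read is an exact round trip.

#' Write a CT volume as NIfTI
#' @param vol a [ct_volume()]
#' @param path output path (.nii or .nii.gz)
#' @return `path` invisibly
#' @export
write_ct_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- c(vol$pixel_spacing, vol$slice_spacing)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a label volume as NIfTI (uint8)
#' @param lab a [label_volume()]
#' @param path output path (.nii or .nii.gz)
#' @return `path` invisibly
#' @export
write_labels_nifti <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  img <- RNifti::asNifti(lab$labels)
  RNifti::pixdim(img) <- c(lab$pixel_spacing, lab$slice_spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a CT or label volume
#'
#' Reads a coronal CT series and populates HU values and grid spacing from
#' the file headers. NIfTI files (`.nii`/`.nii.gz`) are read with RNifti;
#' a DICOM series directory is read with the built-in minimal DICOM reader
#' (uncompressed little-endian transfer syntaxes), slices ordered anterior
#' to posterior by ImagePositionPatient (falling back to InstanceNumber).
#'
#' @param path file (NIfTI) or directory (DICOM series)
#' @param format `"nifti"` or `"dicom"`; `"auto"` guesses from `path`
#' @param source_id study identifier; default derived from `path`
#' @return a [ct_volume()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom"), source_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (is.null(source_id))
    source_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (format == "nifti") {
    if (!file.exists(path)) stop("no such file: ", path)
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(pd[1:3] <= 0)) stop("NIfTI header carries no usable pixdim: ", path)
    ct_volume(img[, , , drop = FALSE], pixel_spacing = pd[1:2],
              slice_spacing = pd[3], source_id = source_id)
  } else {
    read_dicom_series(path, source_id = source_id)
  }
}

#' Read a label volume from NIfTI
#' @param path NIfTI file with integer labels 0..8
#' @param source_id study identifier
#' @return a [label_volume()]
#' @export
read_labels <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(source_id)) source_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  label_volume(round(img[, , , drop = FALSE]), pixel_spacing = pd[1:2],
               slice_spacing = pd[3], source_id = source_id)
}
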