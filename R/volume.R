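#' Scalar image volume
#'
#' A 3D intensity grid with isotropic voxel spacing. The axis convention
#' follows the supine acquisition frame used throughout the package:
#' axis 1 = x, anterior-posterior (positive = posterior); axis 2 = y,
#' cranial-caudal (positive = cranial); axis 3 = z, lateral
#' (positive = right). The centre of voxel `(i, j, k)` sits at
#' `((i, j, k) - 0.5) * spacing` millimetres.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing isotropic voxel size in mm (single positive number).
#' @return an object of class `scalar_volume`: a list with elements `data`
#'   and `spacing`.
#' @examples
#' v <- scalar_volume(array(0, c(8, 8, 8)), spacing = 0.58)
#' dim(v)
#' @export
scalar_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop_input("`data` must be a numeric 3D array")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop_input("`spacing` must be a single positive number (mm)")
  }
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "scalar_volume")
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume> %d x %d x %d voxels, %.3g mm isotropic\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Labelled anatomical mask
#'
#' Integer-coded voxel mask over the same grid as a [scalar_volume()], with a
#' named label table mapping anatomical names (e.g. `"L4"`, `"L4-L5"`) to
#' integer codes. Code 0 is background.
#'
#' @param data integer 3D array of label codes (0 = background).
#' @param labels named integer vector, names are anatomical labels.
#' @param spacing isotropic voxel size in mm.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(data, labels, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_input("`data` must be a 3D array of integer label codes")
  }
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stop_input("`labels` must be a fully named integer vector")
  }
  storage.mode(data) <- "integer"
  structure(list(data = data,
                 labels = stats::setNames(as.integer(labels), names(labels)),
                 spacing = as.numeric(spacing)),
    class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d voxels, %d labels: %s\n",
              d[1], d[2], d[3], length(x$labels),
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

# integer code for an anatomical label, with a helpful error
mask_code <- function(mask, label) {
  if (!label %in% names(mask$labels)) {
    stop_input("label '%s' not present in mask (has: %s)", label,
               paste(names(mask$labels), collapse = ", "))
  }
  mask$labels[[label]]
}

# voxel-centre coordinates (mm) along each axis
voxel_centres <- function(dims, spacing) {
  lapply(seq_len(3), function(a) (seq_len(dims[a]) - 0.5) * spacing)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the isotropic spacing in the header.
#'
#' @param vol a [scalar_volume()] or [label_mask()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a [scalar_volume()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- rep(vol$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1]) {
    stop_input("volume at '%s' is not isotropic (pixdim %s)", path,
               paste(signif(sp, 4), collapse = " x "))
  }
  scalar_volume(array(as.numeric(img), dim(img)), spacing = sp[1])
}
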