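# Imaging containers and file I/O. Downstream modules consume only these
# in-memory types; NIfTI-1 and CSV are the on-disk interchange formats.

#' Construct a 3-D image volume
#'
#' Scalar 3-D grid with physical voxel spacing and origin (world mm, arrays
#' indexed x, y, z). PET volumes hold standardised uptake values (SUV, g/mL);
#' CT volumes hold Hounsfield units.
#'
#' @param data numeric 3-D array (x fastest, as stored in NIfTI).
#' @param spacing numeric length-3, voxel size in mm; strictly positive.
#' @param origin numeric length-3, world coordinate of the first voxel centre.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(1, c(4, 4, 4)), spacing = c(3.18, 3.18, 3))
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("image_volume: data must be a 3-D array")
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: origin must be 3 finite numbers")
  if (any(!is.finite(data)))
    stop("image_volume: data must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' Construct a binary volume-of-interest mask
#'
#' A VOI mask shares the grid (shape, spacing, origin) of its parent volume
#' and must select at least one voxel.
#'
#' @param data logical or 0/1 3-D array.
#' @param spacing,origin grid metadata, as in [image_volume()].
#' @return An object of class `voi_mask` with a logical `data` array.
#' @export
voi_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("voi_mask: data must be a 3-D array")
  if (is.numeric(data)) {
    if (any(!data %in% c(0, 1))) stop("voi_mask: values must be 0/1")
    data <- array(data > 0.5, dim(data))
  }
  if (!is.logical(data)) stop("voi_mask: data must be logical or 0/1")
  if (!any(data)) stop("voi_mask: mask must contain at least one voxel")
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("voi_mask: spacing must be 3 strictly positive numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", paste(dim(x$data), collapse = " x "), " grid, ",
      sum(x$data), " voxels selected\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read a 3-D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  x <- nifti_read(path)
  image_volume(x$data, x$spacing, x$origin)
}

#' Write a 3-D volume to a NIfTI-1 file
#'
#' Volumes are stored as float64 so that write-read round trips are exact.
#' @param volume an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  nifti_write(volume$data, volume$spacing, volume$origin, path,
              datatype = 64L)
  invisible(path)
}

#' Read a VOI mask from a NIfTI-1 file
#'
#' @param path path to the mask file.
#' @param volume optional parent [image_volume()]; if given, the mask grid
#'   must match it exactly (alignment error otherwise).
#' @return A [voi_mask()].
#' @export
read_mask <- function(path, volume = NULL) {
  x <- nifti_read(path)
  m <- voi_mask(array(x$data > 0.5, dim(x$data)), x$spacing, x$origin)
  if (!is.null(volume) && !same_grid(m, volume))
    stop("mask grid does not align with the declared parent volume")
  m
}

#' Write a VOI mask to a NIfTI-1 file
#'
#' Masks are stored as unsigned 8-bit with values {0, 1}.
#' @param mask a [voi_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  nifti_write(array(as.integer(mask$data), dim(mask$data)), mask$spacing,
              mask$origin, path, datatype = 2L)
  invisible(path)
}

#' Read / write a lesion table
#'
#' One row per lesion: `id`, `patient_id`, `cluster`, the three dichotomous
#' biochemistry flags (`adrenergic`, `noradrenergic`, `dopaminergic`) and the
#' 211 named feature columns.
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_lesion_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_lesion_table
#' @param table data.frame to write.
#' @export
write_lesion_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
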