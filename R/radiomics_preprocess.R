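# Preprocessing for feature extraction: CT resampling to 1.5 mm isotropic
# voxels by separable cubic-spline interpolation (grids aligned by the input
# origin; PET is never interpolated) and fixed-bin-size discretisation
# (0.5 g/mL for PET, 25 HU for CT), anchored at the in-mask minimum.

#' Radiomics preprocessing configuration
#'
#' @param ct_iso_spacing isotropic CT target spacing in mm (default 1.5).
#' @param pet_interpolate PET is computed on its native, nearly isotropic
#'   grid; kept as an explicit switch (default FALSE).
#' @param pet_bin_width fixed discretisation bin size for PET, g/mL
#'   (default 0.5).
#' @param ct_bin_width fixed discretisation bin size for CT, HU (default 25).
#' @return List of class `preprocess_config`.
#' @export
radiomics_config <- function(ct_iso_spacing = 1.5, pet_interpolate = FALSE,
                             pet_bin_width = 0.5, ct_bin_width = 25) {
  stopifnot(ct_iso_spacing > 0, pet_bin_width > 0, ct_bin_width > 0)
  structure(list(ct_iso_spacing = ct_iso_spacing,
                 pet_interpolate = pet_interpolate,
                 pet_bin_width = pet_bin_width,
                 ct_bin_width = ct_bin_width),
            class = "preprocess_config")
}

# Cubic-spline interpolation matrix from an n_in regular grid (spacing s_in,
# first centre at 0) to an n_out grid (spacing s_out). Cached per geometry.
.spline_op_cache <- new.env(parent = emptyenv())

spline_operator <- function(n_in, s_in, n_out, s_out) {
  key <- paste(n_in, s_in, n_out, s_out, sep = "|")
  hit <- .spline_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  u <- (seq_len(n_in) - 1) * s_in
  t <- (seq_len(n_out) - 1) * s_out
  W <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    W[, 1] <- 1
  } else if (n_in <= 3L) {
    for (j in seq_len(n_in))
      W[, j] <- stats::approx(u, as.numeric(seq_len(n_in) == j), xout = t,
                              rule = 2)$y
  } else {
    for (j in seq_len(n_in))
      W[, j] <- stats::spline(u, as.numeric(seq_len(n_in) == j), xout = t,
                              method = "natural")$y
  }
  .spline_op_cache[[key]] <- W
  W
}

apply_axis_operator <- function(a, W, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- W %*% matrix(ap, d[1], d[2] * d[3])
  out <- array(m, c(nrow(W), d[2], d[3]))
  aperm(out, order(perm))
}

#' Resample a CT volume (and mask) to an isotropic grid
#'
#' Separable cubic-spline interpolation onto an isotropic grid whose origin
#' coincides with the input origin; output extents cover the input
#' voxel-centre domain. Masks are resampled with the same operator and
#' re-binarised at 0.5.
#'
#' @param ct an [image_volume()].
#' @param config a [radiomics_config()].
#' @param mask optional [voi_mask()] on the same grid.
#' @return List with `volume` (and `mask` if supplied).
#' @export
resample_isotropic <- function(ct, config = radiomics_config(), mask = NULL) {
  stopifnot(inherits(ct, "image_volume"))
  s_out <- config$ct_iso_spacing
  d_in <- dim(ct$data)
  d_out <- pmax(floor((d_in - 1) * ct$spacing / s_out) + 1, 1)
  if (any(d_out < 1L)) stop("resampling produced an empty grid")
  Ws <- lapply(1:3, function(k)
    spline_operator(d_in[k], ct$spacing[k], d_out[k], s_out))
  res <- ct$data
  for (k in 1:3) res <- apply_axis_operator(res, Ws[[k]], k)
  vol <- image_volume(res, rep(s_out, 3), ct$origin)
  if (is.null(mask)) return(list(volume = vol))
  stopifnot(inherits(mask, "voi_mask"))
  md <- array(as.double(mask$data), d_in)
  for (k in 1:3) md <- apply_axis_operator(md, Ws[[k]], k)
  list(volume = vol,
       mask = voi_mask(md >= 0.5, rep(s_out, 3), ct$origin))
}

#' Discretise in-mask intensities with a fixed bin size
#'
#' Bin index `floor((x - min_in_mask) / bin_width) + 1`; the number of grey
#' levels is the maximum index. A zero intensity range yields a single bin
#' and is flagged.
#'
#' @param volume an [image_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param bin_width bin size in intensity units.
#' @return List of class `discretised`: `bins` (integer array cropped to the
#'   mask bounding box, NA outside the mask), `ng` (number of grey levels),
#'   `values` (raw in-mask intensities), `n_voxels`, `spacing`,
#'   `single_bin` flag.
#' @export
discretise <- function(volume, mask, bin_width) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"),
            bin_width > 0)
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("mask grid does not match the volume")
  if (!any(mask$data)) stop("mask is empty")
  w <- which(mask$data)
  cc <- coord_from_lin(w, dim(mask$data))
  lo <- apply(cc, 2, min); hi <- apply(cc, 2, max)
  a <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(a) <- dim(m) <- hi - lo + 1L
  vals <- a[m]
  mn <- min(vals)
  bins <- array(NA_integer_, dim(a))
  bins[m] <- as.integer(floor((a[m] - mn) / bin_width)) + 1L
  ng <- max(bins, na.rm = TRUE)
  structure(list(bins = bins, ng = ng, values = vals,
                 n_voxels = length(vals), spacing = volume$spacing,
                 bin_width = bin_width, single_bin = ng == 1L),
            class = "discretised")
}
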