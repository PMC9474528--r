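# PET VOI delineation: boxing, SUVpeak search (12 mm sphere), local
# background estimation, and the background-corrected 41% adaptive
# isocontour with connected-component selection and the 64-voxel QC filter.

#' Restrict a volume to an axis-aligned box
#'
#' Voxels outside the box are set to `NA` (a background-neutral sentinel)
#' and are excluded from every subsequent peak-search / threshold step.
#' Boxing is how surrounding physiological FDG-avid structures (kidney,
#' brown adipose tissue) are kept out of the delineation.
#'
#' @param volume an [image_volume()].
#' @param box list or vector of voxel index ranges
#'   `c(x0, x1, y0, y1, z0, z1)` (1-based, inclusive); `NULL` means the full
#'   grid.
#' @return An `image_volume` whose out-of-box voxels are `NA`.
#' @export
apply_box <- function(volume, box = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  if (is.null(box)) return(volume)
  box <- as.integer(unlist(box))
  stopifnot(length(box) == 6L)
  lo <- box[c(1, 3, 5)]; hi <- box[c(2, 4, 6)]
  if (any(lo < 1L) || any(hi > d) || any(lo > hi))
    stop("box is empty or outside the grid")
  keep <- array(FALSE, d)
  keep[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  out <- volume
  out$data[!keep] <- NA_real_
  out
}

#' Find the SUVpeak of a boxed PET volume
#'
#' SUVpeak is the maximum, over candidate sphere centres (every in-box
#' voxel), of the mean SUV of the voxels whose centres lie within a sphere
#' of 12 mm diameter. Sphere membership is by voxel-centre inclusion;
#' near edges the mean is taken over the sphere voxels that exist inside
#' the box. Ties break to the lowest linear index.
#'
#' @param volume an [image_volume()], possibly boxed with [apply_box()].
#' @param sphere_diameter_mm sphere diameter (default 12).
#' @return List of class `peak_result`: `suv_peak` (g/mL), `peak_centre`
#'   (voxel index triple), `sphere_radius` (mm).
#' @export
find_suv_peak <- function(volume, sphere_diameter_mm = 12) {
  stopifnot(inherits(volume, "image_volume"))
  a <- volume$data
  if (!any(!is.na(a))) stop("no peak: boxed region is empty")
  offs <- sphere_offsets(sphere_diameter_mm / 2, volume$spacing)
  acc <- array(0, dim(a)); cnt <- array(0L, dim(a))
  for (r in seq_len(nrow(offs))) {
    s <- shift_array(a, offs[r, ])
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  mean_map <- acc / cnt
  mean_map[is.na(a) | cnt == 0L] <- -Inf   # centres must lie inside the box
  best <- which.max(mean_map)              # lowest linear index on ties
  structure(list(
    suv_peak = mean_map[best],
    peak_centre = as.integer(coord_from_lin(best, dim(a))),
    sphere_radius = sphere_diameter_mm / 2
  ), class = "peak_result")
}

#' Estimate local background around a peak
#'
#' Mean SUV in a spherical shell centred on the peak (default inner radius
#' 15 mm, outer 22.5 mm), restricted to the box. If the shell contains no
#' in-box voxel the 10th percentile of the boxed region is used and the
#' result is flagged (`attr(, "fallback")`).
#'
#' @param volume boxed [image_volume()].
#' @param peak a `peak_result` from [find_suv_peak()].
#' @param inner_mm,outer_mm shell radii in mm.
#' @return Background SUV (g/mL).
#' @export
estimate_background <- function(volume, peak, inner_mm = 15, outer_mm = 22.5) {
  stopifnot(inherits(peak, "peak_result"), outer_mm > inner_mm)
  a <- volume$data
  d <- dim(a)
  sp <- volume$spacing
  offs_out <- sphere_offsets(outer_mm, sp)
  d2 <- (offs_out[, 1] * sp[1])^2 + (offs_out[, 2] * sp[2])^2 +
    (offs_out[, 3] * sp[3])^2
  shell <- offs_out[d2 > inner_mm^2, , drop = FALSE]
  ctr <- matrix(peak$peak_centre, nrow(shell), 3, byrow = TRUE) + shell
  inb <- ctr[, 1] >= 1 & ctr[, 1] <= d[1] & ctr[, 2] >= 1 & ctr[, 2] <= d[2] &
    ctr[, 3] >= 1 & ctr[, 3] <= d[3]
  vals <- a[lin_index(ctr[inb, , drop = FALSE], d)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    bg <- stats::quantile(a[!is.na(a)], 0.10, names = FALSE)
    attr(bg, "fallback") <- TRUE
    return(bg)
  }
  mean(vals)
}

#' Delineate the VOI by the background-corrected adaptive isocontour
#'
#' Threshold `T = 0.41 * (SUVpeak - background) + background`; the VOI is
#' the 26-connected component of `{SUV >= T}` containing the peak centre
#' (seeded at the hottest sphere voxel if the centre itself falls below T).
#' Regions of central necrosis excluded by the threshold are not re-added.
#'
#' @param volume boxed [image_volume()].
#' @param peak a `peak_result`.
#' @param background background SUV from [estimate_background()].
#' @param fraction isocontour fraction of the background-corrected peak
#'   (default 0.41).
#' @param min_voxels QC size filter (default 64).
#' @return List of class `segmentation_result`: `mask` ([voi_mask()]),
#'   `threshold`, `background`, `peak`, `passed_size_filter`.
#' @export
adaptive_isocontour <- function(volume, peak, background, fraction = 0.41,
                                min_voxels = 64L) {
  stopifnot(inherits(volume, "image_volume"), inherits(peak, "peak_result"))
  if (!(peak$suv_peak > background))
    stop("no lesion: SUVpeak does not exceed local background")
  thr <- fraction * (peak$suv_peak - background) + background
  a <- volume$data
  supra <- !is.na(a) & a >= thr
  if (!any(supra)) stop("no lesion: no voxel reaches the adaptive threshold")
  d <- dim(a)
  seed <- lin_index(matrix(peak$peak_centre, 1), d)
  if (!supra[seed]) {
    # seed at the hottest voxel within the peak sphere instead
    offs <- sphere_offsets(peak$sphere_radius, volume$spacing)
    ctr <- matrix(peak$peak_centre, nrow(offs), 3, byrow = TRUE) + offs
    inb <- ctr[, 1] >= 1 & ctr[, 1] <= d[1] & ctr[, 2] >= 1 &
      ctr[, 2] <= d[2] & ctr[, 3] >= 1 & ctr[, 3] <= d[3]
    cand <- lin_index(ctr[inb, , drop = FALSE], d)
    cand <- cand[supra[cand]]
    if (length(cand) == 0L)
      stop("no lesion: peak sphere contains no supra-threshold voxel")
    seed <- cand[which.max(a[cand])]
  }
  # crop to the supra-threshold bounding box before component labelling
  w <- which(supra)
  cc <- coord_from_lin(w, d)
  lo <- pmax(apply(cc, 2, min) - 1L, 1L)
  hi <- pmin(apply(cc, 2, max) + 1L, d)
  sub <- supra[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  seed_c <- coord_from_lin(seed, d) - matrix(lo - 1L, 1)
  comp_sub <- connected_component(sub, lin_index(seed_c, dim(sub)))
  comp <- array(FALSE, d)
  comp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- comp_sub
  mask <- voi_mask(comp, volume$spacing, volume$origin)
  structure(list(
    mask = mask, threshold = thr, background = as.numeric(background),
    peak = peak,
    passed_size_filter = size_filter(mask, min_voxels)
  ), class = "segmentation_result")
}

#' VOI size quality filter
#'
#' The minimal recommended VOI size is 64 voxels; smaller delineations are
#' flagged and excluded from the cohort table.
#'
#' @param mask a [voi_mask()].
#' @param min_voxels minimum voxel count (default 64).
#' @return TRUE iff the mask has at least `min_voxels` voxels.
#' @export
size_filter <- function(mask, min_voxels = 64L) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$data) >= min_voxels
}

#' Full PET delineation for one volume
#'
#' Convenience wrapper: box, peak search, background estimation, adaptive
#' isocontour.
#'
#' @param volume an [image_volume()] in SUV units.
#' @param box optional voxel box (see [apply_box()]).
#' @param fraction,min_voxels see [adaptive_isocontour()].
#' @param inner_mm,outer_mm see [estimate_background()].
#' @return A `segmentation_result`.
#' @export
segment_pet <- function(volume, box = NULL, fraction = 0.41,
                        min_voxels = 64L, inner_mm = 15, outer_mm = 22.5) {
  boxed <- apply_box(volume, box)
  pk <- find_suv_peak(boxed)
  bg <- estimate_background(boxed, pk, inner_mm, outer_mm)
  adaptive_isocontour(boxed, pk, bg, fraction, min_voxels)
}
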