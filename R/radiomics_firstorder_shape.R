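# First-order (intensity histogram) and shape (mesh / moment) features.

#' First-order intensity features
#'
#' The 18-feature first-order set: intensity statistics from the raw
#' in-mask values, entropy and uniformity from the fixed-bin-size
#' discretisation (`entropy = -sum p_k log2 p_k`). Percentiles use the
#' standard linear-interpolation quantile.
#'
#' @param disc a [discretise()] result.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(disc) {
  stopifnot(inherits(disc, "discretised"))
  x <- disc$values
  n <- length(x)
  if (n == 0L) stop("empty mask")
  vv <- prod(disc$spacing)
  p <- tabulate(disc$bins[!is.na(disc$bins)], disc$ng) / n
  p_pos <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[4]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p_pos * log2(p_pos)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' Shape features of a binary mask
#'
#' The 14-feature 3-D shape set from the marching-tetrahedra surface mesh
#' (mesh volume -- the metabolic tumour volume on PET -- surface area,
#' sphericity, maximum 3-D diameter as the largest pairwise Euclidean
#' distance between mesh vertices) and from the principal components of the
#' physical in-mask voxel-centre coordinates (axis lengths `4 sqrt(lambda)`,
#' elongation, flatness). The three maximum 2-D diameters are the largest
#' pairwise vertex distances in the x-y (`Slice`), x-z (`Column`) and y-z
#' (`Row`) planes. A degenerate mesh falls back to the voxel-count volume
#' and is flagged.
#'
#' @param mask a [voi_mask()].
#' @return Named numeric vector of 14 features (in mm / mm^2 / mm^3).
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  d <- dim(mask$data)
  sp <- mask$spacing
  w <- which(mask$data)
  n <- length(w)
  cc <- coord_from_lin(w, d)
  lo <- apply(cc, 2, min); hi <- apply(cc, 2, max)
  sub <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  mesh <- mask_mesh(sub, sp)
  vol <- mesh_volume(mesh)
  area <- mesh_surface_area(mesh)
  degenerate <- !(vol > 0) || !(area > 0)
  if (degenerate) vol <- n * prod(sp)
  diam <- max_pairwise_diameters(mesh$vertices, sp)
  coords <- sweep(cc, 2, sp, `*`)
  if (n >= 2) {
    ev <- sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0), decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  out <- c(MeshVolume = vol,
           VoxelVolume = n * prod(sp),
           SurfaceArea = area,
           SurfaceVolumeRatio = if (vol > 0) area / vol else NA_real_,
           Sphericity = if (area > 0) (36 * pi * vol^2)^(1 / 3) / area
                        else NA_real_,
           Maximum3DDiameter = diam[1],
           Maximum2DDiameterSlice = diam[2],
           Maximum2DDiameterColumn = diam[3],
           Maximum2DDiameterRow = diam[4],
           MajorAxisLength = major,
           MinorAxisLength = minor,
           LeastAxisLength = least,
           Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
           Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
  attr(out, "degenerate_mesh") <- degenerate
  out
}
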