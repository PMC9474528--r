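# Texture families: GLCM (22 of the 24 named co-occurrence features --
# SumAverage, identically 2 x JointAverage for a symmetric matrix, and the
# eigen-based MCC are excluded to give the 73-feature texture set), GLRLM,
# GLSZM, NGTDM and GLDM. Conventions: symmetric co-occurrence at distance 1
# over the 13 unique 3-D directions with per-direction features averaged
# (not merged matrices); run lengths over the same 13 directions, averaged;
# size zones 26-connected; NGTDM/GLDM neighbourhoods are the 26 voxels at
# Chebyshev distance 1, GLDM similarity tolerance 0 and dependence defined
# as 1 + the number of equal-grey neighbours.

glcm_matrix <- function(bins, off) {
  ng <- max(bins, na.rm = TRUE)
  b2 <- shift_array(bins * 1.0, off)
  ok <- !is.na(bins) & !is.na(b2)
  if (!any(ok)) return(NULL)
  idx <- (bins[ok] - 1L) * ng + b2[ok]
  C <- matrix(tabulate(idx, ng * ng), ng, ng)
  C <- C + t(C)
  C / sum(C)
}

glcm_features_single <- function(p) {
  ng <- nrow(p)
  i <- seq_len(ng)
  px <- rowSums(p)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  ii <- matrix(i, ng, ng); jj <- t(ii)
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(ii - jj) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[ii + jj == k]), 0)
  pos <- p > 0
  hxy <- -sum(p[pos] * log2(p[pos]))
  pxpy <- px[ii] * px[jj]
  hxy1 <- -sum(p[pos] * log2(pxpy[pos]))
  pp <- pxpy > 0
  hxy2 <- -sum(pxpy[pp] * log2(pxpy[pp]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  da <- sum(k_diff * p_diff)
  pd_pos <- p_diff > 0
  imc2_arg <- max(0, 1 - exp(-2 * (hxy2 - hxy)))
  c(Autocorrelation = sum(ii * jj * p),
    ClusterProminence = sum((ii + jj - 2 * mu)^4 * p),
    ClusterShade = sum((ii + jj - 2 * mu)^3 * p),
    ClusterTendency = sum((ii + jj - 2 * mu)^2 * p),
    Contrast = sum((ii - jj)^2 * p),
    Correlation = if (sig2 > 0) (sum(ii * jj * p) - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff[pd_pos] * log2(p_diff[pd_pos])),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p_diff / (1 + k_diff)),
    Idm = sum(p_diff / (1 + k_diff^2)),
    Idmn = sum(p_diff / (1 + k_diff^2 / ng^2)),
    Idn = sum(p_diff / (1 + k_diff / ng)),
    Imc1 = if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(imc2_arg),
    InverseVariance = if (ng > 1)
      sum(p_diff[-1] / k_diff[-1]^2) else 0,
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    SumSquares = sig2)
}

#' Grey-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence matrices at distance 1 over the 13 unique 3-D
#' directions, normalised, with the 22 retained features computed per
#' direction and averaged. Cluster shade, the third central cross-moment,
#' measures the skewness of the co-occurrence distribution.
#'
#' @param disc a [discretise()] result.
#' @return Named numeric vector of 22 features.
#' @export
glcm_features <- function(disc) {
  stopifnot(inherits(disc, "discretised"))
  dirs <- directions13()
  feats <- NULL
  nd <- 0L
  for (r in seq_len(nrow(dirs))) {
    p <- glcm_matrix(disc$bins, dirs[r, ])
    if (is.null(p)) next
    f <- glcm_features_single(p)
    feats <- if (is.null(feats)) f else feats + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("no voxel pair in any direction; mask too small")
  feats / nd
}

glrlm_matrix <- function(bins, off) {
  d <- dim(bins)
  nb <- shift_array(bins * 1.0, off)
  same <- !is.na(bins) & !is.na(nb) & bins == nb
  prev <- shift_array(bins * 1.0, -off)
  is_start <- !is.na(bins) & !(!is.na(prev) & prev == bins)
  starts <- which(is_start)
  if (length(starts) == 0L) return(NULL)
  rl <- rep(1L, length(starts))
  cur <- coord_from_lin(starts, d)
  alive <- seq_along(starts)
  repeat {
    cont <- same[lin_index(cur, d)]
    if (!any(cont)) break
    alive <- alive[cont]
    cur <- cur[cont, , drop = FALSE] +
      matrix(off, length(alive), 3, byrow = TRUE)
    rl[alive] <- rl[alive] + 1L
  }
  ng <- max(bins, na.rm = TRUE)
  g <- bins[starts]
  lmax <- max(rl)
  P <- matrix(tabulate((rl - 1L) * ng + g, ng * lmax), ng, lmax)
  P
}

rl_style_features <- function(P, np, prefix_short, prefix_long, dim_label) {
  ng <- nrow(P); lmax <- ncol(P)
  g <- seq_len(ng); l <- seq_len(lmax)
  nr <- sum(P)
  pg <- rowSums(P); pl <- colSums(P)
  p <- P / nr
  mug <- sum(g * rowSums(p))
  mul <- sum(l * colSums(p))
  gl2 <- outer(g^2, l^2)
  ppos <- p[p > 0]
  vals <- c(
    sum(P %*% (1 / l^2)) / nr,            # short emphasis
    sum(P %*% l^2) / nr,                  # long emphasis
    sum(pg^2) / nr,                       # GrayLevelNonUniformity
    sum(pg^2) / nr^2,                     # GrayLevelNonUniformityNormalized
    sum(pl^2) / nr,                       # run/size non-uniformity
    sum(pl^2) / nr^2,                     # ... normalized
    nr / np,                              # percentage
    sum(p * outer((g - mug)^2, rep(1, lmax))),  # GrayLevelVariance
    sum(p * outer(rep(1, ng), (l - mul)^2)),    # run/size variance
    -sum(ppos * log2(ppos)),              # entropy
    sum((1 / g^2) %*% P) / nr,            # LowGrayLevel emphasis
    sum(g^2 %*% P) / nr,                  # HighGrayLevel emphasis
    sum(P / gl2) / nr,                    # short + low
    sum(P * outer(g^2, 1 / l^2)) / nr,    # short + high
    sum(P * outer(1 / g^2, l^2)) / nr,    # long + low
    sum(P * gl2) / nr                     # long + high
  )
  names(vals) <- c(
    paste0("Short", prefix_short, "Emphasis"),
    paste0("Large", prefix_long, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(dim_label, "NonUniformity"),
    paste0(dim_label, "NonUniformityNormalized"),
    paste0(dim_label, "Percentage"),
    "GrayLevelVariance",
    paste0(dim_label, "Variance"),
    paste0(dim_label, "Entropy"),
    paste0("LowGrayLevel", prefix_short, "Emphasis"),
    paste0("HighGrayLevel", prefix_short, "Emphasis"),
    paste0("Short", prefix_short, "LowGrayLevelEmphasis"),
    paste0("Short", prefix_short, "HighGrayLevelEmphasis"),
    paste0("Large", prefix_long, "LowGrayLevelEmphasis"),
    paste0("Large", prefix_long, "HighGrayLevelEmphasis")
  )
  vals
}

#' Grey-level run-length (GLRLM) features
#'
#' Run-length matrices over the 13 unique 3-D directions; the 16 features
#' are computed per direction and averaged.
#'
#' @param disc a [discretise()] result.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(disc) {
  stopifnot(inherits(disc, "discretised"))
  dirs <- directions13()
  np <- disc$n_voxels
  feats <- NULL; nd <- 0L
  for (r in seq_len(nrow(dirs))) {
    P <- glrlm_matrix(disc$bins, dirs[r, ])
    if (is.null(P)) next
    f <- rl_style_features(P, np, "Run", "Run", "RunLength")
    # conventional GLRLM naming
    names(f) <- sub("^LargeRun", "LongRun", names(f))
    names(f) <- sub("^ShortRun", "ShortRun", names(f))
    names(f) <- sub("RunLengthVariance", "RunVariance", names(f))
    names(f) <- sub("RunLengthEntropy", "RunEntropy", names(f))
    names(f) <- sub("RunLengthPercentage", "RunPercentage", names(f))
    names(f) <- sub("LowGrayLevelRunEmphasis", "LowGrayLevelRunEmphasis",
                    names(f))
    feats <- if (is.null(feats)) f else feats + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("no run in any direction")
  feats / nd
}

glszm_pairs <- function(disc) {
  m <- !is.na(disc$bins)
  lab <- label_zones(disc$bins * 1.0, m)
  labs <- lab[m]
  zones <- tapply(seq_along(labs), labs, length)
  greys <- disc$bins[m][match(as.numeric(names(zones)), labs)]
  data.frame(g = as.integer(greys), s = as.integer(zones))
}

pairs_features <- function(pairs, np, prefix_short, prefix_long, dim_label) {
  agg <- stats::aggregate(cnt ~ g + s,
                          data = cbind(pairs, cnt = 1), FUN = sum)
  g <- agg$g; s <- agg$s; cnt <- agg$cnt
  nz <- sum(cnt)
  p <- cnt / nz
  mug <- sum(p * g); mus <- sum(p * s)
  pg <- tapply(cnt, g, sum); ps <- tapply(cnt, s, sum)
  vals <- c(
    sum(cnt / s^2) / nz,
    sum(cnt * s^2) / nz,
    sum(pg^2) / nz,
    sum(pg^2) / nz^2,
    sum(ps^2) / nz,
    sum(ps^2) / nz^2,
    nz / np,
    sum(p * (g - mug)^2),
    sum(p * (s - mus)^2),
    -sum(p * log2(p)),
    sum(cnt / g^2) / nz,
    sum(cnt * g^2) / nz,
    sum(cnt / (g^2 * s^2)) / nz,
    sum(cnt * g^2 / s^2) / nz,
    sum(cnt * s^2 / g^2) / nz,
    sum(cnt * g^2 * s^2) / nz
  )
  names(vals) <- c(
    paste0("Small", prefix_short, "Emphasis"),
    paste0("Large", prefix_long, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(dim_label, "NonUniformity"),
    paste0(dim_label, "NonUniformityNormalized"),
    paste0(dim_label, "Percentage"),
    "GrayLevelVariance",
    paste0(dim_label, "Variance"),
    paste0(dim_label, "Entropy"),
    paste0("LowGrayLevel", prefix_short, "Emphasis"),
    paste0("HighGrayLevel", prefix_short, "Emphasis"),
    paste0("Small", prefix_short, "LowGrayLevelEmphasis"),
    paste0("Small", prefix_short, "HighGrayLevelEmphasis"),
    paste0("Large", prefix_long, "LowGrayLevelEmphasis"),
    paste0("Large", prefix_long, "HighGrayLevelEmphasis")
  )
  vals
}

#' Grey-level size-zone (GLSZM) features
#'
#' Zones are 26-connected regions of equal grey level; 16 features from the
#' zone-size distribution (single matrix, no directions).
#'
#' @param disc a [discretise()] result.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(disc) {
  stopifnot(inherits(disc, "discretised"))
  pairs <- glszm_pairs(disc)
  f <- pairs_features(pairs, disc$n_voxels, "Area", "Area", "SizeZone")
  names(f) <- sub("^SmallArea", "SmallArea", names(f))
  names(f) <- sub("SizeZoneVariance", "ZoneVariance", names(f))
  names(f) <- sub("SizeZoneEntropy", "ZoneEntropy", names(f))
  names(f) <- sub("SizeZonePercentage", "ZonePercentage", names(f))
  names(f) <- sub("LowGrayLevelAreaEmphasis", "LowGrayLevelZoneEmphasis",
                  names(f))
  names(f) <- sub("HighGrayLevelAreaEmphasis", "HighGrayLevelZoneEmphasis",
                  names(f))
  f
}

#' Neighbourhood grey-tone difference (NGTDM) features
#'
#' For each in-mask voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its grey level and the mean grey level of
#' its neighbours is accumulated per level; Coarseness, Contrast, Busyness,
#' Complexity and Strength follow.
#'
#' @param disc a [discretise()] result.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(disc) {
  stopifnot(inherits(disc, "discretised"))
  bins <- disc$bins
  offs <- offsets26()
  acc <- array(0, dim(bins)); cnt <- array(0L, dim(bins))
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(bins * 1.0, offs[r, ])
    ok <- !is.na(nb)
    acc[ok] <- acc[ok] + nb[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  valid <- !is.na(bins) & cnt > 0L
  g <- bins[valid]
  diffs <- abs(g - acc[valid] / cnt[valid])
  nvc <- length(g)
  ng <- disc$ng
  ni <- tabulate(g, ng)
  si <- vapply(seq_len(ng), function(k) sum(diffs[g == k]), 0)
  pi_ <- ni / nvc
  lv <- seq_len(ng)
  present <- pi_ > 0
  ngp <- sum(present)
  coarseness <- {
    den <- sum(pi_ * si)
    if (den > 0) 1 / den else 1e6
  }
  contrast <- if (ngp > 1) {
    sum(outer(pi_, pi_) * outer(lv, lv, `-`)^2) / (ngp * (ngp - 1)) *
      sum(si) / nvc
  } else 0
  pmat <- outer(present, present, `&`)
  busy_den <- sum(abs(outer(lv * pi_, lv * pi_, `-`))[pmat])
  busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
  num_c <- outer(pi_ * si, pi_ * si, function(a, b) a + b)
  psum <- outer(pi_, pi_, `+`)
  cmplx <- abs(outer(lv, lv, `-`)) * num_c / psum
  complexity <- sum(cmplx[pmat & psum > 0]) / nvc
  stren_num <- sum((outer(pi_, pi_, `+`) * outer(lv, lv, `-`)^2)[pmat])
  strength <- if (sum(si) > 0) stren_num / sum(si) else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Grey-level dependence (GLDM) features
#'
#' Dependence of a voxel is 1 plus the number of its 26 Chebyshev-distance-1
#' neighbours with the same grey level (similarity tolerance 0); 14 features
#' from the grey-level x dependence distribution.
#'
#' @param disc a [discretise()] result.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(disc) {
  stopifnot(inherits(disc, "discretised"))
  bins <- disc$bins
  offs <- offsets26()
  dep <- array(1L, dim(bins))
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(bins * 1.0, offs[r, ])
    eq <- !is.na(bins) & !is.na(nb) & bins == nb
    dep[eq] <- dep[eq] + 1L
  }
  valid <- !is.na(bins)
  pairs <- data.frame(g = bins[valid], s = dep[valid])
  f <- pairs_features(pairs, disc$n_voxels, "Dependence", "Dependence",
                      "Dependence")
  # GLDM has no normalized grey-level non-uniformity; replace it with
  # DependenceNonUniformityNormalized ordering below (registry order).
  f <- f[c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
           "GrayLevelNonUniformity", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "GrayLevelVariance",
           "DependenceVariance", "DependenceEntropy",
           "LowGrayLevelDependenceEmphasis",
           "HighGrayLevelDependenceEmphasis",
           "SmallDependenceLowGrayLevelEmphasis",
           "SmallDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis",
           "LargeDependenceHighGrayLevelEmphasis")]
  names(f)[9:10] <- c("LowGrayLevelEmphasis", "HighGrayLevelEmphasis")
  f
}
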