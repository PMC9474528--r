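# Isosurface mesh of a binary mask by marching tetrahedra.
#
# Each grid cell (8 neighbouring voxel centres) is split into the six
# tetrahedra around the main diagonal; the 0.5-level surface of the blended
# occupancy field crosses tetrahedron edges at linearly interpolated points.
# This yields a closed, consistently outward-oriented triangle mesh in the
# same convergence class as marching cubes, without a 256-case table, which
# is then Taubin-smoothed. Used for mesh volume
# (the metabolic tumour volume on PET), surface area, sphericity and the
# maximum 3-D diameter.

# The six tetrahedra of a cube, as corner ids 0..7 (bit order x, y, z),
# one per monotone edge path from corner 0 to corner 7.
TET_DECOMP <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L)
)

CORNER_BITS <- cbind(x = bitwAnd(0:7, 1L),
                     y = bitwAnd(0:7, 2L) %/% 2L,
                     z = bitwAnd(0:7, 4L) %/% 4L)

# Triangles (as pairs of tet-local vertex ids whose edge midpoints form the
# triangle corners) for each of the 14 mixed sign patterns of a tetrahedron.
tet_case_tris <- function(inside) {
  ins <- which(inside); out <- which(!inside)
  if (length(ins) == 1L) {
    a <- ins
    list(rbind(c(a, out[1]), c(a, out[2]), c(a, out[3])))
  } else if (length(ins) == 3L) {
    a <- out
    list(rbind(c(a, ins[1]), c(a, ins[2]), c(a, ins[3])))
  } else {
    a <- ins[1]; b <- ins[2]; c_ <- out[1]; d <- out[2]
    list(rbind(c(a, c_), c(a, d), c(b, d)),
         rbind(c(a, c_), c(b, d), c(b, c_)))
  }
}

#' Triangulated 0.5-isosurface of a binary mask
#'
#' The binary occupancy is blended half-and-half with its 3x3x3 box mean
#' before contouring and edge crossings are placed by linear interpolation:
#' the raw binary field with midpoint crossings produces a heavily faceted
#' surface whose area is biased upward by 15-20% on digital spheres, while
#' the blended field converges to the analytic area within a few percent
#' and still guarantees a surface around isolated single voxels.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing (mm).
#' @return List with `p1`, `p2`, `p3` (n_tri x 3 physical-coordinate
#'   matrices of triangle corners, outward-oriented) and `vertices`
#'   (unique mesh vertices).
#' @keywords internal
mask_mesh <- function(mask, spacing) {
  d <- dim(mask)
  pd <- d + 2L
  padded <- array(0, pd)
  padded[2:(pd[1] - 1L), 2:(pd[2] - 1L), 2:(pd[3] - 1L)] <- as.double(mask)
  # blend with the 3^3 box mean (zero-padded outside)
  box <- array(0, pd)
  cnt <- 27
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    s <- shift_array(padded, c(dx, dy, dz))
    s[is.na(s)] <- 0
    box <- box + s
  }
  field <- (padded + box / cnt) / 2
  nc <- pd - 1L
  # field value of each of the 8 corners, per cell
  corner <- matrix(0, prod(nc), 8L)
  for (t in 1:8) {
    b <- CORNER_BITS[t, ]
    corner[, t] <- as.vector(
      field[(1L + b[1]):(nc[1] + b[1]),
            (1L + b[2]):(nc[2] + b[2]),
            (1L + b[3]):(nc[3] + b[3])])
  }
  corner_in <- corner > 0.5
  ns <- rowSums(corner_in)
  mixed <- which(ns > 0L & ns < 8L)
  if (length(mixed) == 0L)
    return(list(p1 = matrix(0, 0, 3), p2 = matrix(0, 0, 3),
                p3 = matrix(0, 0, 3), vertices = matrix(0, 0, 3),
                spacing = spacing))
  corner <- corner[mixed, , drop = FALSE]
  corner_in <- corner_in[mixed, , drop = FALSE]
  cc <- coord_from_lin(mixed, nc)           # cell base index in padded grid
  # integer grid index of each corner (physical coord = (idx - 2) * spacing)
  corner_idx <- lapply(1:8, function(t)
    sweep(cc, 2, CORNER_BITS[t, ], `+`))
  # linear code for lexicographic edge canonicalisation
  mlin <- max(pd) + 1
  corner_lin <- lapply(corner_idx, function(ix)
    (ix[, 1] * mlin + ix[, 2]) * mlin + ix[, 3])

  P1 <- P2 <- P3 <- vector("list", 0L)
  for (tt in seq_len(nrow(TET_DECOMP))) {
    tc <- TET_DECOMP[tt, ] + 1L            # 1-based corner ids
    v <- corner_in[, tc, drop = FALSE]
    caseid <- v %*% c(1L, 2L, 4L, 8L)
    for (cs in 1:14) {
      rows <- which(caseid == cs)
      if (length(rows) == 0L) next
      inside <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      tris <- tet_case_tris(inside)
      ic <- which(inside); oc <- which(!inside)
      for (tr in tris) {
        mid <- lapply(1:3, function(q) {
          a <- tc[tr[q, 1]]; b <- tc[tr[q, 2]]
          # canonical edge orientation: identical arithmetic in every cell
          # sharing the edge, so shared vertices are bitwise equal
          sw <- corner_lin[[b]][rows] < corner_lin[[a]][rows]
          va <- ifelse(sw, corner[rows, b], corner[rows, a])
          vb <- ifelse(sw, corner[rows, a], corner[rows, b])
          ia <- corner_idx[[a]][rows, , drop = FALSE]
          ib <- corner_idx[[b]][rows, , drop = FALSE]
          if (any(sw)) {
            tmp <- ia[sw, , drop = FALSE]
            ia[sw, ] <- ib[sw, , drop = FALSE]
            ib[sw, ] <- tmp
          }
          t_ <- (0.5 - va) / (vb - va)
          sweep((ia - 2) + t_ * (ib - ia), 2, spacing, `*`)
        })
        # orient outward: normal must point from inside towards outside
        cxyz <- function(a) sweep(corner_idx[[a]][rows, , drop = FALSE] - 2,
                                  2, spacing, `*`)
        cin <- Reduce(`+`, lapply(tc[ic], cxyz)) / length(ic)
        cout <- Reduce(`+`, lapply(tc[oc], cxyz)) / length(oc)
        e1 <- mid[[2]] - mid[[1]]; e2 <- mid[[3]] - mid[[1]]
        nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                     e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                     e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
        flip <- rowSums(nrm * (cout - cin)) < 0
        p2 <- mid[[2]]; p3 <- mid[[3]]
        if (any(flip)) {
          tmp <- p2[flip, , drop = FALSE]
          p2[flip, ] <- p3[flip, , drop = FALSE]
          p3[flip, ] <- tmp
        }
        P1[[length(P1) + 1L]] <- mid[[1]]
        P2[[length(P2) + 1L]] <- p2
        P3[[length(P3) + 1L]] <- p3
      }
    }
  }
  p1 <- do.call(rbind, P1); p2 <- do.call(rbind, P2); p3 <- do.call(rbind, P3)
  n_tri <- nrow(p1)
  all_v <- rbind(p1, p2, p3)
  cd <- coord_codes(all_v)
  m_ <- max(cd) + 1
  key <- (cd[, 1] * m_ + cd[, 2]) * m_ + cd[, 3]
  keep <- !duplicated(key)
  V <- all_v[keep, , drop = FALSE]
  vid <- match(key, key[keep])
  V <- taubin_smooth(V, matrix(vid, n_tri, 3))
  list(p1 = V[vid[seq_len(n_tri)], , drop = FALSE],
       p2 = V[vid[n_tri + seq_len(n_tri)], , drop = FALSE],
       p3 = V[vid[2 * n_tri + seq_len(n_tri)], , drop = FALSE],
       vertices = V, spacing = spacing)
}

# Taubin lambda/mu smoothing: removes the stair-step faceting of the
# tetrahedral isosurface (which otherwise biases surface area upward)
# while avoiding the volume shrinkage of plain Laplacian smoothing.
taubin_smooth <- function(V, tris, iterations = 20L, lambda = 0.6,
                          mu = -0.62) {
  if (nrow(V) < 4L) return(V)
  from <- c(tris[, 1], tris[, 2], tris[, 2], tris[, 3], tris[, 3],
            tris[, 1])
  to <- c(tris[, 2], tris[, 1], tris[, 3], tris[, 2], tris[, 1],
          tris[, 3])
  ek <- !duplicated(from * (nrow(V) + 1) + to)
  from <- from[ek]; to <- to[ek]
  deg <- tabulate(from, nrow(V))
  idx <- sort(unique(from))
  step <- function(V, w) {
    nb <- rowsum(V[to, , drop = FALSE], from, reorder = TRUE)
    lap <- V
    lap[idx, ] <- nb / deg[idx]
    V + w * (lap - V)
  }
  for (i in seq_len(iterations)) {
    V <- step(V, lambda)
    V <- step(V, mu)
  }
  V
}

# Exact integer codes for coordinate rows (shared-edge vertices are computed
# from identical inputs, so equality is exact).
coord_codes <- function(v) {
  c1 <- match(v[, 1], sort(unique(v[, 1])))
  c2 <- match(v[, 2], sort(unique(v[, 2])))
  c3 <- match(v[, 3], sort(unique(v[, 3])))
  cbind(c1, c2, c3)
}

mesh_surface_area <- function(mesh) {
  e1 <- mesh$p2 - mesh$p1; e2 <- mesh$p3 - mesh$p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(nrm^2))) / 2
}

mesh_volume <- function(mesh) {
  # divergence theorem over the closed outward-oriented surface
  p1 <- mesh$p1; p2 <- mesh$p2; p3 <- mesh$p3
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  sum(rowSums(p1 * cr)) / 6
}

# Maximum pairwise distances over a vertex set.
# Returns c(d3, d_xy, d_xz, d_yz): full 3-D diameter and the three
# plane-projected diameters. exact (chunked O(n^2)) up to 1500 vertices;
# larger sets are first reduced to their directional extremes over a
# Fibonacci sphere of 500 directions (plus 360-direction fans per
# projection plane). Diameter endpoints are hull-extreme points, so the
# deterministic error of the reduction is bounded by
# r_max (1 - cos theta) with theta the ~9 degree sampling gap -- well
# below one voxel at clinical lesion sizes. All oracle tests run in the
# exact regime.
max_pairwise_diameters <- function(v, spacing = NULL) {
  if (nrow(v) < 2L) return(c(0, 0, 0, 0))
  if (nrow(v) > 1500L) {
    ctr <- colMeans(v)
    vc <- sweep(v, 2, ctr)
    k <- 500L
    i <- seq_len(k)
    phi <- (1 + sqrt(5)) / 2
    z <- 1 - (2 * i - 1) / k
    r <- sqrt(pmax(1 - z^2, 0))
    th <- 2 * pi * i / phi
    dirs <- cbind(r * cos(th), r * sin(th), z)
    cand <- unique(max.col(tcrossprod(dirs, vc), ties.method = "first"))
    ang <- 2 * pi * seq_len(360L) / 360
    fan <- cbind(cos(ang), sin(ang))
    for (pl in list(c(1, 2), c(1, 3), c(2, 3)))
      cand <- union(cand,
                    unique(max.col(tcrossprod(fan, vc[, pl, drop = FALSE]),
                                   ties.method = "first")))
    v <- v[cand, , drop = FALSE]
  }
  w <- v
  n <- nrow(w)
  best <- c(0, 0, 0, 0)
  step <- max(1L, floor(4e6 / n))
  i <- 1L
  while (i <= n) {
    j <- min(i + step - 1L, n)
    dx2 <- outer(w[i:j, 1], w[, 1], `-`)^2
    dy2 <- outer(w[i:j, 2], w[, 2], `-`)^2
    dz2 <- outer(w[i:j, 3], w[, 3], `-`)^2
    best <- pmax(best, c(max(dx2 + dy2 + dz2), max(dx2 + dy2),
                         max(dx2 + dz2), max(dy2 + dz2)))
    i <- j + 1L
  }
  sqrt(best)
}
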