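# Internal array / RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library internals never perturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Counter-based per-item seed derivation: extending a cohort never reshuffles
# earlier lesions. Kept below 2^31 - 1.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) + 7919 * as.double(counter)) %% 2147483629) + 1L
}

# result[v] = a[v + off] (value of the neighbour at offset `off`), NA outside.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(NA_real_, d)
  idx_src <- idx_dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) {
      if (o >= d[k]) return(out)
      idx_src[[k]] <- (1L + o):d[k]
      idx_dst[[k]] <- 1L:(d[k] - o)
    } else {
      if (-o >= d[k]) return(out)
      idx_src[[k]] <- 1L:(d[k] + o)
      idx_dst[[k]] <- (1L - o):d[k]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# All 26 neighbour offsets, and the 13 unique (up to sign) 3-D directions.
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

directions13 <- function() {
  g <- offsets26()
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# Label 26-connected zones of equal value inside `mask` by iterative minimum
# propagation. Returns an integer array of zone labels (NA outside mask);
# labels are arbitrary but deterministic (minimum linear index of the zone).
label_zones <- function(values, mask) {
  d <- dim(mask)
  lab <- array(NA_real_, d)
  lab[mask] <- which(mask)
  offs <- offsets26()
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      nb_lab <- shift_array(lab, offs[r, ])
      nb_val <- shift_array(values, offs[r, ])
      ok <- !is.na(nb_lab) & !is.na(lab) & !is.na(nb_val) & !is.na(values) &
        nb_val == values & nb_lab < lab
      if (any(ok)) {
        lab[ok] <- nb_lab[ok]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# 26-connected component of `mask` containing linear index `seed`.
connected_component <- function(mask, seed) {
  if (!mask[seed]) stop("seed voxel is not inside the mask")
  lab <- label_zones(array(1, dim(mask)), mask)
  comp <- array(FALSE, dim(mask))
  comp[!is.na(lab) & lab == lab[seed]] <- TRUE
  comp
}

# Voxel-centre offsets (integer) whose physical distance from the centre voxel
# is <= radius_mm for the given spacing.
sphere_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# Small separable Gaussian smoothing (used for correlated texture fields).
smooth_gaussian3 <- function(a, sigma_vox = 1.5, halfwidth = 3L) {
  x <- (-halfwidth):halfwidth
  w <- exp(-x^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    acc <- array(0, dim(a))
    nrm <- array(0, dim(a))
    for (i in seq_along(x)) {
      off <- c(0L, 0L, 0L)
      off[axis] <- x[i]
      s <- shift_array(a, off)
      ok <- !is.na(s)
      acc[ok] <- acc[ok] + w[i] * s[ok]
      nrm[ok] <- nrm[ok] + w[i]
    }
    a <- acc / nrm
  }
  a
}

lin_index <- function(coords, d) {
  # coords: n x 3 matrix of 1-based voxel indices
  coords[, 1] + (coords[, 2] - 1L) * d[1] + (coords[, 3] - 1L) * d[1] * d[2]
}

coord_from_lin <- function(idx, d) {
  idx0 <- idx - 1L
  x <- idx0 %% d[1]
  y <- (idx0 %/% d[1]) %% d[2]
  z <- idx0 %/% (d[1] * d[2])
  cbind(x + 1L, y + 1L, z + 1L)
}
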