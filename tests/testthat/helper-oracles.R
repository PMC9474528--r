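# Independent brute-force oracles: plain scalar loops, no shared code paths
# with the package implementation. Used to freeze expected values and for
# the oracle-equivalence acceptance criterion.

oracle_dirs13 <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      out[[length(out) + 1]] <- c(dx, dy, dz)
  }
  out
}

oracle_offsets26 <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    if (abs(dx) + abs(dy) + abs(dz) > 0)
      out[[length(out) + 1]] <- c(dx, dy, dz)
  out
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# --- SUVpeak: exhaustive sphere-membership mean over all candidate centres
oracle_suv_peak <- function(a, spacing, radius_mm = 6) {
  d <- dim(a)
  best <- -Inf; best_centre <- NULL
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (is.na(a[x, y, z])) next
    vals <- c()
    for (zz in 1:d[3]) for (yy in 1:d[2]) for (xx in 1:d[1]) {
      if (is.na(a[xx, yy, zz])) next
      dist <- sqrt(((xx - x) * spacing[1])^2 + ((yy - y) * spacing[2])^2 +
                     ((zz - z) * spacing[3])^2)
      if (dist <= radius_mm + 1e-9) vals <- c(vals, a[xx, yy, zz])
    }
    m <- mean(vals)
    if (m > best) { best <- m; best_centre <- c(x, y, z) }
  }
  list(suv_peak = best, centre = best_centre)
}

# --- 26-connected component by explicit stack flood fill
oracle_component <- function(mask, seed_coord) {
  d <- dim(mask)
  comp <- array(FALSE, d)
  stack <- list(seed_coord)
  offs <- oracle_offsets26()
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (comp[p[1], p[2], p[3]]) next
    comp[p[1], p[2], p[3]] <- TRUE
    for (o in offs) {
      q <- p + o
      if (in_bounds(q, d) && mask[q[1], q[2], q[3]] &&
          !comp[q[1], q[2], q[3]])
        stack[[length(stack) + 1]] <- q
    }
  }
  comp
}

# --- discretisation + first-order histogram statistics
oracle_bins <- function(vals, width) floor((vals - min(vals)) / width) + 1

oracle_entropy <- function(vals, width) {
  b <- oracle_bins(vals, width)
  p <- as.numeric(table(b)) / length(b)
  -sum(p * log2(p))
}

# --- GLCM by explicit voxel-pair loops (symmetric, distance 1, 13 dirs)
oracle_glcm_matrix <- function(bins, dir) {
  d <- dim(bins)
  ng <- max(bins, na.rm = TRUE)
  C <- matrix(0, ng, ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (is.na(bins[x, y, z])) next
    q <- c(x, y, z) + dir
    if (!in_bounds(q, d)) next
    g2 <- bins[q[1], q[2], q[3]]
    if (is.na(g2)) next
    g1 <- bins[x, y, z]
    C[g1, g2] <- C[g1, g2] + 1
    C[g2, g1] <- C[g2, g1] + 1
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

oracle_glcm_features <- function(bins) {
  dirs <- oracle_dirs13()
  acc <- NULL; nd <- 0
  for (dir in dirs) {
    p <- oracle_glcm_matrix(bins, dir)
    if (is.null(p)) next
    ng <- nrow(p)
    f <- c()
    mu_x <- 0
    for (i in 1:ng) for (j in 1:ng) mu_x <- mu_x + i * p[i, j]
    sig2 <- 0
    for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu_x)^2 * p[i, j]
    shade <- prom <- tend <- contrast <- autoc <- 0
    jener <- 0; jentr <- 0; maxp <- 0
    for (i in 1:ng) for (j in 1:ng) {
      v <- p[i, j]
      shade <- shade + (i + j - 2 * mu_x)^3 * v
      prom <- prom + (i + j - 2 * mu_x)^4 * v
      tend <- tend + (i + j - 2 * mu_x)^2 * v
      contrast <- contrast + (i - j)^2 * v
      autoc <- autoc + i * j * v
      jener <- jener + v^2
      if (v > 0) jentr <- jentr - v * log2(v)
      maxp <- max(maxp, v)
    }
    corr <- if (sig2 > 0) (autoc - mu_x^2) / sig2 else 1
    pd <- rep(0, ng); ps <- rep(0, 2 * ng)
    for (i in 1:ng) for (j in 1:ng) {
      pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
      ps[i + j] <- ps[i + j] + p[i, j]
    }
    da <- sum((0:(ng - 1)) * pd)
    dentr <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
    dvar <- sum(((0:(ng - 1)) - da)^2 * pd)
    id <- sum(pd / (1 + 0:(ng - 1)))
    idm <- sum(pd / (1 + (0:(ng - 1))^2))
    idmn <- sum(pd / (1 + (0:(ng - 1))^2 / ng^2))
    idn <- sum(pd / (1 + (0:(ng - 1)) / ng))
    invvar <- if (ng > 1) sum(pd[-1] / (1:(ng - 1))^2) else 0
    px <- rowSums(p)
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    hxy1 <- 0; hxy2 <- 0
    for (i in 1:ng) for (j in 1:ng) {
      pp <- px[i] * px[j]
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(pp)
      if (pp > 0) hxy2 <- hxy2 - pp * log2(pp)
    }
    imc1 <- if (hx > 0) (jentr - hxy1) / hx else 0
    imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - jentr))))
    sentr <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
    f <- c(Autocorrelation = autoc, ClusterProminence = prom,
           ClusterShade = shade, ClusterTendency = tend,
           Contrast = contrast, Correlation = corr,
           DifferenceAverage = da, DifferenceEntropy = dentr,
           DifferenceVariance = dvar, Id = id, Idm = idm, Idmn = idmn,
           Idn = idn, Imc1 = imc1, Imc2 = imc2, InverseVariance = invvar,
           JointAverage = mu_x, JointEnergy = jener, JointEntropy = jentr,
           MaximumProbability = maxp, SumEntropy = sentr, SumSquares = sig2)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# --- GLRLM by naive per-voxel run walking
oracle_glrlm_matrix <- function(bins, dir) {
  d <- dim(bins)
  runs <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    g <- bins[x, y, z]
    if (is.na(g)) next
    prev <- c(x, y, z) - dir
    if (in_bounds(prev, d) && !is.na(bins[prev[1], prev[2], prev[3]]) &&
        bins[prev[1], prev[2], prev[3]] == g) next  # not a run start
    len <- 1
    q <- c(x, y, z) + dir
    while (in_bounds(q, d) && !is.na(bins[q[1], q[2], q[3]]) &&
           bins[q[1], q[2], q[3]] == g) {
      len <- len + 1
      q <- q + dir
    }
    runs[[length(runs) + 1]] <- c(g, len)
  }
  if (length(runs) == 0) return(NULL)
  runs <- do.call(rbind, runs)
  ng <- max(bins, na.rm = TRUE)
  P <- matrix(0, ng, max(runs[, 2]))
  for (r in seq_len(nrow(runs)))
    P[runs[r, 1], runs[r, 2]] <- P[runs[r, 1], runs[r, 2]] + 1
  P
}

# --- GLSZM zone list by stack flood fill per zone
oracle_glszm_pairs <- function(bins) {
  d <- dim(bins)
  seen <- array(FALSE, d)
  offs <- oracle_offsets26()
  out <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (is.na(bins[x, y, z]) || seen[x, y, z]) next
    g <- bins[x, y, z]
    size <- 0
    stack <- list(c(x, y, z))
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (seen[p[1], p[2], p[3]]) next
      if (is.na(bins[p[1], p[2], p[3]]) ||
          bins[p[1], p[2], p[3]] != g) next
      seen[p[1], p[2], p[3]] <- TRUE
      size <- size + 1
      for (o in offs) {
        q <- p + o
        if (in_bounds(q, d) && !seen[q[1], q[2], q[3]] &&
            !is.na(bins[q[1], q[2], q[3]]) && bins[q[1], q[2], q[3]] == g)
          stack[[length(stack) + 1]] <- q
      }
    }
    out[[length(out) + 1]] <- c(g, size)
  }
  do.call(rbind, out)
}

# --- GLDM dependence counts per voxel
oracle_gldm_pairs <- function(bins) {
  d <- dim(bins)
  offs <- oracle_offsets26()
  out <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    g <- bins[x, y, z]
    if (is.na(g)) next
    dep <- 1
    for (o in offs) {
      q <- c(x, y, z) + o
      if (in_bounds(q, d) && !is.na(bins[q[1], q[2], q[3]]) &&
          bins[q[1], q[2], q[3]] == g)
        dep <- dep + 1
    }
    out[[length(out) + 1]] <- c(g, dep)
  }
  do.call(rbind, out)
}

# --- NGTDM s_i / n_i accumulators
oracle_ngtdm <- function(bins) {
  d <- dim(bins)
  offs <- oracle_offsets26()
  ng <- max(bins, na.rm = TRUE)
  si <- rep(0, ng); ni <- rep(0, ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    g <- bins[x, y, z]
    if (is.na(g)) next
    nb <- c()
    for (o in offs) {
      q <- c(x, y, z) + o
      if (in_bounds(q, d) && !is.na(bins[q[1], q[2], q[3]]))
        nb <- c(nb, bins[q[1], q[2], q[3]])
    }
    if (length(nb) == 0) next
    si[g] <- si[g] + abs(g - mean(nb))
    ni[g] <- ni[g] + 1
  }
  list(si = si, ni = ni)
}

# --- generic features from (grey, size) pair table, naive formulas
oracle_pairs_features <- function(pairs, np) {
  key <- paste(pairs[, 1], pairs[, 2])
  tab <- table(key)
  gs <- do.call(rbind, strsplit(names(tab), " "))
  g <- as.numeric(gs[, 1]); s <- as.numeric(gs[, 2])
  cnt <- as.numeric(tab)
  nz <- sum(cnt); p <- cnt / nz
  pg <- tapply(cnt, g, sum); ps <- tapply(cnt, s, sum)
  mug <- sum(p * g); mus <- sum(p * s)
  c(sum(cnt / s^2) / nz, sum(cnt * s^2) / nz,
    sum(pg^2) / nz, sum(pg^2) / nz^2, sum(ps^2) / nz, sum(ps^2) / nz^2,
    nz / np, sum(p * (g - mug)^2), sum(p * (s - mus)^2),
    -sum(p * log2(p)),
    sum(cnt / g^2) / nz, sum(cnt * g^2) / nz,
    sum(cnt / (g^2 * s^2)) / nz, sum(cnt * g^2 / s^2) / nz,
    sum(cnt * s^2 / g^2) / nz, sum(cnt * g^2 * s^2) / nz)
}

# --- maximum pairwise distances over a vertex set, O(n^2)
oracle_max_diameters <- function(v) {
  best <- c(0, 0, 0, 0)
  n <- nrow(v)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx2 <- (v[i, 1] - v[j, 1])^2
    dy2 <- (v[i, 2] - v[j, 2])^2
    dz2 <- (v[i, 3] - v[j, 3])^2
    best[1] <- max(best[1], dx2 + dy2 + dz2)
    best[2] <- max(best[2], dx2 + dy2)
    best[3] <- max(best[3], dx2 + dz2)
    best[4] <- max(best[4], dy2 + dz2)
  }
  sqrt(best)
}

# --- KMO from the inverse correlation matrix, explicit loops
oracle_kmo <- function(R) {
  inv <- solve(R)
  p <- nrow(R)
  r2 <- 0; q2 <- 0
  for (i in 1:p) for (j in 1:p) {
    if (i == j) next
    r2 <- r2 + R[i, j]^2
    q <- -inv[i, j] / sqrt(inv[i, i] * inv[j, j])
    q2 <- q2 + q^2
  }
  r2 / (r2 + q2)
}

# --- pairwise AUC by explicit concordant / tied pair counting
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_hand_till <- function(p_i, p_j, labels, ci, cj) {
  keep <- labels %in% c(ci, cj)
  (oracle_auc(p_i[keep], labels[keep] == ci) +
     oracle_auc(p_j[keep], labels[keep] == cj)) / 2
}
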