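# Texture families against brute-force oracles, plus the degenerate-input
# limits and the invariance properties.

disc_of <- function(volume, mask, width = 0.5) discretise(volume, mask, width)

test_that("GLCM features: degenerate limits and symmetry zeros", {
  const <- image_volume(array(2, c(4, 4, 4)), c(1, 1, 1))
  g <- glcm_features(disc_of(const, full_mask(const)))
  expect_equal(g[["ClusterShade"]], 0)
  expect_equal(g[["Contrast"]], 0)
  expect_equal(g[["JointEnergy"]], 1)
  expect_equal(g[["Correlation"]], 1)

  # checkerboard: co-occurrence distribution symmetric about its mean ->
  # cluster shade (odd central moment) is zero
  d <- c(4, 4, 4)
  idx <- expand.grid(x = 1:4, y = 1:4, z = 1:4)
  chk <- array(ifelse((idx$x + idx$y + idx$z) %% 2 == 0, 1, 2), d)
  vol <- image_volume(chk, c(1, 1, 1))
  g2 <- glcm_features(disc_of(vol, full_mask(vol), 1))
  expect_equal(g2[["ClusterShade"]], 0, tolerance = 1e-12)
})

test_that("GLCM features equal the triple-loop oracle on random regions", {
  for (seed in c(1, 2, 7)) {
    reg <- rand_region(c(6, 6, 6), ng = 4, seed = seed)
    disc <- disc_of(reg$volume, reg$mask, 1)
    mine <- glcm_features(disc)
    orc <- oracle_glcm_features(disc$bins)
    expect_equal(mine, orc[names(mine)], tolerance = 1e-8)
  }
})

test_that("GLRLM matrices and features equal naive run enumeration", {
  for (seed in c(1, 5)) {
    reg <- rand_region(c(6, 6, 5), ng = 3, seed = seed)
    disc <- disc_of(reg$volume, reg$mask, 1)
    # matrix-level agreement per direction
    dirs <- petclust:::directions13()
    for (r in c(1, 6, 13)) {
      P1 <- petclust:::glrlm_matrix(disc$bins, dirs[r, ])
      P2 <- oracle_glrlm_matrix(disc$bins, dirs[r, ])
      expect_identical(dim(P1), dim(P2))
      expect_equal(P1, P2)
    }
    # feature-level agreement averaged over all 13 directions
    mine <- glrlm_features(disc)
    acc <- NULL; nd <- 0
    for (r in seq_len(nrow(dirs))) {
      P <- oracle_glrlm_matrix(disc$bins, dirs[r, ])
      if (is.null(P)) next
      f <- petclust:::rl_style_features(P, disc$n_voxels, "Run", "Run",
                                        "RunLength")
      acc <- if (is.null(acc)) f else acc + f
      nd <- nd + 1
    }
    expect_equal(unname(mine), unname(acc / nd), tolerance = 1e-8)
  }
})

test_that("GLSZM zones: constant block, checkerboard, random oracle", {
  # constant 4^3 region -> a single 64-voxel zone
  const <- image_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
  disc <- disc_of(const, full_mask(const))
  pairs <- petclust:::glszm_pairs(disc)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$s, 64L)

  # 3-D checkerboard with 26-connectivity: equal-value diagonal neighbours
  # connect, giving exactly two zones (one per colour)
  d <- c(4, 4, 4)
  idx <- expand.grid(x = 1:4, y = 1:4, z = 1:4)
  chk <- array(ifelse((idx$x + idx$y + idx$z) %% 2 == 0, 1, 2), d)
  vol <- image_volume(chk, c(1, 1, 1))
  dchk <- disc_of(vol, full_mask(vol), 1)
  pchk <- petclust:::glszm_pairs(dchk)
  orc_chk <- oracle_glszm_pairs(dchk$bins)
  expect_identical(nrow(pchk), nrow(orc_chk))
  expect_equal(sort(pchk$s), sort(orc_chk[, 2]))

  # random regions: zone multiset and features equal the flood-fill oracle
  for (seed in c(2, 9)) {
    reg <- rand_region(c(6, 6, 6), ng = 3, seed = seed)
    disc <- disc_of(reg$volume, reg$mask, 1)
    mine <- glszm_features(disc)
    orc <- oracle_pairs_features(oracle_glszm_pairs(disc$bins),
                                 disc$n_voxels)
    expect_equal(unname(mine), unname(orc), tolerance = 1e-8)
  }
})

test_that("GLDM features equal the per-voxel dependence oracle", {
  for (seed in c(3, 8)) {
    reg <- rand_region(c(6, 6, 6), ng = 3, seed = seed)
    disc <- disc_of(reg$volume, reg$mask, 1)
    mine <- gldm_features(disc)
    orc <- oracle_pairs_features(oracle_gldm_pairs(disc$bins),
                                 disc$n_voxels)
    # oracle order: SDE,LDE,GLN,GLNN,DN,DNN,DP,GLV,DV,DE,LGL,HGL,SDL,SDH,LDL,LDH
    expect_equal(unname(mine), unname(orc[c(1, 2, 3, 5, 6, 8, 9, 10, 11, 12,
                                            13, 14, 15, 16)]),
                 tolerance = 1e-8)
  }
})

test_that("NGTDM features equal the per-voxel neighbourhood oracle", {
  for (seed in c(4, 10)) {
    reg <- rand_region(c(6, 6, 6), ng = 4, seed = seed)
    disc <- disc_of(reg$volume, reg$mask, 1)
    mine <- ngtdm_features(disc)
    o <- oracle_ngtdm(disc$bins)
    ng <- disc$ng
    nvc <- sum(o$ni)
    pi_ <- o$ni / nvc
    lv <- seq_len(ng); present <- pi_ > 0; ngp <- sum(present)
    coars <- if (sum(pi_ * o$si) > 0) 1 / sum(pi_ * o$si) else 1e6
    contr <- if (ngp > 1)
      sum(outer(pi_, pi_) * outer(lv, lv, `-`)^2) / (ngp * (ngp - 1)) *
        sum(o$si) / nvc else 0
    pm <- outer(present, present, `&`)
    busy_den <- sum(abs(outer(lv * pi_, lv * pi_, `-`))[pm])
    busy <- if (busy_den > 0) sum(pi_ * o$si) / busy_den else 0
    psum <- outer(pi_, pi_, `+`)
    cm <- abs(outer(lv, lv, `-`)) * outer(pi_ * o$si, pi_ * o$si, `+`) / psum
    cplx <- sum(cm[pm & psum > 0]) / nvc
    stren <- if (sum(o$si) > 0)
      sum((psum * outer(lv, lv, `-`)^2)[pm]) / sum(o$si) else 0
    expect_equal(unname(mine), c(coars, contr, busy, cplx, stren),
                 tolerance = 1e-8)
    expect_gt(mine[["Busyness"]], 0)
  }
})

test_that("single-grey-level regions yield flagged degenerate texture", {
  const <- image_volume(array(5, c(3, 3, 3)), c(1, 1, 1))
  disc <- disc_of(const, full_mask(const))
  expect_true(disc$single_bin)
  expect_equal(glrlm_features(disc)[["GrayLevelVariance"]], 0)
  expect_equal(glszm_features(disc)[["GrayLevelVariance"]], 0)
  expect_equal(ngtdm_features(disc)[["Contrast"]], 0)
  expect_equal(gldm_features(disc)[["GrayLevelVariance"]], 0)
})

test_that("direction-averaged texture features are 90-degree rotation invariant", {
  reg <- rand_region(c(6, 6, 6), ng = 4, seed = 12, frac = 0.75,
                     spacing = c(1, 1, 1))
  disc <- disc_of(reg$volume, reg$mask, 1)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  vol_r <- image_volume(rot(reg$volume$data), c(1, 1, 1))
  mask_r <- voi_mask(rot(reg$mask$data * 1), c(1, 1, 1))
  disc_r <- disc_of(vol_r, mask_r, 1)
  for (fn in list(glcm_features, glrlm_features, glszm_features,
                  ngtdm_features, gldm_features))
    expect_equal(fn(disc), fn(disc_r), tolerance = 1e-9)
})

test_that("texture features are invariant to constant intensity shifts", {
  reg <- rand_region(c(6, 6, 6), ng = 4, seed = 13)
  disc <- disc_of(reg$volume, reg$mask, 0.5)
  shifted <- image_volume(reg$volume$data + 7.3, reg$volume$spacing)
  disc_s <- disc_of(shifted, reg$mask, 0.5)
  expect_equal(glcm_features(disc), glcm_features(disc_s), tolerance = 1e-9)
  expect_equal(gldm_features(disc), gldm_features(disc_s), tolerance = 1e-9)
  fo <- first_order_features(disc); fo_s <- first_order_features(disc_s)
  expect_equal(fo_s[["Maximum"]], fo[["Maximum"]] + 7.3, tolerance = 1e-9)
  expect_equal(fo_s[["Mean"]], fo[["Mean"]] + 7.3, tolerance = 1e-9)
})
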