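# dimred: scaler, redundancy filter, KMO, factor model, scores, labels.

test_that("scaler: closed form, training-mean zero, constant columns dropped", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  # population convention: scaled training column has variance exactly 1
  expect_lt(max(abs(colMeans(xs))), 1e-12)
  expect_equal(unname(colMeans(xs^2)), c(1, 1), tolerance = 1e-12)
  expect_warning(sc2 <- fit_scaler(cbind(x, cst = c(5, 5, 5))),
                 "zero-variance")
  expect_identical(sc2$features, c("a", "b"))
})

test_that("{1,2,3} scales to the closed form +/- 1.2247", {
  sc <- fit_scaler(matrix(c(1, 2, 3), 3, 1,
                          dimnames = list(NULL, "f")))
  xs <- apply_scaler(sc, matrix(c(1, 2, 3), 3, 1,
                                dimnames = list(NULL, "f")))
  expect_equal(as.numeric(xs), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
})

test_that("redundancy filter removes planted duplicates; survivors clean", {
  petclust:::with_seed(42, {
    n <- 40
    base <- matrix(stats::rnorm(n * 7), n, 7)
    x <- cbind(base,
               base[, 1] + stats::rnorm(n, 0, 1e-8),  # near-duplicates
               base[, 2] * 3 + 1e-9 * stats::rnorm(n),
               base[, 3])
    colnames(x) <- paste0("f", 1:10)
  })
  kept <- redundancy_filter(x, 0.95)
  expect_lt(length(kept), 10L)
  r <- abs(stats::cor(x[, kept], method = "spearman"))
  diag(r) <- 0
  expect_true(all(r < 0.95))   # exhaustive pair scan

  # two identical columns: exactly one survives
  xx <- cbind(a = stats::rnorm(20), b = 0)
  xx[, "b"] <- xx[, "a"]
  expect_length(redundancy_filter(xx, 0.95), 1L)

  # mutually uncorrelated columns: all retained
  petclust:::with_seed(1, u <- matrix(stats::rnorm(300), 100, 3,
                                      dimnames = list(NULL, c("p", "q", "r"))))
  expect_identical(redundancy_filter(u, 0.95), c("p", "q", "r"))
  expect_identical(redundancy_filter(u[, 1, drop = FALSE], 0.95), "p")
})

test_that("KMO equals the inverse-correlation oracle; limits behave", {
  # identity matrix: undefined, flagged
  k0 <- kmo(diag(4))
  expect_true(is.nan(k0))
  expect_true(isTRUE(attr(k0, "undefined")))

  # 3x3 with all off-diagonals 0.5
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  expect_equal(as.numeric(kmo(R)), oracle_kmo(R), tolerance = 1e-10)

  # random SPD correlation matrices
  for (seed in 1:4) {
    petclust:::with_seed(seed, {
      A <- matrix(stats::rnorm(100), 20, 5)
      R <- stats::cor(A)
    })
    expect_equal(as.numeric(kmo(R)), oracle_kmo(R), tolerance = 1e-10)
  }

  # near-duplicate features: KMO tends to the 0.5 limit
  petclust:::with_seed(9, {
    a <- stats::rnorm(200)
    R2 <- stats::cor(cbind(a, a + stats::rnorm(200, 0, 1e-4)))
  })
  expect_equal(as.numeric(kmo(R2)), oracle_kmo(R2), tolerance = 1e-8)
  expect_lt(abs(as.numeric(kmo(R2)) - 0.5), 0.01)
})

test_that("factor count rule and the factor model recover planted structure", {
  # 32 training lesions, 10 subjects per factor -> 3 factors
  petclust:::with_seed(5, x32 <- matrix(stats::rnorm(32 * 40), 32, 40,
    dimnames = list(NULL, paste0("f", 1:40))))
  model <- suppressWarnings(dimred_fit(x32))
  expect_identical(model$m, 3L)
  expect_identical(ncol(model$loadings), 3L)

  # exact 2-factor data: loadings recover the planted structure
  petclust:::with_seed(6, {
    n <- 300
    f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
    lam <- cbind(c(0.9, 0.8, 0.85, 0, 0, 0), c(0, 0, 0, 0.9, 0.85, 0.8))
    x <- cbind(f1, f2) %*% t(lam) + matrix(stats::rnorm(n * 6, 0, 0.3), n, 6)
    colnames(x) <- paste0("v", 1:6)
  })
  fit <- fit_factors(scale(x), 2)
  # congruence with the planted loading pattern, up to column order/sign
  cong <- abs(crossprod(lam / sqrt(colSums(lam^2)),
                        fit$loadings %*%
                          diag(1 / sqrt(colSums(fit$loadings^2)))))
  expect_gt(max(cong[1, ]), 0.95)
  expect_gt(max(cong[2, ]), 0.95)

  # m = 1: single factor, rotation is the identity
  fit1 <- fit_factors(scale(x), 1)
  expect_identical(ncol(fit1$loadings), 1L)
  # sign convention: the largest-magnitude loading is positive
  expect_gt(fit1$loadings[which.max(abs(fit1$loadings[, 1])), 1], 0)
})

test_that("factor scores: zero-centred on training, mean lesion scores ~ 0", {
  petclust:::with_seed(7, x <- matrix(stats::rnorm(50 * 12), 50, 12,
    dimnames = list(NULL, paste0("f", 1:12))))
  model <- suppressWarnings(dimred_fit(x))
  s <- factor_scores(model, x)
  expect_lt(max(abs(colMeans(s))), 1e-8)
  # a lesion at the training mean scores ~ 0
  mean_row <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
  expect_lt(max(abs(factor_scores(model, mean_row))), 1e-8)
  expect_error(factor_scores(model, x[, 1:3]), "missing feature")
})

test_that("scores with orthonormal loadings reduce to loading-weighted sums", {
  # if R = I and loadings are columns of the identity, B = R^-1 L = L
  p <- 5
  L <- diag(p)[, 1:2]
  model <- structure(list(
    scaler = structure(list(mean = rep(0, p), sd = rep(1, p),
                            features = paste0("f", 1:p)),
                       class = "feature_scaler"),
    retained_features = paste0("f", 1:p),
    loadings = `rownames<-`(L, paste0("f", 1:p)),
    m = 2L, kmo = NA_real_, R = diag(p)), class = "factor_model")
  petclust:::with_seed(8, z <- matrix(stats::rnorm(20 * p), 20, p,
                                      dimnames = list(NULL, paste0("f", 1:p))))
  expect_equal(unname(factor_scores(model, z)), unname(z %*% L),
               tolerance = 1e-12)
})

test_that("factor labels: planted drivers, single-feature, tie rule", {
  L <- matrix(c(0.9, 0.2, 0.1, 0.1, 0.1, 0.85), 3, 2,
              dimnames = list(c("alpha", "beta", "gamma"), NULL))
  m <- list(loadings = L)
  expect_identical(label_factors(m), c("alpha", "gamma"))
  expect_identical(label_factors(list(loadings = L[, 1, drop = FALSE])),
                   "alpha")
  # tie in |loading|: lower row index wins
  Lt <- matrix(c(0.5, -0.5, 0.1), 3, 1,
               dimnames = list(c("a", "b", "c"), NULL))
  expect_identical(label_factors(list(loadings = Lt)), "a")
})

test_that("scores are invariant to feature order and affine rescaling", {
  # well-determined planted 2-factor structure, n = 25 -> m = 2
  petclust:::with_seed(11, {
    n <- 25
    f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
    x <- cbind(f1 + 0.2 * stats::rnorm(n), f1 + 0.2 * stats::rnorm(n),
               f1 + 0.2 * stats::rnorm(n), f2 + 0.2 * stats::rnorm(n),
               f2 + 0.2 * stats::rnorm(n), f2 + 0.2 * stats::rnorm(n))
    colnames(x) <- paste0("f", 1:6)
    perm <- sample(6)
    mult <- stats::runif(6, 0.5, 2)
    offs <- stats::runif(6, -3, 3)
  })
  m1 <- suppressWarnings(dimred_fit(x))
  s1 <- factor_scores(m1, x)
  # column permutation: same scores once columns are matched by label
  m2 <- suppressWarnings(dimred_fit(x[, perm]))
  s2 <- factor_scores(m2, x[, perm])
  map <- match(m1$factor_labels, m2$factor_labels)
  expect_equal(abs(unname(s1)), abs(unname(s2[, map, drop = FALSE])),
               tolerance = 1e-6)
  # affine rescaling of raw features is absorbed by the scaler
  x_aff <- sweep(sweep(x, 2, mult, `*`), 2, offs, `+`)
  m3 <- suppressWarnings(dimred_fit(x_aff))
  s3 <- factor_scores(m3, x_aff)
  expect_equal(abs(unname(s1)), abs(unname(s3)), tolerance = 1e-6)
})
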