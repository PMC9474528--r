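# Per-training-fold unsupervised dimensionality reduction: z-scaling,
# Spearman redundancy filtering (rho = 0.95), orthogonally rotated factor
# analysis with the 1-factor-per-10-training-subjects rule, KMO sampling
# adequacy, and regression-type projection of test lesions onto the
# training factors. Everything is fitted on training data only.

#' Dimensionality-reduction configuration
#'
#' @param spearman_threshold redundancy cut-off on |Spearman rho|
#'   (default 0.95).
#' @param subjects_per_factor training subjects per retained factor
#'   (default 10; 32-lesion training folds retain 3 factors).
#' @param kmo_min adequacy threshold; values below it are warned about,
#'   never fatal (default 0.9).
#' @return List of class `dimred_config`.
#' @export
dimred_config <- function(spearman_threshold = 0.95,
                          subjects_per_factor = 10L, kmo_min = 0.9) {
  stopifnot(spearman_threshold > 0, spearman_threshold <= 1,
            subjects_per_factor >= 1)
  structure(list(spearman_threshold = spearman_threshold,
                 subjects_per_factor = as.integer(subjects_per_factor),
                 kmo_min = kmo_min),
            class = "dimred_config")
}

#' Fit / apply a z-scaler
#'
#' Column means and standard deviations (population convention, denominator
#' n, so scaled training columns have variance exactly 1) from the training
#' set; zero-variance columns are dropped with a warning. Test data are
#' transformed with training parameters only.
#'
#' @param x numeric matrix or data.frame of training features.
#' @return List of class `feature_scaler` with `mean`, `sd`, `features`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_ <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- sd_ > 1e-12
  if (!all(keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  if (!any(keep)) stop("no feature with positive variance")
  structure(list(mean = mu[keep], sd = sd_[keep],
                 features = colnames(x)[keep]),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `feature_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  missing <- setdiff(scaler$features, colnames(x))
  if (length(missing) > 0)
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  xs <- x[, scaler$features, drop = FALSE]
  sweep(sweep(xs, 2, scaler$mean), 2, scaler$sd, `/`)
}

#' Spearman redundancy filter
#'
#' Iteratively removes the feature with the greatest number of partners at
#' `|rho| >= threshold` (ties: larger mean absolute correlation, then lower
#' column index) until no pair exceeds the threshold.
#'
#' @param x scaled training feature matrix.
#' @param threshold Spearman cut-off (default 0.95).
#' @return Character vector of surviving feature names.
#' @export
redundancy_filter <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) return(colnames(x))
  r <- abs(stats::cor(x, method = "spearman"))
  diag(r) <- 0
  alive <- rep(TRUE, ncol(x))
  repeat {
    sub <- r[alive, alive, drop = FALSE]
    counts <- rowSums(sub >= threshold)
    if (max(counts) == 0) break
    worst <- which(counts == max(counts))
    if (length(worst) > 1L) {
      mac <- rowMeans(sub[worst, , drop = FALSE])
      worst <- worst[mac == max(mac)]
    }
    drop_name <- rownames(sub)[worst[1L]]
    alive[match(drop_name, colnames(r))] <- FALSE
  }
  colnames(r)[alive]
}

# Solve a (near-)singular symmetric matrix with escalating ridge; used for
# KMO and regression factor scores where training folds have p > n.
ridge_solve <- function(R, what = "matrix") {
  for (delta in c(0, 1e-8, 1e-6, 1e-4, 1e-2)) {
    Rr <- R + diag(delta, nrow(R))
    inv <- tryCatch(solve(Rr), error = function(e) NULL)
    if (!is.null(inv) && all(is.finite(inv))) {
      if (delta > 0) attr(inv, "ridge") <- delta
      return(inv)
    }
  }
  stop(what, " is singular even after ridge regularisation")
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal
#' entries, where `q` are the anti-image partial correlations from the
#' inverse correlation matrix. An identity correlation matrix has no
#' off-diagonal mass; the result is `NaN` with `attr(, "undefined")`.
#' Near-singular matrices are ridge-regularised (logged via
#' `attr(, "ridge")`).
#'
#' @param R correlation matrix.
#' @return KMO in \[0, 1\] (or flagged NaN).
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  off <- row(R) != col(R)
  r2 <- sum(R[off]^2)
  if (r2 == 0) {
    out <- NaN
    attr(out, "undefined") <- TRUE
    return(out)
  }
  inv <- ridge_solve(R, "correlation matrix")
  s <- diag(inv)
  Q <- -inv / sqrt(outer(s, s))
  q2 <- sum(Q[off]^2)
  out <- r2 / (r2 + q2)
  attr(out, "ridge") <- attr(inv, "ridge")
  out
}

#' Shrinkage estimate of a correlation matrix
#'
#' Training folds have more features than lesions, so the sample
#' correlation matrix is singular and regression factor scores computed
#' from its (pseudo)inverse do not generalise. Following the
#' radiomics-factor-modelling practice, the correlation matrix is shrunk
#' toward the identity, `R* = (1 - gamma) R + gamma I`, with the analytic
#' Schafer-Strimmer intensity
#' `gamma = sum_ij Var(r_ij) / sum_ij r_ij^2` (clamped to \[0, 1\]).
#'
#' @param x numeric matrix (n x p).
#' @return Shrunk correlation matrix with `attr(, "gamma")`.
#' @export
shrink_correlation <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  z <- scale(x)
  r <- stats::cor(x)
  z2 <- z^2
  sw2 <- crossprod(z2)                  # sum_k w_kij^2
  wbar <- crossprod(z) / n
  varr <- n / ((n - 1)^3) * (sw2 - n * wbar^2)
  off <- row(r) != col(r)
  denom <- sum(r[off]^2)
  gamma <- if (denom > 0) min(1, max(0, sum(varr[off]) / denom)) else 1
  rs <- (1 - gamma) * r
  diag(rs) <- 1
  attr(rs, "gamma") <- gamma
  rs
}

# Principal-axis factoring on a correlation matrix (handles p > n, where
# maximum-likelihood estimation fails on the singular matrix).
principal_axis <- function(R, m, max_iter = 200L, tol = 1e-6) {
  p <- nrow(R)
  inv <- tryCatch(ridge_solve(R), error = function(e) NULL)
  h2 <- if (!is.null(inv)) pmin(pmax(1 - 1 / diag(inv), 0.1), 0.995)
  else {
    r0 <- abs(R); diag(r0) <- 0
    apply(r0, 1, max)
  }
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(lam), m, m)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  rownames(L) <- rownames(R)
  L
}

#' Fit the orthogonally rotated factor model
#'
#' Common-factor model on the redundancy-filtered training correlation
#' matrix: maximum-likelihood extraction when it converges, principal-axis
#' fallback otherwise (always the case when features outnumber training
#' lesions), followed by varimax rotation. Factors are ordered by explained
#' variance (sum of squared loadings), and each column is signed so its
#' largest-magnitude loading is positive.
#'
#' @param x scaled, redundancy-filtered training feature matrix.
#' @param m number of factors.
#' @return List of class `factor_model_fit`: `loadings`
#'   (features x m), `m`, `estimator`, `R` (training correlation matrix).
#' @export
fit_factors <- function(x, m) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(m >= 1, n > m)
  R <- shrink_correlation(x)
  L <- NULL; estimator <- "ml"
  if (p > m) {
    fa <- tryCatch(
      stats::factanal(covmat = R, factors = m, n.obs = n,
                      rotation = "none"),
      error = function(e) NULL)
    if (!is.null(fa)) {
      L <- matrix(fa$loadings, p, m)
      rownames(L) <- colnames(x)
    }
  }
  if (is.null(L)) {
    estimator <- "principal_axis"
    L <- principal_axis(R, m)
  }
  if (m > 1L) {
    rot <- stats::varimax(L)
    L <- L %*% rot$rotmat
    rownames(L) <- colnames(x)
  }
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (k in seq_len(ncol(L))) {
    top <- which.max(abs(L[, k]))
    if (L[top, k] < 0) L[, k] <- -L[, k]
  }
  colnames(L) <- paste0("factor", seq_len(m))
  structure(list(loadings = L, m = m, estimator = estimator, R = R),
            class = "factor_model_fit")
}

#' Fit the complete per-fold dimensionality reduction
#'
#' Chains scaling, Spearman redundancy filtering, the floor(n/10) factor
#' rule, KMO and the rotated factor model into one training-fold artefact.
#'
#' @param x training feature matrix (raw scale).
#' @param config a [dimred_config()].
#' @return List of class `factor_model`: `scaler`, `retained_features`,
#'   `loadings`, `m`, `kmo`, `factor_labels`, `estimator`, `R`.
#' @export
dimred_fit <- function(x, config = dimred_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 training lesions")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  retained <- redundancy_filter(xs, config$spearman_threshold)
  xr <- xs[, retained, drop = FALSE]
  m <- max(1L, n %/% config$subjects_per_factor)
  m <- min(m, length(retained))
  fit <- fit_factors(xr, m)
  k <- kmo(fit$R)
  if (is.finite(k) && k < config$kmo_min)
    warning(sprintf("KMO %.3f below adequacy threshold %.2f", k,
                    config$kmo_min))
  model <- structure(list(
    scaler = scaler, retained_features = retained,
    loadings = fit$loadings, m = m, kmo = as.numeric(k),
    estimator = fit$estimator, R = fit$R
  ), class = "factor_model")
  model$factor_labels <- label_factors(model)
  model
}

#' Regression (Thomson) factor scores
#'
#' `scores = Z R^{-1} Lambda` with the training correlation matrix and
#' rotated loadings; the identical formula projects training and test
#' lesions.
#'
#' @param model a `factor_model` from [dimred_fit()].
#' @param x feature matrix (raw scale) containing all retained features.
#' @return n x m score matrix.
#' @export
factor_scores <- function(model, x) {
  stopifnot(inherits(model, "factor_model"))
  xs <- apply_scaler(model$scaler, as.matrix(x))
  missing <- setdiff(model$retained_features, colnames(xs))
  if (length(missing) > 0)
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  z <- xs[, model$retained_features, drop = FALSE]
  B <- ridge_solve(model$R, "training correlation matrix") %*% model$loadings
  s <- z %*% B
  colnames(s) <- colnames(model$loadings)
  s
}

#' Label factors by their best-corresponding feature
#'
#' Per factor, the retained feature with the maximum absolute loading
#' (ties: lower row index). Used for reporting and to define the
#' feature-based model.
#'
#' @param model a `factor_model` (or `factor_model_fit`).
#' @return Character vector of length m.
#' @export
label_factors <- function(model) {
  L <- model$loadings
  vapply(seq_len(ncol(L)),
         function(k) rownames(L)[which.max(abs(L[, k]))], "")
}
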