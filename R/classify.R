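# Stratified 5-fold multinomial classification over the model menu,
# Hand-Till multiclass AUC, and the label-shuffling sham experiment.
# Dimensionality reduction is refitted inside every training fold; nothing
# fitted on a training set ever sees a test lesion.

CLUSTER_LEVELS <- c("cluster1", "cluster2", "sporadic")
BIOCHEM_COLS <- c("adrenergic", "noradrenergic", "dopaminergic")

#' Model specification
#'
#' The evaluated model menu: the biochemical profile alone, SUVmax alone,
#' three PET factors, three PET/CT factors, the three PET features
#' labelling the PET factors, each optionally combined with the
#' biochemical profile (three dichotomous predictors).
#'
#' @param name one of `"biochem"`, `"suvmax"`, `"pet3factor"`,
#'   `"petct3factor"`, `"pet3feature"`.
#' @param biochem add the three biochemistry flags as predictors.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(name = c("biochem", "suvmax", "pet3factor",
                                "petct3factor", "pet3feature"),
                       biochem = FALSE) {
  name <- match.arg(name)
  if (name == "biochem") biochem <- FALSE
  label <- if (biochem) paste0(name, "+biochem") else name
  structure(list(name = name, biochem = biochem, label = label),
            class = "model_spec")
}

#' The full evaluated model menu
#'
#' The nine evaluated models: the biochemical profile alone, then SUVmax,
#' PET 3-factor, PET/CT 3-factor and PET 3-feature, each with and without
#' the biochemical profile.
#' @return List of [model_spec()] objects.
#' @export
model_menu <- function() {
  out <- list(model_spec("biochem"))
  for (nm in c("suvmax", "pet3factor", "petct3factor", "pet3feature"))
    out <- c(out, list(model_spec(nm, biochem = FALSE)),
             list(model_spec(nm, biochem = TRUE)))
  out
}

#' Stratified k-fold assignment
#'
#' Per-class counts per fold differ by at most 1 and overall fold sizes
#' differ by at most 1 (per-class remainders go to the currently smallest
#' folds). With 40 lesions and k = 5 every fold has 8 lesions and every
#' training set 32.
#'
#' @param labels class labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("k exceeds the number of lesions")
  classes <- unique(labels)
  cl_sizes <- vapply(classes, function(cl) sum(labels == cl), 0L)
  if (any(cl_sizes < k))
    message("stratification degraded: class(es) smaller than k")
  fold <- integer(n)
  with_seed(seed, {
    totals <- integer(k)
    for (cl in classes[order(cl_sizes, decreasing = TRUE)]) {
      idx <- sample(which(labels == cl))
      n_cl <- length(idx)
      base <- n_cl %/% k
      extra <- n_cl %% k
      counts <- rep(base, k)
      if (extra > 0) {
        recipients <- order(totals, seq_len(k))[seq_len(extra)]
        counts[recipients] <- counts[recipients] + 1L
      }
      fold[idx] <- rep(seq_len(k), counts)
      totals <- totals + counts
    }
  })
  fold
}

#' Ridge-penalised multinomial logistic regression
#'
#' Softmax-linear model maximising the multinomial likelihood with a small
#' fixed ridge penalty on the slopes only (intercepts unpenalised); the
#' penalty keeps the optimum finite under the perfect training separation
#' the strongest models reach, without materially changing probability
#' ranks.
#'
#' @param x predictor matrix (n x p, no intercept column).
#' @param y factor (or character) of class labels; >= 2 classes present.
#' @param lambda ridge penalty on slopes (default 1e-4).
#' @param maxit BFGS iteration cap.
#' @return List of class `multinomial_model`.
#' @export
fit_multinomial <- function(x, y, lambda = 1e-4, maxit = 1000L) {
  x <- as.matrix(x)
  if (is.null(x) || ncol(x) == 0L) x <- matrix(0, length(y), 0L)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes in the training fold")
  K <- nlevels(y)
  n <- nrow(x); p <- ncol(x)
  xa <- cbind(`(Intercept)` = 1, x)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  npar <- (p + 1L) * (K - 1L)
  slope_mask <- matrix(rep(c(FALSE, rep(TRUE, p)), K - 1L), p + 1L, K - 1L)
  obj <- function(theta) {
    B <- matrix(theta, p + 1L, K - 1L)
    eta <- cbind(0, xa %*% B)
    eta <- eta - apply(eta, 1, max)
    logZ <- log(rowSums(exp(eta)))
    nll <- -sum(eta[cbind(seq_len(n), as.integer(y))] - logZ)
    nll + lambda / 2 * sum((B * slope_mask)^2)
  }
  grad <- function(theta) {
    B <- matrix(theta, p + 1L, K - 1L)
    eta <- cbind(0, xa %*% B)
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta) / rowSums(exp(eta))
    G <- t(xa) %*% (P[, -1L, drop = FALSE] - Y[, -1L, drop = FALSE])
    as.vector(G + lambda * (B * slope_mask))
  }
  fit <- stats::optim(rep(0, npar), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (fit$convergence != 0)
    fit <- stats::optim(fit$par, obj, grad, method = "BFGS",
                        control = list(maxit = maxit * 4L, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("multinomial fit did not converge (code ", fit$convergence,
         ", value ", signif(fit$value, 6), ")")
  structure(list(beta = matrix(fit$par, p + 1L, K - 1L),
                 classes = levels(y), features = colnames(x),
                 lambda = lambda),
            class = "multinomial_model")
}

#' Predicted class probabilities
#' @param model a `multinomial_model`.
#' @param x predictor matrix with the training columns.
#' @return n x K matrix of probabilities summing to 1 per row.
#' @export
predict_multinomial <- function(model, x) {
  x <- as.matrix(x)
  if (length(model$features) > 0) x <- x[, model$features, drop = FALSE]
  else x <- matrix(0, nrow(x), 0L)
  eta <- cbind(0, cbind(1, x) %*% model$beta)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta) / rowSums(exp(eta))
  colnames(P) <- model$classes
  P
}

# Two-class rank AUC with mid-ranks: P(score_pos > score_neg) + 0.5 ties.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hand-Till pairwise AUC between two classes
#'
#' `A(i, j) = [A(i|j) + A(j|i)] / 2`, where `A(i|j)` is the rank AUC of the
#' class-i probability over the lesions of classes i and j (mid-ranks for
#' ties). Returns `NA` with a warning if either class is absent.
#'
#' @param probs n x K probability matrix with class-named columns.
#' @param labels class labels of the n lesions.
#' @param ci,cj the two class names.
#' @return A(i, j) in \[0, 1\], or NA.
#' @export
pairwise_auc <- function(probs, labels, ci, cj) {
  keep <- labels %in% c(ci, cj)
  if (sum(labels == ci) == 0L || sum(labels == cj) == 0L) {
    warning("pairwise AUC undefined: class absent (", ci, " vs ", cj, ")")
    return(NA_real_)
  }
  lab <- labels[keep]
  a_ij <- auc_rank(probs[keep, ci], lab == ci)
  a_ji <- auc_rank(probs[keep, cj], lab == cj)
  (a_ij + a_ji) / 2
}

#' Hand-Till multiclass AUC
#'
#' `M = 2 / (c (c - 1)) * sum_{i < j} A(i, j)`: the mean of the pairwise
#' AUCs. Undefined pairs propagate as NA.
#'
#' @param pairwise numeric vector of pairwise AUCs.
#' @return M.
#' @export
multiclass_auc <- function(pairwise) mean(pairwise)

all_pairs <- function(levels = CLUSTER_LEVELS) {
  cbind(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L))
}

eval_auc <- function(probs, labels) {
  pr <- all_pairs()
  a <- vapply(seq_len(nrow(pr)), function(r)
    pairwise_auc(probs, labels, CLUSTER_LEVELS[pr[r, 1]],
                 CLUSTER_LEVELS[pr[r, 2]]), 0)
  names(a) <- c("auc_c1_c2", "auc_c1_sp", "auc_c2_sp")
  c(a, multiclass = multiclass_auc(a))
}

# Build the predictor matrices for one fold under a model spec.
# Returns train/test matrices plus the fitted dimensionality-reduction
# artefact (NULL for specs that use none).
build_predictors <- function(features, spec, train_idx, config) {
  cols <- colnames(features)
  pet_cols <- grep("^PET_", cols, value = TRUE)
  ct_cols <- grep("^CT_", cols, value = TRUE)
  bio <- as.matrix(features[, BIOCHEM_COLS]) * 1
  dr <- NULL
  if (spec$name == "biochem") {
    tr <- bio[train_idx, , drop = FALSE]
    te <- bio[-train_idx, , drop = FALSE]
  } else if (spec$name == "suvmax") {
    x <- as.matrix(features[, "PET_firstorder_Maximum", drop = FALSE])
    sc <- fit_scaler(x[train_idx, , drop = FALSE])
    tr <- apply_scaler(sc, x[train_idx, , drop = FALSE])
    te <- apply_scaler(sc, x[-train_idx, , drop = FALSE])
    dr <- list(scaler = sc)
  } else if (spec$name %in% c("pet3factor", "petct3factor")) {
    fc <- if (spec$name == "pet3factor") pet_cols else c(pet_cols, ct_cols)
    x <- as.matrix(features[, fc])
    dr <- dimred_fit(x[train_idx, , drop = FALSE], config)
    tr <- factor_scores(dr, x[train_idx, , drop = FALSE])
    te <- factor_scores(dr, x[-train_idx, , drop = FALSE])
  } else {  # pet3feature: the features labelling the PET factors
    x <- as.matrix(features[, pet_cols])
    dr <- dimred_fit(x[train_idx, , drop = FALSE], config)
    sel <- dr$factor_labels
    xs_tr <- apply_scaler(dr$scaler, x[train_idx, , drop = FALSE])
    xs_te <- apply_scaler(dr$scaler, x[-train_idx, , drop = FALSE])
    tr <- xs_tr[, sel, drop = FALSE]
    te <- xs_te[, sel, drop = FALSE]
  }
  if (spec$biochem) {
    tr <- cbind(tr, bio[train_idx, , drop = FALSE])
    te <- cbind(te, bio[-train_idx, , drop = FALSE])
  }
  list(train = tr, test = te, dimred = dr)
}

#' Cross-validated evaluation of one model specification
#'
#' Stratified k-fold cross-validation with the full dimensionality
#' reduction (scaler, redundancy filter, factor model) refitted on every
#' training fold. Per-fold train and test pairwise and multiclass AUCs are
#' reported and averaged over folds (never pooled predictions).
#'
#' @param features feature table from [extract_cohort()] (columns:
#'   `cluster`, biochemistry flags, feature columns).
#' @param spec a [model_spec()].
#' @param config a [dimred_config()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold split.
#' @param keep_models keep per-fold artefacts (for audits / reports).
#' @return List of class `cv_result`: `per_fold` (data.frame),
#'   `mean_train`, `mean_test`, `spec`, `folds`, optionally `models`.
#' @export
run_cv <- function(features, spec, config = dimred_config(), k = 5L,
                   seed = 1L, keep_models = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  labels <- features$cluster
  folds <- make_folds(labels, k, seed)
  rows <- list(); models <- list()
  for (f in sort(unique(folds))) {
    train_idx <- which(folds != f)
    pred <- tryCatch(
      build_predictors(features, spec, train_idx, config),
      error = function(e) stop("fold ", f, " failed: ", conditionMessage(e)))
    y_tr <- labels[train_idx]; y_te <- labels[-train_idx]
    mdl <- fit_multinomial(pred$train, y_tr)
    p_tr <- predict_multinomial(mdl, pred$train)
    p_te <- predict_multinomial(mdl, pred$test)
    a_tr <- eval_auc(p_tr, y_tr)
    a_te <- eval_auc(p_te, y_te)
    rows[[f]] <- data.frame(fold = f, split = c("train", "test"),
                            rbind(a_tr, a_te), row.names = NULL)
    if (keep_models)
      models[[f]] <- list(dimred = pred$dimred, model = mdl,
                          train_idx = train_idx)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("auc_c1_c2", "auc_c1_sp", "auc_c2_sp", "multiclass")
  mean_split <- function(s)
    colMeans(per_fold[per_fold$split == s, metric_cols, drop = FALSE],
             na.rm = TRUE)
  out <- list(per_fold = per_fold, mean_train = mean_split("train"),
              mean_test = mean_split("test"), spec = spec, folds = folds,
              k = k, seed = seed)
  if (keep_models) out$models <- models
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$spec$label, " (k = ", x$k, ")\n", sep = "")
  cat("  mean test : ", paste(sprintf("%s=%.3f", names(x$mean_test),
                                      x$mean_test), collapse = "  "), "\n")
  cat("  mean train: ", paste(sprintf("%s=%.3f", names(x$mean_train),
                                      x$mean_train), collapse = "  "), "\n")
  invisible(x)
}

#' Sham (label-shuffling) experiment
#'
#' Uniformly permutes the cluster labels (class counts preserved) and
#' reruns the complete cross-validated pipeline -- including the per-fold
#' dimensionality reduction -- for each iteration and model specification.
#' Randomisation preserves the feature distributions and multicollinearity
#' and the outcome prevalence, but uncouples features from outcome, so mean
#' AUCs must come out at chance level.
#'
#' @param features feature table from [extract_cohort()].
#' @param specs list of [model_spec()] (default: the full menu).
#' @param iterations number of shuffles (default 100).
#' @param config a [dimred_config()].
#' @param k folds.
#' @param seed master seed; per-iteration seeds are derived.
#' @return List of class `sham_result`: `per_iteration` (iterations x
#'   specs matrix of mean test multiclass AUCs), `mean` (per spec).
#' @export
sham_experiment <- function(features, specs = model_menu(),
                            iterations = 100L, config = dimred_config(),
                            k = 5L, seed = 1L) {
  labels <- features$cluster
  n <- length(labels)
  spec_labels <- vapply(specs, `[[`, "", "label")
  M <- matrix(NA_real_, iterations, length(specs),
              dimnames = list(NULL, spec_labels))
  for (it in seq_len(iterations)) {
    it_seed <- derive_seed(seed, it)
    perm <- with_seed(it_seed, sample(n))
    shuffled <- features
    shuffled$cluster <- labels[perm]
    for (s in seq_along(specs)) {
      res <- tryCatch(
        run_cv(shuffled, specs[[s]], config, k,
               seed = derive_seed(it_seed, 1L)),
        error = function(e) NULL)
      if (is.null(res)) {   # one resample, then hard error
        perm2 <- with_seed(derive_seed(it_seed, 2L), sample(n))
        shuffled2 <- features
        shuffled2$cluster <- labels[perm2]
        res <- run_cv(shuffled2, specs[[s]], config, k,
                      seed = derive_seed(it_seed, 3L))
      }
      M[it, s] <- res$mean_test[["multiclass"]]
    }
  }
  structure(list(per_iteration = M, mean = colMeans(M),
                 iterations = iterations, seed = seed),
            class = "sham_result")
}
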