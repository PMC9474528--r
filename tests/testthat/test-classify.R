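# classify: folds, multinomial fit, Hand-Till AUCs, cross-validation,
# leakage audit, sham behaviour.

test_that("stratified folds: sizes, per-class balance, determinism", {
  labels <- c(rep("cluster1", 13), rep("cluster2", 18), rep("sporadic", 9))
  f <- make_folds(labels, k = 5, seed = 3)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 8))                     # every fold 8 lesions
  for (k in 1:5) expect_identical(sum(f != k), 32L)   # training sets of 32
  per_class <- table(labels, f)
  expect_true(all(apply(per_class, 1, function(r) max(r) - min(r) <= 1)))
  expect_identical(f, make_folds(labels, k = 5, seed = 3))
  expect_false(identical(f, make_folds(labels, k = 5, seed = 4)))

  # n = k: leave-one-out layout
  expect_identical(sort(make_folds(c("a", "a", "b", "b", "b"), k = 5,
                                   seed = 1)), 1:5)
  expect_error(make_folds(c("a", "b"), k = 5), "exceeds")
})

test_that("multinomial: separability, intercept-only, parameter recovery", {
  # perfectly separable 1-D predictor: training pairwise AUC 1
  y <- rep(c("cluster1", "cluster2"), each = 10)
  x <- matrix(c(stats::rnorm(10, 5), stats::rnorm(10, -5)), ncol = 1,
              dimnames = list(NULL, "v"))
  m <- fit_multinomial(x, y)
  p <- predict_multinomial(m, x)
  expect_equal(pairwise_auc(p, y, "cluster1", "cluster2"), 1)

  # intercept-only model: probabilities equal class frequencies
  y3 <- c(rep("a", 6), rep("b", 3), rep("c", 1))
  m0 <- fit_multinomial(matrix(0, 10, 0), y3)
  p0 <- predict_multinomial(m0, matrix(0, 10, 0))
  expect_equal(unname(p0[1, ]), c(0.6, 0.3, 0.1), tolerance = 1e-4)
  expect_equal(rowSums(p0), rep(1, 10))

  # planted 3-class softmax: coefficients recovered at large n, tiny lambda
  petclust:::with_seed(31, {
    n <- 8000
    X <- cbind(a = stats::rnorm(n), b = stats::rnorm(n))
    B_true <- rbind(c(0.3, -0.2), c(1.2, -0.8), c(-0.7, 1.0))  # int, a, b
    eta <- cbind(0, cbind(1, X) %*% B_true)
    P <- exp(eta) / rowSums(exp(eta))
    yy <- apply(P, 1, function(p) sample(c("k1", "k2", "k3"), 1, prob = p))
  })
  fit <- fit_multinomial(X, yy, lambda = 1e-8)
  expect_lt(max(abs(fit$beta[, 1] - B_true[, 1])), 3 * 2.5 / sqrt(n) * 3)
  expect_lt(max(abs(fit$beta - B_true)), 0.15)
})

test_that("pairwise AUC equals the concordant-pair oracle; ties give 0.5", {
  # identical scores: 0.5 by mid-ranks
  y <- c("cluster1", "cluster1", "cluster2", "cluster2")
  p_const <- matrix(0.5, 4, 3,
                    dimnames = list(NULL, c("cluster1", "cluster2",
                                            "sporadic")))
  expect_equal(pairwise_auc(p_const, y, "cluster1", "cluster2"), 0.5)

  # 6-lesion toy with ties, frozen scores, vs exhaustive pair counting
  yy <- c("cluster1", "cluster1", "cluster2", "cluster2", "cluster2",
          "cluster1")
  p1 <- c(0.8, 0.6, 0.6, 0.2, 0.4, 0.3)
  p2 <- c(0.1, 0.3, 0.35, 0.7, 0.4, 0.5)
  probs <- cbind(cluster1 = p1, cluster2 = p2, sporadic = 1 - p1 - p2)
  expect_equal(pairwise_auc(probs, yy, "cluster1", "cluster2"),
               oracle_hand_till(p1, p2, yy, "cluster1", "cluster2"),
               tolerance = 1e-12)

  # random score sets vs oracle
  for (seed in 1:5) {
    petclust:::with_seed(seed, {
      n <- 20
      lab <- sample(c("cluster1", "cluster2"), n, replace = TRUE,
                    prob = c(.5, .5))
      if (length(unique(lab)) < 2) lab[1:2] <- c("cluster1", "cluster2")
      s1 <- round(stats::runif(n), 1)   # rounded: exercises ties
      s2 <- round(stats::runif(n), 1)
    })
    pr <- cbind(cluster1 = s1, cluster2 = s2, sporadic = 0)
    expect_equal(pairwise_auc(pr, lab, "cluster1", "cluster2"),
                 oracle_hand_till(s1, s2, lab, "cluster1", "cluster2"),
                 tolerance = 1e-12)
  }

  # absent class: NA with warning
  expect_warning(
    a <- pairwise_auc(p_const, c("cluster1", "cluster1", "cluster1",
                                 "cluster1"), "cluster1", "cluster2"),
    "absent")
  expect_true(is.na(a))
})

test_that("pairwise AUC is symmetric in class roles; M symmetric", {
  petclust:::with_seed(2, {
    lab <- sample(c("cluster1", "cluster2"), 14, replace = TRUE)
    lab[1:2] <- c("cluster1", "cluster2")
    pr <- matrix(stats::runif(14 * 3), 14, 3,
                 dimnames = list(NULL, c("cluster1", "cluster2",
                                         "sporadic")))
  })
  expect_equal(pairwise_auc(pr, lab, "cluster1", "cluster2"),
               pairwise_auc(pr, lab, "cluster2", "cluster1"))
  expect_equal(multiclass_auc(c(1.0, 0.9, 0.7)), 0.8666667,
               tolerance = 1e-6)
  expect_equal(multiclass_auc(c(1, 1, 1)), 1)
  # random scores at large n: M -> 0.5
  petclust:::with_seed(3, {
    n <- 3000
    lab3 <- sample(c("cluster1", "cluster2", "sporadic"), n, replace = TRUE)
    pr3 <- matrix(stats::runif(n * 3), n, 3,
                  dimnames = list(NULL, c("cluster1", "cluster2",
                                          "sporadic")))
  })
  ev <- petclust:::eval_auc(pr3, lab3)
  expect_lt(abs(ev[["multiclass"]] - 0.5), 0.03)
})

test_that("run_cv separates a planted strong signal and nulls without one", {
  feats <- toy_feature_table(delta = 3)
  cv <- run_cv(feats, model_spec("pet3factor"), k = 5, seed = 4)
  expect_gte(cv$mean_test[["auc_c1_c2"]], 0.95)
  # train >= test on average for the overfitting-prone combined model
  cvb <- run_cv(feats, model_spec("pet3factor", biochem = TRUE), k = 5,
                seed = 4)
  expect_gte(cvb$mean_train[["multiclass"]], cvb$mean_test[["multiclass"]])

  # labels independent of features: chance level
  null_feats <- toy_feature_table(delta = 0, seed = 123)
  ms <- vapply(1:6, function(s)
    run_cv(null_feats, model_spec("suvmax"), k = 5,
           seed = s)$mean_test[["multiclass"]], 0)
  expect_lt(abs(mean(ms) - 0.5), 0.12)
})

test_that("no leakage: mutating a test-fold lesion leaves training artefacts", {
  feats <- toy_feature_table()
  cv <- suppressWarnings(run_cv(feats, model_spec("pet3factor"), k = 5,
                                seed = 9, keep_models = TRUE))
  target_fold <- cv$folds[1]   # lesion 1 is a test lesion of its own fold
  mutated <- feats
  fcols <- grep("^PET_", colnames(feats))
  mutated[1, fcols] <- mutated[1, fcols] * 10 + 5
  cv2 <- suppressWarnings(run_cv(mutated, model_spec("pet3factor"), k = 5,
                                 seed = 9, keep_models = TRUE))
  m_a <- cv$models[[target_fold]]
  m_b <- cv2$models[[target_fold]]
  expect_identical(m_a$train_idx, m_b$train_idx)
  expect_identical(m_a$dimred$scaler, m_b$dimred$scaler)
  expect_identical(m_a$dimred$retained_features,
                   m_b$dimred$retained_features)
  expect_identical(m_a$dimred$loadings, m_b$dimred$loadings)
  expect_identical(m_a$model$beta, m_b$model$beta)
})

test_that("sham: identity shuffle reproduces, fixed seed reproduces", {
  feats <- toy_feature_table(n1 = 8, n2 = 9, ns = 6, delta = 2)
  # identity permutation: same AUC as the unpermuted run
  base <- run_cv(feats, model_spec("suvmax"), k = 3, seed = 5)
  same <- feats; same$cluster <- feats$cluster[seq_len(nrow(feats))]
  again <- run_cv(same, model_spec("suvmax"), k = 3, seed = 5)
  expect_identical(base$mean_test, again$mean_test)

  sh1 <- sham_experiment(feats, list(model_spec("suvmax")), iterations = 3,
                         k = 3, seed = 77)
  sh2 <- sham_experiment(feats, list(model_spec("suvmax")), iterations = 3,
                         k = 3, seed = 77)
  expect_identical(sh1$per_iteration, sh2$per_iteration)
  expect_identical(dim(sh1$per_iteration), c(3L, 1L))
})

test_that("model menu matches the evaluated set", {
  menu <- model_menu()
  expect_length(menu, 9L)
  labels <- vapply(menu, `[[`, "", "label")
  expect_identical(labels[1], "biochem")
  expect_true(all(c("suvmax", "suvmax+biochem", "pet3factor",
                    "pet3factor+biochem", "petct3factor",
                    "petct3factor+biochem", "pet3feature",
                    "pet3feature+biochem") %in% labels))
})
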