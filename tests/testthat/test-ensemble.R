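test_that("AUC weights normalize and order correctly", {
  w <- auc_weights(c(0.8, 0.8, 0.8, 0.8))
  expect_equal(w$weight, rep(0.25, 4))
  w2 <- auc_weights(c(a = 0.9, b = 0.6))
  expect_equal(w2$weight, c(0.6, 0.4))
  expect_equal(w2$learner, c("a", "b"))
  set.seed(1)
  for (rep in 1:20) {
    h <- runif(4, 0.5, 1)
    expect_equal(sum(auc_weights(h)$weight), 1, tolerance = 1e-12)
  }
  expect_error(auc_weights(c(0.5, 0)), class = "pcgstack_invalid_input")
  expect_error(auc_weights(c(0.5, 1.2)), class = "pcgstack_invalid_input")
})

test_that("meta inputs are columnwise weighted posteriors", {
  P <- matrix(runif(20), 5, 4)
  Z <- build_meta_input(P, rep(0.25, 4))
  expect_equal(Z, P / 4)
  expect_equal(build_meta_input(matrix(c(0.5, 0.5), 1), c(0.6, 0.4)),
               matrix(c(0.30, 0.20), 1), tolerance = 1e-12)
  P0 <- cbind(P[, 1:3], 0)
  expect_true(all(build_meta_input(P0, rep(0.25, 4))[, 4] == 0))
  # bound: 0 <= zeta <= weight
  w <- auc_weights(c(0.9, 0.8, 0.7, 0.6))$weight
  Zw <- build_meta_input(P, w)
  expect_true(all(Zw >= 0 & Zw <= rep(w, each = 5)))
  expect_error(build_meta_input(P, c(0.5, 0.5)),
               class = "pcgstack_invalid_input")
})

test_that("out-of-fold stacking defeats a memorizing learner", {
  # the canary: predicts 1 exactly when the row was in its training data;
  # in-fold it would look perfect, out-of-fold it must collapse to chance
  d <- make_informative_features(n = 100, p = 5, k_inf = 0, seed = 21)
  subjects <- sprintf("s%03d", 1:100)
  memorizer <- list(
    kind = "custom",
    data = d$X,
    fit = function(X, y) {
      keys <- apply(round(X, 8), 1, paste, collapse = "|")
      keys[y > 0]
    },
    score = function(model, X) {
      keys <- apply(round(X, 8), 1, paste, collapse = "|")
      as.numeric(keys %in% model)
    }
  )
  st <- out_of_fold_stack(list(mem = memorizer), d$y, subjects,
                          K = 5, seed = 2)
  expect_gte(st$aucs[["mem"]], 0.35)
  expect_lte(st$aucs[["mem"]], 0.65)
  # while the same learner scored in-fold is perfect
  fit_all <- memorizer$fit(d$X, d$y)
  expect_equal(roc_auc(memorizer$score(fit_all, d$X), d$y), 1)
})

test_that("out-of-fold structure partitions training rows by subject", {
  d <- make_informative_features(n = 60, p = 8, k_inf = 3, seed = 22)
  subjects <- rep(sprintf("s%02d", 1:20), each = 3)
  st <- out_of_fold_stack(
    list(rf = list(kind = "deep_pca_rf", data = d$X)),
    d$y, subjects, K = 4, seed = 3)
  expect_equal(dim(st$oof), c(60, 1))
  expect_true(all(is.finite(st$oof)))
  # folds respect subjects and cover everything
  expect_equal(sort(unique(st$folds)), 1:4)
  expect_true(all(tapply(st$folds, subjects, function(v) length(unique(v))) == 1))
  expect_error(
    out_of_fold_stack(list(rf = list(kind = "deep_pca_rf", data = d$X)),
                      d$y, rep("s1", 60), K = 4, seed = 1),
    class = "pcgstack_invalid_config")
})

test_that("the meta MLP fits separable data deterministically", {
  set.seed(31)
  n <- 200
  Z <- matrix(runif(n * 4), n, 4)
  y <- ifelse(Z[, 1] + Z[, 2] > Z[, 3] + Z[, 4], 1, -1)
  m <- train_mlp(Z, y, hidden = c(32, 16), seed = 5)
  p <- predict(m, Z)
  expect_gte(mean((p > 0.5) == (y > 0)), 0.95)
  expect_true(all(p >= 0 & p <= 1))
  m2 <- train_mlp(Z, y, hidden = c(32, 16), seed = 5)
  expect_identical(predict(m2, Z), p)
  expect_length(predict(m, Z[0, , drop = FALSE]), 0)
  expect_error(train_mlp(Z, rep(1, n)), class = "pcgstack_invalid_input")
  expect_error(predict(m, Z[, 1:3]), class = "pcgstack_invalid_input")
})

test_that("fused prediction pipes posteriors through weights and meta", {
  d <- make_informative_features(n = 90, p = 12, k_inf = 6, effect = 2,
                                 seed = 41)
  subjects <- rep(sprintf("s%02d", 1:30), each = 3)
  specs <- list(
    a = list(kind = "deep_pca_rf", data = d$X),
    b = list(kind = "texture_svm_rfe", data = d$X,
             params = list(n_select = 6))
  )
  model <- fit_stacked_ensemble(specs, d$y, subjects, K = 3, seed = 7,
                                hidden = c(16, 8))
  expect_equal(sum(model$weights$weight), 1, tolerance = 1e-12)
  sets <- list(a = d$X, b = d$X)
  p <- predict_ensemble(model, sets)$p_pos
  expect_length(p, 90)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(roc_auc(p, d$y), 0.9)
  # determinism of the fitted model
  expect_equal(predict_ensemble(model, sets)$p_pos, p)
  # empty batch -> empty output
  empty <- list(a = d$X[0, , drop = FALSE], b = d$X[0, , drop = FALSE])
  expect_equal(nrow(predict_ensemble(model, empty)), 0)
  # tidiers
  td <- tidy(model)
  expect_equal(names(td), c("learner", "auc", "weight"))
  expect_equal(nrow(glance(model)), 1)
})

test_that("baseline strategies reduce as the algebra says", {
  # identical base posteriors: voting returns them unchanged
  d <- make_informative_features(n = 60, p = 6, k_inf = 3, seed = 51)
  subjects <- sprintf("s%03d", 1:60)
  specs <- list(a = list(kind = "deep_pca_rf", data = d$X),
                b = list(kind = "deep_pca_rf", data = d$X))
  model <- fit_stacked_ensemble(specs, d$y, subjects, K = 3, seed = 9,
                                strategy = "voting")
  expect_equal(mean(c(0.2, 0.4, 0.6, 0.8)), 0.5) # soft-vote arithmetic
  P <- pcgstack:::ensemble_base_posteriors(model, list(a = d$X, b = d$X))
  v <- predict_ensemble(model, list(a = d$X, b = d$X))$p_pos
  expect_equal(v, rowMeans(P), tolerance = 1e-12)
  # equal AUCs: weighted meta-input equals plain input scaled by 1/mu
  h_equal <- c(0.8, 0.8, 0.8)
  w <- auc_weights(h_equal)
  Pm <- matrix(runif(30), 10, 3)
  expect_equal(build_meta_input(Pm, w), Pm / 3, tolerance = 1e-12)
  # all-ones posterior row maps to the weight vector itself
  w4 <- auc_weights(c(0.9, 0.8, 0.7, 0.6))
  expect_equal(as.numeric(build_meta_input(matrix(1, 1, 4), w4)),
               w4$weight)
})
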