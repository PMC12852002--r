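test_that("SVM-RFE recovers informative features on ground-truth data", {
  hits <- 0
  for (seed in 1:10) {
    d <- make_informative_features(n = 120, p = 50, k_inf = 5,
                                   effect = 0.8, seed = seed)
    lr <- train_texture_svm_rfe(d$X, d$y, n_select = 10, seed = seed)
    expect_length(lr$selected, 10)
    if (sum(lr$selected <= 5) >= 4) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("the RFE path is nested and posteriors are proper", {
  d <- make_informative_features(seed = 3)
  lr <- train_texture_svm_rfe(d$X, d$y, n_select = 5, seed = 1)
  path <- lr$rfe_path # smallest set first
  for (i in seq_len(length(path) - 1)) {
    expect_true(all(path[[i]] %in% path[[i + 1]]))
  }
  p <- predict_posterior(lr, d$X)$p_pos
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_texture_svm_rfe(d$X, rep(1, nrow(d$X))),
               class = "pcgstack_invalid_input")
  expect_error(train_texture_svm_rfe(d$X, d$y, n_select = 100),
               class = "pcgstack_invalid_input")
  # identical samples get identical posteriors; empty input, empty output
  pp <- predict_posterior(lr, d$X[c(1, 1), ])$p_pos
  expect_equal(pp[1], pp[2])
  expect_length(predict_posterior(lr, d$X[0, , drop = FALSE])$p_pos, 0)
})

test_that("PCA-RF separates separable data and is seed-deterministic", {
  d <- make_informative_features(n = 100, p = 20, k_inf = 20, effect = 3,
                                 seed = 5)
  lr <- train_deep_pca_rf(d$X, d$y, seed = 2)
  p <- predict_posterior(lr, d$X)$p_pos
  expect_gte(roc_auc(p, d$y), 0.99)
  lr2 <- train_deep_pca_rf(d$X, d$y, seed = 2)
  expect_equal(predict_posterior(lr2, d$X)$p_pos, p)
  expect_error(train_deep_pca_rf(d$X, rep(-1, 100)),
               class = "pcgstack_invalid_input")
})

test_that("label-shuffled PCA-RF stays near chance out of fold", {
  d <- make_informative_features(n = 120, p = 20, k_inf = 5, seed = 6)
  set.seed(9)
  y_perm <- sample(d$y)
  subjects <- sprintf("s%03d", seq_along(y_perm)) # one segment per subject
  st <- out_of_fold_stack(
    list(rf = list(kind = "deep_pca_rf", data = d$X)),
    y_perm, subjects, K = 5, seed = 3)
  expect_gte(st$aucs[["rf"]], 0.35)
  expect_lte(st$aucs[["rf"]], 0.65)
})

test_that("Platt calibration preserves ranking and improves the Brier score", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 300
    s <- rnorm(n)
    y <- ifelse(runif(n) < 1 / (1 + exp(-3 * s)), 1, -1)
    # a miscalibrated but monotone raw score
    raw <- pmin(pmax(0.5 + 0.08 * s, 0), 1)
    map <- pcgstack:::platt_fit(s, y)
    cal <- pcgstack:::platt_apply(map, s)
    expect_equal(roc_auc(cal, y), roc_auc(s, y), tolerance = 1e-12)
    expect_true(all(cal >= 0 & cal <= 1))
    brier <- function(p) mean((p - (y > 0))^2)
    if (brier(cal) <= brier(raw) + 0.01) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("calibrate() refits on held-out data without changing AUC", {
  d <- make_informative_features(n = 200, seed = 11)
  tr <- 1:120; va <- 121:200
  lr <- train_texture_svm_rfe(d$X[tr, ], d$y[tr], n_select = 10, seed = 4)
  p_before <- predict_posterior(lr, d$X[va, ])$p_pos
  lr2 <- calibrate(lr, d$X[va, ], d$y[va])
  p_after <- predict_posterior(lr2, d$X[va, ])$p_pos
  expect_equal(roc_auc(p_after, d$y[va]), roc_auc(p_before, d$y[va]),
               tolerance = 1e-12)
  expect_error(calibrate(lr, d$X[va, ], rep(1, 80)),
               class = "pcgstack_invalid_input")
  expect_error(predict_posterior(structure(list(), class = "list"), d$X),
               class = "pcgstack_state_error")
})

test_that("no leakage: a label-equal validation feature cannot help", {
  # canary: append a feature equal to the label on validation rows only;
  # training-fold statistics must never see it aligned with val labels
  d <- make_informative_features(n = 120, p = 10, k_inf = 0, seed = 12)
  set.seed(13)
  subjects <- sprintf("s%03d", 1:120)
  canary <- d$y # perfectly informative column...
  X <- cbind(d$X, canary = canary)
  y_indep <- sample(d$y) # ...but the labels used are independent of it
  st <- out_of_fold_stack(
    list(svm = list(kind = "texture_svm_rfe", data = X,
                    params = list(n_select = 5))),
    y_indep, subjects, K = 5, seed = 5)
  expect_lt(st$aucs[["svm"]], 0.7)
})
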