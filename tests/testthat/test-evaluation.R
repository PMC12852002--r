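test_that("roc_auc equals the all-pairs oracle and handles edge cases", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(-1, -1, -1, 1, 1, 1)), 1)
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(round(rnorm(n), 1)) # coarse -> ties occur
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(-1, 1)
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # independent scores hover at one half
  set.seed(62)
  s <- rnorm(2000); y <- sample(c(-1, 1), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep(1, 5)), class = "pcgstack_invalid_input")
})

test_that("roc_auc agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(63)
  for (rep in 1:10) {
    s <- rnorm(60); y <- sample(c(-1, 1), 60, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("binary metrics reproduce hand confusion-matrix arithmetic", {
  # TP=3, FP=1, FN=1, TN=5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  labels <- c(1, 1, 1, -1, 1, -1, -1, -1, -1, -1)
  m <- binary_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  # all correct -> all ones
  perfect <- binary_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, -1, -1))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1", "auc")]) == 1))
  # no predicted positives -> precision 0, flagged
  none <- binary_metrics(c(0.1, 0.2, 0.3, 0.4), c(1, -1, 1, -1))
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)
  # F1 identity on random confusion matrices
  set.seed(64)
  for (rep in 1:100) {
    y <- sample(c(-1, 1), 40, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    s <- runif(40)
    mm <- binary_metrics(s, y)
    if (mm$precision + mm$sensitivity > 0) {
      expect_equal(mm$f1, 2 * mm$precision * mm$sensitivity /
                           (mm$precision + mm$sensitivity), tolerance = 1e-12)
    }
  }
})

test_that("the DeLong test is symmetric with exact degenerate behavior", {
  set.seed(65)
  z <- rnorm(60)
  y <- ifelse(z + rnorm(60) > 0, 1, -1)
  sa <- z + rnorm(60, 0, 0.5)
  sb <- z + rnorm(60, 0, 0.8)
  same <- delong_test(sa, sa, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  ab <- delong_test(sa, sb, y)
  ba <- delong_test(sb, sa, y)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$z, -ba$z)
  expect_error(delong_test(sa, sb[1:10], y), class = "pcgstack_invalid_input")
})

test_that("DeLong agrees with pROC and a paired-bootstrap oracle", {
  skip_if_not_installed("pROC")
  set.seed(66)
  n <- 50
  z <- rnorm(n)
  y <- ifelse(z + rnorm(n, 0, 0.8) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
  sa <- z + rnorm(n, 0, 0.6)
  sb <- 0.5 * z + rnorm(n, 0, 0.9)
  got <- delong_test(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(got$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
  boot_p <- oracle_bootstrap_delong_p(sa, sb, y, reps = 10000, seed = 4)
  expect_lt(abs(got$p_value - boot_p), 0.03)
})

test_that("DeLong null p-values are approximately uniform", {
  set.seed(67)
  pv <- numeric(500)
  for (i in 1:500) {
    n <- 80
    z <- rnorm(n)
    y <- ifelse(z + rnorm(n) > 0, 1, -1)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    # equally informative, correlated scores
    sa <- z + rnorm(n)
    sb <- z + rnorm(n)
    pv[i] <- delong_test(sa, sb, y)$p_value
  }
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("the AUC interval covers and clips correctly", {
  ci <- auc_ci(c(1, 2, 3, 11, 12, 13), c(-1, -1, -1, 1, 1, 1))
  expect_equal(unname(ci["upper"]), 1)
  set.seed(68)
  s <- rnorm(100); y <- ifelse(s + rnorm(100) > 0, 1, -1)
  a <- roc_auc(s, y)
  ci2 <- auc_ci(s, y)
  expect_lte(ci2["lower"], a)
  expect_gte(ci2["upper"], a)
  # coverage at the nominal level for a known AUC of 0.8
  mu <- sqrt(2) * qnorm(0.8)
  hits <- 0
  for (i in 1:1000) {
    scores <- c(rnorm(50, mu), rnorm(50, 0))
    labels <- rep(c(1, -1), each = 50)
    ci3 <- auc_ci(scores, labels)
    if (ci3["lower"] <= 0.8 && 0.8 <= ci3["upper"]) hits <- hits + 1
  }
  expect_gte(hits / 1000, 0.925)
  expect_lte(hits / 1000, 0.975)
})

test_that("subject splits are grouped, stratified and deterministic", {
  cfg <- sim_config(n_subjects_per_class = 20, segments_per_subject = 3,
                    duration_s = 0.2, seed = 5)
  ds <- simulate_pcg_dataset(cfg)
  sp <- subject_stratified_split(ds, 0.7, seed = 3)
  expect_setequal(unique(sp$partition), c("train", "test"))
  counts <- table(sp$label, sp$partition)
  expect_equal(unname(counts[, "train"]), c(14, 14))
  # no subject on both sides (subjects appear once in the plan)
  expect_equal(anyDuplicated(sp$subject_id), 0)
  sp2 <- subject_stratified_split(ds, 0.7, seed = 3)
  expect_identical(sp, sp2)
  tiny <- dplyr::filter(ds, subject_id %in% c("neg001", "pos001"))
  expect_error(subject_stratified_split(tiny), class = "pcgstack_invalid_input")
})

test_that("the Youden threshold maximizes sensitivity + specificity", {
  set.seed(69)
  s <- c(rnorm(50, 1.5), rnorm(50, 0))
  y <- rep(c(1, -1), each = 50)
  th <- youden_threshold(s, y)
  j_at <- function(t) mean(s[y > 0] >= t) + mean(s[y < 0] < t) - 1
  expect_true(all(j_at(th) >= vapply(s, j_at, numeric(1)) - 1e-12))
})
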