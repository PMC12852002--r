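# The heterogeneous stacking ensemble.
#
# Four calibrated base learners feed a second-order meta-learner. Each
# learner mu gets a weight
#
#   w_mu = h_mu / sum(h)          (h_mu = its validation AUC)
#
# and the meta-learner input for a sample is the columnwise weighted
# posterior zeta[, mu] = w_mu * P[, mu].  The validation AUC is the pooled
# out-of-fold AUC on the training set: folds are grouped by subject and
# stratified by label, each base learner predicts every training sample
# from a model that never saw any segment of that sample's subject, and
# final learners are refitted on the full training set.  Two baselines
# share the machinery: soft voting (unweighted mean of calibrated
# posteriors, no meta-learner) and plain stacking (weights forced to 1).

#' AUC-proportional ensemble weights
#'
#' @param h Validation AUCs of the base learners, each in (0, 1].
#' @return Tibble with `learner`, `auc`, `weight`; weights sum to 1 and are
#'   proportional to the AUCs.
#' @export
auc_weights <- function(h) {
  auc <- if (is.data.frame(h)) h$auc else as.numeric(h)
  nm <- if (is.data.frame(h) && !is.null(h$learner)) {
    h$learner
  } else if (!is.null(names(h))) {
    names(h)
  } else {
    sprintf("learner_%d", seq_along(auc))
  }
  if (any(!is.finite(auc)) || any(auc <= 0) || any(auc > 1)) {
    rlang::abort("validation AUCs must lie in (0, 1].",
                 class = "pcgstack_invalid_input")
  }
  tibble::tibble(learner = nm, auc = auc, weight = auc / sum(auc))
}

#' Weighted meta-learner inputs
#'
#' Scales column `mu` of the posterior matrix by the `mu`-th weight.
#'
#' @param P Samples x learners matrix of positive-class posteriors.
#' @param weights Output of [auc_weights()] (or a bare weight vector).
#' @return Matrix of the same shape, entries in `[0, w_mu]`.
#' @export
build_meta_input <- function(P, weights) {
  w <- if (is.data.frame(weights)) weights$weight else as.numeric(weights)
  P <- as.matrix(P)
  if (ncol(P) != length(w)) {
    rlang::abort("posterior matrix width must equal the number of weights.",
                 class = "pcgstack_invalid_input")
  }
  sweep(P, 2, w, "*")
}

# subject-grouped, label-stratified K folds; returns fold id per row
subject_folds <- function(subjects, y, K, seed) {
  y <- as_label_pm1(y)
  subj_label <- tapply(y, subjects, function(v) v[1])
  fold_of_subject <- with_local_seed(seed, {
    out <- integer(0)
    nm <- character(0)
    for (cl in c(-1, 1)) {
      ss <- names(subj_label)[subj_label == cl]
      if (length(ss) == 0) next
      ss <- sample(ss)
      out <- c(out, rep_len(seq_len(K), length(ss)))
      nm <- c(nm, ss)
    }
    stats::setNames(out, nm)
  })
  if (min(table(fold_of_subject)) < 1 || length(unique(subjects)) < K) {
    rlang::abort("fewer subjects than folds.", class = "pcgstack_invalid_config")
  }
  unname(fold_of_subject[as.character(subjects)])
}

# fit one base learner from its spec on given rows
fit_base_spec <- function(spec, rows, seed) {
  X <- spec$data[rows, , drop = FALSE]
  y <- spec$y[rows]
  switch(spec$kind,
    texture_svm_rfe = do.call(train_texture_svm_rfe,
      c(list(X = X, y = y, seed = seed), spec$params %||% list())),
    deep_pca_rf = do.call(train_deep_pca_rf,
      c(list(F = X, y = y, seed = seed), spec$params %||% list())),
    custom = {
      fit <- spec$fit(X, y)
      structure(list(kind = "custom", fit = fit, score = spec$score,
                     calibration = list(a = -1, b = 0),
                     validation_auc = NA_real_),
                class = "pcg_base_learner")
    },
    rlang::abort("unknown base learner kind.", class = "pcgstack_invalid_config")
  )
}

#' Out-of-fold stacking of the base learners
#'
#' @param base_specs Named list of base-learner specs; each spec is a list
#'   with `kind` (`"texture_svm_rfe"`, `"deep_pca_rf"` or `"custom"`),
#'   `data` (its feature matrix/tibble, training rows), optional `params`,
#'   and for `custom` the functions `fit(X, y)` and `score(model, X)`.
#' @param y Training labels (-1/+1), one per row of every `data`.
#' @param subjects Subject id per training row; folds never split a
#'   subject.
#' @param K Number of folds.
#' @param seed Integer seed.
#' @return List: `learners` (refit on all rows, calibrated on pooled OOF
#'   scores, `validation_auc` filled in), `oof` (n x mu posterior matrix),
#'   `aucs` (pooled OOF AUC per learner), `folds` (fold id per row).
#' @export
out_of_fold_stack <- function(base_specs, y, subjects, K = 5, seed = 1) {
  y <- check_two_classes(y)
  n <- length(y)
  if (K < 2) rlang::abort("K must be >= 2.", class = "pcgstack_invalid_config")
  for (sp in base_specs) sp$y <- NULL
  base_specs <- lapply(base_specs, function(sp) {
    sp$y <- y
    sp$data <- as_feature_matrix(sp$data)
    if (nrow(sp$data) != n) {
      rlang::abort("base learner data rows must match length(y).",
                   class = "pcgstack_invalid_input")
    }
    sp
  })
  folds <- subject_folds(subjects, y, K, seed)
  mu <- length(base_specs)
  oof_raw <- matrix(NA_real_, n, mu)
  for (k in seq_len(K)) {
    tr <- which(folds != k)
    te <- which(folds == k)
    if (length(te) == 0) next
    for (m in seq_len(mu)) {
      lf <- fit_base_spec(base_specs[[m]], tr, derive_seed(seed, k, m))
      oof_raw[te, m] <- learner_raw_score(lf,
        base_specs[[m]]$data[te, , drop = FALSE])
    }
  }
  # pooled OOF calibration + AUC, then refit on the full training set
  learners <- vector("list", mu)
  oof <- matrix(NA_real_, n, mu)
  aucs <- numeric(mu)
  for (m in seq_len(mu)) {
    cal <- platt_fit(oof_raw[, m], y)
    oof[, m] <- platt_apply(cal, oof_raw[, m])
    aucs[m] <- roc_auc(oof[, m], y)
    lf <- fit_base_spec(base_specs[[m]], seq_len(n), derive_seed(seed, 0L, m))
    lf$calibration <- cal
    lf$validation_auc <- aucs[m]
    learners[[m]] <- lf
  }
  nm <- names(base_specs) %||% sprintf("learner_%d", seq_len(mu))
  names(learners) <- nm
  colnames(oof) <- nm
  list(learners = learners, oof = oof,
       aucs = stats::setNames(aucs, nm), folds = folds)
}

#' Fit the stacked ensemble on a training set
#'
#' Runs out-of-fold stacking, derives AUC weights, and trains the fusion
#' head of the requested strategy on the out-of-fold posteriors:
#' `weighted_stacking` trains the MLP on weight-scaled posteriors,
#' `plain_stacking` on unscaled posteriors, `voting` needs no training.
#'
#' @inheritParams out_of_fold_stack
#' @param strategy One of `"weighted_stacking"`, `"plain_stacking"`,
#'   `"voting"`.
#' @param hidden Meta-MLP hidden layer sizes.
#' @return Object of class `pcg_stacked_ensemble`.
#' @export
fit_stacked_ensemble <- function(base_specs, y, subjects, K = 5, seed = 1,
                                 strategy = "weighted_stacking",
                                 hidden = c(256, 128, 64)) {
  strategy <- match.arg(strategy,
                        c("weighted_stacking", "plain_stacking", "voting"))
  st <- out_of_fold_stack(base_specs, y, subjects, K = K, seed = seed)
  w <- auc_weights(st$aucs)
  meta <- NULL
  if (strategy == "weighted_stacking") {
    meta <- train_mlp(build_meta_input(st$oof, w), y, hidden = hidden,
                      seed = derive_seed(seed, 99L))
  } else if (strategy == "plain_stacking") {
    meta <- train_mlp(st$oof, y, hidden = hidden,
                      seed = derive_seed(seed, 99L))
  }
  structure(list(learners = st$learners, weights = w, meta = meta,
                 strategy = strategy, oof = st$oof, folds = st$folds,
                 K = K, seed = seed),
            class = "pcg_stacked_ensemble")
}

# base posterior matrix on new data; feature sets given per learner name
ensemble_base_posteriors <- function(model, feature_sets) {
  nm <- names(model$learners)
  P <- matrix(NA_real_, nrow(as_feature_matrix(feature_sets[[nm[1]]])),
              length(nm))
  for (m in seq_along(nm)) {
    P[, m] <- predict_posterior(model$learners[[m]], feature_sets[[nm[m]]])$p_pos
  }
  colnames(P) <- nm
  P
}

#' Predict ensemble posteriors
#'
#' @param model A fitted [fit_stacked_ensemble()].
#' @param feature_sets Named list of feature matrices/tibbles, one per base
#'   learner (names matching the fit).
#' @param strategy Override the fitted strategy (only meaningful when the
#'   fitted object holds the required fusion head).
#' @return Tibble with `p_pos`.
#' @export
predict_ensemble <- function(model, feature_sets, strategy = NULL) {
  if (!inherits(model, "pcg_stacked_ensemble")) {
    rlang::abort("model is not a fitted stacked ensemble.",
                 class = "pcgstack_state_error")
  }
  strategy <- strategy %||% model$strategy
  P <- ensemble_base_posteriors(model, feature_sets)
  if (nrow(P) == 0) return(tibble::tibble(p_pos = numeric(0)))
  p <- switch(strategy,
    voting = rowMeans(P),
    plain_stacking = {
      if (is.null(model$meta)) {
        rlang::abort("no meta-learner fitted for stacking.",
                     class = "pcgstack_state_error")
      }
      predict(model$meta, P)
    },
    weighted_stacking = {
      if (is.null(model$meta)) {
        rlang::abort("no meta-learner fitted for stacking.",
                     class = "pcgstack_state_error")
      }
      predict(model$meta, build_meta_input(P, model$weights))
    },
    rlang::abort("unknown strategy.", class = "pcgstack_invalid_config")
  )
  tibble::tibble(p_pos = as.numeric(p))
}

#' @export
print.pcg_stacked_ensemble <- function(x, ...) {
  cat(sprintf("<pcg_stacked_ensemble: %s, %d base learners, K = %d>\n",
              x$strategy, length(x$learners), x$K))
  print(x$weights)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-learner summary of a stacked ensemble
#'
#' @param x A `pcg_stacked_ensemble`.
#' @param ... Unused.
#' @return Tibble with `learner`, `auc` (pooled out-of-fold), `weight`.
#' @export
tidy.pcg_stacked_ensemble <- function(x, ...) x$weights

#' One-row summary of a stacked ensemble
#'
#' @param x A `pcg_stacked_ensemble`.
#' @param ... Unused.
#' @return Tibble with the strategy, fold count, number of learners, and
#'   the out-of-fold AUC of the fused posterior on the training set.
#' @export
glance.pcg_stacked_ensemble <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    n_learners = length(x$learners),
    K = x$K,
    mean_base_auc = mean(x$weights$auc),
    max_base_auc = max(x$weights$auc)
  )
}
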