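# First-order base learners.
#
# Two kinds: an RFE-SVM over texture features (recursive feature
# elimination ranked by linear-SVM weight magnitudes, final RBF SVM on the
# survivors) and a PCA + random forest over deep features.  Both expose
# calibrated positive-class posteriors: raw scores (SVM decision values /
# forest vote fractions) go through a Platt sigmoid fitted either on the
# training scores (default) or on held-out scores via calibrate().  Platt
# scaling is monotone, so calibration never changes a learner's AUC.

# ---- Platt sigmoid calibration ----

# Fit p(y=+1 | s) = 1 / (1 + exp(a*s + b)) by regularized logistic
# regression with Platt's smoothed targets (avoids divergence on
# separable scores).
platt_fit <- function(scores, y) {
  y <- as_label_pm1(y)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  tt <- ifelse(y > 0, t_pos, t_neg)
  a <- 0; b <- log((n_neg + 1) / (n_pos + 1))
  for (it in 1:100) {
    f <- a * scores + b
    p <- 1 / (1 + exp(f))
    g <- tt - p # d(-loglik)/df with this parametrization
    w <- pmax(p * (1 - p), 1e-12)
    H <- rbind(c(sum(w * scores^2) + 1e-10, sum(w * scores)),
               c(sum(w * scores), sum(w) + 1e-10))
    gr <- c(sum(g * scores), sum(g))
    step <- solve(H, gr)
    a <- a - step[1]; b <- b - step[2]
    if (max(abs(step)) < 1e-10) break
  }
  list(a = a, b = b)
}

platt_apply <- function(map, scores) 1 / (1 + exp(map$a * scores + map$b))

# ---- SVM-RFE texture learner ----

svm_weights <- function(model) {
  # primal weights of a linear SVM: w = t(coefs) %*% SV
  as.numeric(crossprod(model$coefs, model$SV))
}

#' Train the texture RFE-SVM base learner
#'
#' Features are z-scored with training statistics; recursive feature
#' elimination ranks features by squared linear-SVM weights, dropping
#' `rfe_step` of the remainder each round until `n_select` survive; the
#' final RBF-kernel SVM is trained on the survivors. Posteriors come from
#' Platt scaling of the decision values.
#'
#' @param X Feature matrix or tibble (numeric columns used).
#' @param y Labels in -1/+1.
#' @param n_select Number of features to keep.
#' @param rfe_step Fraction of remaining features removed per round.
#' @param cost SVM cost parameter.
#' @param gamma RBF kernel width (default `1/n_select`).
#' @param seed Integer seed.
#' @return Object of class `pcg_base_learner` (kind `texture_svm_rfe`).
#' @export
train_texture_svm_rfe <- function(X, y, n_select = 20, rfe_step = 0.1,
                                  cost = 1, gamma = NULL, seed = 1) {
  Xm <- as_feature_matrix(X)
  y <- check_two_classes(y)
  if (n_select > ncol(Xm)) {
    rlang::abort("n_select exceeds the feature count.",
                 class = "pcgstack_invalid_input")
  }
  scaler <- fit_scaler(Xm)
  Xs <- apply_scaler(scaler, Xm)
  yf <- factor(y, levels = c(-1, 1))

  selected <- seq_len(ncol(Xs))
  path <- list(selected)
  with_local_seed(seed, {
    while (length(selected) > n_select) {
      lin <- e1071::svm(Xs[, selected, drop = FALSE], yf, kernel = "linear",
                        cost = cost, scale = FALSE)
      w2 <- svm_weights(lin)^2
      n_drop <- min(max(1L, ceiling(rfe_step * length(selected))),
                    length(selected) - n_select)
      selected <- selected[order(w2, decreasing = TRUE)[
        seq_len(length(selected) - n_drop)]]
      selected <- sort(selected)
      path[[length(path) + 1L]] <- selected
    }
  })
  if (is.null(gamma)) gamma <- 1 / length(selected)
  fit <- with_local_seed(derive_seed(seed, 2L), {
    e1071::svm(Xs[, selected, drop = FALSE], yf, kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
  })
  dv <- raw_decision_values(fit, Xs[, selected, drop = FALSE])
  structure(list(kind = "texture_svm_rfe", scaler = scaler,
                 selected = selected, rfe_path = rev(path), fit = fit,
                 calibration = platt_fit(dv, y),
                 feature_names = colnames(Xm), validation_auc = NA_real_),
            class = "pcg_base_learner")
}

# decision values oriented so larger = more positive class
raw_decision_values <- function(fit, X) {
  pr <- predict(fit, X, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  # libsvm orients the decision value toward the first training class
  if (colnames(attr(pr, "decision.values"))[1] == "-1/1") dv <- -dv
  dv
}

# ---- PCA + random forest learner ----

#' Train a PCA + random-forest base learner on deep features
#'
#' PCA is fitted on the training features only (keeping
#' `variance_fraction` of variance); a random forest is trained on the
#' scores. Raw scores are out-of-bag-style vote fractions, passed through
#' Platt scaling.
#'
#' @param F Deep feature matrix or tibble.
#' @param y Labels in -1/+1.
#' @param variance_fraction PCA retained-variance target.
#' @param ntree Number of trees.
#' @param seed Integer seed.
#' @return Object of class `pcg_base_learner` (kind `deep_pca_rf`).
#' @export
train_deep_pca_rf <- function(F, y, variance_fraction = 0.95, ntree = 500,
                              seed = 1) {
  Fm <- as_feature_matrix(F)
  y <- check_two_classes(y)
  pca <- fit_pca(Fm, variance_fraction)
  S <- transform_pca(pca, Fm)
  yf <- factor(y, levels = c(-1, 1))
  fit <- with_local_seed(seed, {
    randomForest::randomForest(S, yf, ntree = ntree)
  })
  votes <- predict(fit, S, type = "prob")[, "1"]
  structure(list(kind = "deep_pca_rf", pca = pca, fit = fit,
                 calibration = platt_fit(votes, y),
                 validation_auc = NA_real_),
            class = "pcg_base_learner")
}

# raw (pre-calibration) score of a base learner, larger = more positive
learner_raw_score <- function(learner, X) {
  Xm <- as_feature_matrix(X)
  if (nrow(Xm) == 0) return(numeric(0))
  switch(learner$kind,
    texture_svm_rfe = {
      Xs <- apply_scaler(learner$scaler, Xm)
      raw_decision_values(learner$fit, Xs[, learner$selected, drop = FALSE])
    },
    deep_pca_rf = {
      S <- transform_pca(learner$pca, Xm)
      predict(learner$fit, S, type = "prob")[, "1"]
    },
    custom = learner$score(learner$fit, Xm),
    rlang::abort("unknown learner kind.", class = "pcgstack_invalid_input")
  )
}

#' Calibrate a base learner on held-out data
#'
#' Refits the Platt sigmoid on validation scores. The map is monotone, so
#' the learner's ranking (and AUC) is unchanged; only the probability
#' scale moves.
#'
#' @param learner A `pcg_base_learner`.
#' @param X_val,y_val Held-out features and labels (both classes present).
#' @return The learner with an updated calibration map.
#' @export
calibrate <- function(learner, X_val, y_val) {
  y_val <- check_two_classes(y_val)
  s <- learner_raw_score(learner, X_val)
  learner$calibration <- platt_fit(s, y_val)
  learner
}

#' Calibrated positive-class posteriors of a base learner
#'
#' @param learner A fitted `pcg_base_learner`.
#' @param X Feature matrix/tibble.
#' @return Tibble with `p_pos` (and implicitly `p_neg = 1 - p_pos`).
#' @export
predict_posterior <- function(learner, X) {
  if (!inherits(learner, "pcg_base_learner")) {
    rlang::abort("learner is not a fitted pcg_base_learner.",
                 class = "pcgstack_state_error")
  }
  s <- learner_raw_score(learner, X)
  tibble::tibble(p_pos = platt_apply(learner$calibration, s))
}

#' @export
print.pcg_base_learner <- function(x, ...) {
  cat(sprintf("<pcg_base_learner: %s%s>\n", x$kind,
              if (is.finite(x$validation_auc)) {
                sprintf(", OOF AUC %.3f", x$validation_auc)
              } else ""))
  invisible(x)
}
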