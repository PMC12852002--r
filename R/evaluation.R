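# Evaluation protocol: subject-grouped stratified splits, the binary
# metric panel, ROC AUC with DeLong variance, and the DeLong test for
# correlated ROC curves.

#' ROC AUC (Mann-Whitney)
#'
#' The probability that a random positive scores above a random negative,
#' ties counted one half — computed from midranks.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Labels in -1/+1 (or 0/1).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- check_two_classes(labels)
  r <- rank(scores)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  (sum(r[y > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half), and vice versa.
delong_placements <- function(scores, labels) {
  y <- as_label_pm1(labels)
  pos <- scores[y > 0]; neg <- scores[y < 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  v_pos <- (r_all[seq_len(m)] - r_pos) / n          # V10
  v_neg <- 1 - (r_all[m + seq_len(n)] - r_neg) / m  # V01
  list(v_pos = v_pos, v_neg = v_neg, auc = mean(v_pos))
}

#' DeLong variance of a single AUC
#' @keywords internal
delong_var <- function(scores, labels) {
  pl <- delong_placements(scores, labels)
  stats::var(pl$v_pos) / length(pl$v_pos) +
    stats::var(pl$v_neg) / length(pl$v_neg)
}

#' DeLong confidence interval for an AUC
#'
#' Normal approximation with the DeLong variance, clipped to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @param level Confidence level.
#' @return Named vector `c(lower, upper)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  y <- check_two_classes(labels)
  a <- roc_auc(scores, y)
  se <- sqrt(delong_var(scores, y))
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = max(0, a - z * se), upper = min(1, a + z * se))
}

#' DeLong test for two correlated ROC curves
#'
#' Both score sets must rate the same samples. Uses the placement-value
#' covariance estimate; the statistic is
#' `z = (AUC_A - AUC_B) / sqrt(var(AUC_A - AUC_B))` against a standard
#' normal.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared labels in -1/+1.
#' @return Tibble with `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- check_two_classes(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y)) {
    rlang::abort("score vectors and labels must have equal length.",
                 class = "pcgstack_invalid_input")
  }
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- length(pa$v_pos); n <- length(pa$v_neg)
  s10 <- stats::cov(cbind(pa$v_pos, pb$v_pos))
  s01 <- stats::cov(cbind(pa$v_neg, pb$v_neg))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= 1e-300) {
    if (abs(delta) < 1e-12) {
      return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = 0,
                            z = 0, p_value = 1))
    }
    rlang::abort("zero variance with unequal AUCs; DeLong test undefined.",
                 class = "pcgstack_degenerate_input")
  }
  z <- delta / sqrt(var_delta)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Confusion-matrix metric panel
#'
#' Thresholded metrics plus AUC with its DeLong confidence interval.
#' Precision with no predicted positives is reported as 0 and flagged.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold on the scores.
#' @param ci_level Confidence level for the AUC interval.
#' @return One-row tibble: `auc`, `auc_lower`, `auc_upper`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `threshold`,
#'   `n_pos`, `n_neg`, `precision_defined`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5,
                           ci_level = 0.95) {
  y <- check_two_classes(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y > 0); fp <- sum(pred & y < 0)
  fn <- sum(!pred & y > 0); tn <- sum(!pred & y < 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec_def <- (tp + fp) > 0
  prec <- if (prec_def) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  ci <- auc_ci(scores, y, ci_level)
  tibble::tibble(
    auc = roc_auc(scores, y), auc_lower = ci["lower"], auc_upper = ci["upper"],
    accuracy = (tp + tn) / length(y),
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    threshold = threshold, n_pos = sum(y > 0), n_neg = sum(y < 0),
    precision_defined = prec_def
  )
}

#' Subject-grouped stratified train/test split
#'
#' Splits at the subject level (every segment of a subject lands on one
#' side) with per-class subject counts matching the ratio to within one.
#'
#' @param dataset Dataset tibble with `subject_id` and `label`.
#' @param ratio Training fraction of subjects per class.
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `label`, `partition`
#'   (`"train"`/`"test"`).
#' @export
subject_stratified_split <- function(dataset, ratio = 0.7, seed = 1) {
  subj <- dplyr::distinct(dataset, .data$subject_id, .data$label)
  if (any(table(subj$label) < 2)) {
    rlang::abort("need at least 2 subjects per class.",
                 class = "pcgstack_invalid_input")
  }
  with_local_seed(seed, {
    subj <- dplyr::group_by(subj, .data$label)
    subj <- dplyr::mutate(subj, .ord = sample.int(dplyr::n()))
    subj <- dplyr::mutate(subj,
      partition = ifelse(.data$.ord <= round(ratio * dplyr::n()),
                         "train", "test"))
    dplyr::select(dplyr::ungroup(subj), -".ord")
  })
}

#' Youden-optimal threshold
#'
#' Threshold maximizing sensitivity + specificity - 1 over the observed
#' scores.
#'
#' @inheritParams roc_auc
#' @return A single threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  y <- check_two_classes(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    sens <- mean(scores[y > 0] >= th)
    spec <- mean(scores[y < 0] < th)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Plot an ROC curve from scores
#'
#' @inheritParams roc_auc
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  y <- check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  tpr <- c(0, cumsum(ys > 0) / sum(ys > 0))
  fpr <- c(0, cumsum(ys < 0) / sum(ys < 0))
  df <- tibble::tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", roc_auc(scores, y))) +
    ggplot2::theme_minimal()
}
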