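# End-to-end pipeline wiring: raw recordings -> preprocessing ->
# gammatonegram -> {texture features, deep features x 3 backbones} ->
# calibrated base learners -> out-of-fold stacking -> AUC-weighted MLP
# fusion -> held-out evaluation.

#' Pipeline configuration
#'
#' Nested configuration for every stage, with a single global seed from
#' which all stage seeds derive. The three deep backbones default to
#' `desk_default` featurizers with different seeds, standing in for the
#' architectural diversity of distinct pretrained CNNs; swapping in real
#' backbones is a configuration change only.
#'
#' @param seed Global integer seed.
#' @param preprocess A [preprocess_config()].
#' @param n_channels,fmin,fmax Gammatone filterbank shape.
#' @param frame_s,hop_s Spectrogram frame length and hop (seconds).
#' @param image_size Gray-image size fed to the deep backbones.
#' @param texture_image_size Gray-image size for texture analysis (texture
#'   statistics saturate well below CNN input resolution).
#' @param dynamic_range_db Image dynamic range (dB).
#' @param n_levels Texture quantization levels.
#' @param n_select RFE-SVM selected feature count.
#' @param variance_fraction PCA retained variance for the deep learners.
#' @param ntree Random-forest size.
#' @param K Stacking folds.
#' @param ratio Train fraction of subjects per class.
#' @param strategy Fusion strategy.
#' @param hidden Meta-MLP hidden layers.
#' @param threshold Classification threshold on the fused posterior.
#' @param youden Use the Youden-optimal threshold (estimated on training
#'   out-of-fold posteriors) instead of `threshold`.
#' @return List of class `pcg_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            preprocess = preprocess_config(),
                            n_channels = 64, fmin = 20, fmax = 1000,
                            frame_s = 0.025, hop_s = 0.010,
                            image_size = c(224, 224),
                            texture_image_size = c(128, 128),
                            dynamic_range_db = 60,
                            n_levels = 32,
                            n_select = 20,
                            variance_fraction = 0.95,
                            ntree = 500,
                            K = 5, ratio = 0.7,
                            strategy = "weighted_stacking",
                            hidden = c(256, 128, 64),
                            threshold = 0.5,
                            youden = FALSE) {
  structure(as.list(environment()), class = "pcg_pipeline_config")
}

#' Compute all per-recording features of a dataset
#'
#' Preprocesses every recording, builds its gammatonegram, and extracts
#' the texture feature table and the three deep feature matrices. Feature
#' extraction is strictly per-recording, so it can run once before any
#' train/test split without leakage (all cross-sample statistics live
#' inside the learners).
#'
#' @param dataset Dataset tibble (`segment_id`, `subject_id`, `label`,
#'   `fs`, `samples`).
#' @param config A [pipeline_config()].
#' @return List with `texture` (tibble), `deep` (named list of 3 feature
#'   tibbles), `ids`, `labels`, `subjects`.
#' @export
compute_pcg_features <- function(dataset, config = pipeline_config()) {
  pp <- preprocess_pcg(dataset, config$preprocess)
  fs <- config$preprocess$target_fs
  bank <- gammatone_filterbank(fs, config$n_channels, config$fmin,
                               min(config$fmax, fs / 2 - 1))
  frame_len <- round(config$frame_s * fs)
  hop <- round(config$hop_s * fs)
  tex_imgs <- vector("list", nrow(pp))
  deep_imgs <- vector("list", nrow(pp))
  for (i in seq_len(nrow(pp))) {
    G <- compute_gammatonegram(pp$samples[[i]], fs, bank, frame_len, hop)
    tex_imgs[[i]] <- gammatonegram_image(G, config$dynamic_range_db,
                                         config$texture_image_size)
    deep_imgs[[i]] <- gammatonegram_image(G, config$dynamic_range_db,
                                          config$image_size)
  }
  texture <- extract_texture_features(tex_imgs, ids = pp$segment_id,
                                      n_levels = config$n_levels)
  backbones <- lapply(1:3, function(b) {
    backbone_spec("desk_default", seed = derive_seed(config$seed, 1000L, b))
  })
  names(backbones) <- paste0("deep_", 1:3)
  deep <- lapply(backbones, function(sp) {
    extract_deep_features(deep_imgs, sp, ids = pp$segment_id)
  })
  list(texture = texture, deep = deep, ids = pp$segment_id,
       labels = pp$label, subjects = pp$subject_id)
}

# assemble base-learner specs for given training rows
pipeline_base_specs <- function(features, rows, config) {
  c(
    list(texture = list(kind = "texture_svm_rfe",
                        data = features$texture[rows, , drop = FALSE],
                        params = list(n_select = config$n_select))),
    lapply(features$deep, function(Fm) {
      list(kind = "deep_pca_rf", data = Fm[rows, , drop = FALSE],
           params = list(variance_fraction = config$variance_fraction,
                         ntree = config$ntree))
    })
  )
}

#' Run the full training and evaluation pipeline
#'
#' Splits subjects 7:3 (stratified by class), fits the stacking ensemble
#' on the training segments with K-fold out-of-fold stacking, and reports
#' the metric panel on the held-out test segments.
#'
#' @inheritParams compute_pcg_features
#' @param features Optional precomputed [compute_pcg_features()] output
#'   (reused across repeats; per-recording features are split-independent).
#' @param split Optional precomputed [subject_stratified_split()].
#' @return Object of class `pcg_pipeline_fit`: `model`, `split`,
#'   `metrics` (one-row tibble), `test_scores` tibble, `weights`, `config`.
#' @export
run_pcg_pipeline <- function(dataset, config = pipeline_config(),
                             features = NULL, split = NULL) {
  if (is.null(features)) features <- compute_pcg_features(dataset, config)
  if (is.null(split)) {
    split <- subject_stratified_split(dataset, config$ratio,
                                      derive_seed(config$seed, 11L))
  }
  train_subj <- split$subject_id[split$partition == "train"]
  tr <- which(features$subjects %in% train_subj)
  te <- which(!features$subjects %in% train_subj)
  specs <- pipeline_base_specs(features, tr, config)
  model <- fit_stacked_ensemble(specs, features$labels[tr],
                                features$subjects[tr],
                                K = config$K,
                                seed = derive_seed(config$seed, 21L),
                                strategy = config$strategy,
                                hidden = config$hidden)
  test_sets <- list(texture = features$texture[te, , drop = FALSE])
  for (nm in names(features$deep)) {
    test_sets[[nm]] <- features$deep[[nm]][te, , drop = FALSE]
  }
  names(test_sets) <- names(model$learners)
  p <- predict_ensemble(model, test_sets)$p_pos
  thr <- config$threshold
  if (isTRUE(config$youden)) {
    oof_fused <- switch(model$strategy,
      voting = rowMeans(model$oof),
      weighted_stacking = predict(model$meta,
        build_meta_input(model$oof, model$weights)),
      plain_stacking = predict(model$meta, model$oof))
    thr <- youden_threshold(oof_fused, features$labels[tr])
  }
  metrics <- binary_metrics(p, features$labels[te], threshold = thr)
  structure(list(
    model = model, split = split, metrics = metrics,
    test_scores = tibble::tibble(segment_id = features$ids[te],
                                 subject_id = features$subjects[te],
                                 label = features$labels[te], p_pos = p),
    weights = model$weights, config = config
  ), class = "pcg_pipeline_fit")
}

#' @export
print.pcg_pipeline_fit <- function(x, ...) {
  cat("<pcg_pipeline_fit>\n")
  print(x$weights)
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.pcg_pipeline_fit <- function(x, ...) x$weights

#' @export
glance.pcg_pipeline_fit <- function(x, ...) x$metrics

#' Repeat the split / fit / evaluate protocol
#'
#' Fresh subject-stratified splits, independent stacking fits, averaged
#' test metrics. Features are computed once (they are split-independent).
#'
#' @inheritParams run_pcg_pipeline
#' @param repeats Number of repetitions.
#' @return List: `mean` (averaged metric row), `per_repeat` (tibble with
#'   `repeat_index` and the metric panel), `seeds`.
#' @export
repeated_evaluation <- function(dataset, config = pipeline_config(),
                                repeats = 10, features = NULL) {
  if (is.null(features)) features <- compute_pcg_features(dataset, config)
  per <- vector("list", repeats)
  seeds <- integer(repeats)
  for (r in seq_len(repeats)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, 500L, r)
    seeds[r] <- cfg_r$seed
    fit <- run_pcg_pipeline(dataset, cfg_r, features = features)
    per[[r]] <- dplyr::mutate(fit$metrics, repeat_index = r,
                              .before = 1)
  }
  per <- dplyr::bind_rows(per)
  num <- vapply(per, is.numeric, logical(1))
  mean_row <- tibble::as_tibble(as.list(colMeans(per[, num])))
  mean_row$repeat_index <- NULL
  list(mean = mean_row, per_repeat = per, seeds = seeds)
}

#' Compare fusion strategies on identical splits and base learners
#'
#' Runs the out-of-fold stacking once, then evaluates soft voting, plain
#' stacking and AUC-weighted stacking with identical upstream state, plus
#' pairwise DeLong tests between the strategies' test-set ROC curves.
#'
#' @inheritParams run_pcg_pipeline
#' @return List: `metrics` (tibble, one row per strategy), `delong`
#'   (pairwise comparisons), `weights`.
#' @export
run_strategy_comparison <- function(dataset, config = pipeline_config(),
                                    features = NULL, split = NULL) {
  if (is.null(features)) features <- compute_pcg_features(dataset, config)
  if (is.null(split)) {
    split <- subject_stratified_split(dataset, config$ratio,
                                      derive_seed(config$seed, 11L))
  }
  train_subj <- split$subject_id[split$partition == "train"]
  tr <- which(features$subjects %in% train_subj)
  te <- which(!features$subjects %in% train_subj)
  specs <- pipeline_base_specs(features, tr, config)
  st <- out_of_fold_stack(specs, features$labels[tr], features$subjects[tr],
                          K = config$K, seed = derive_seed(config$seed, 21L))
  w <- auc_weights(st$aucs)
  meta_seed <- derive_seed(config$seed, 99L)
  meta_w <- train_mlp(build_meta_input(st$oof, w), features$labels[tr],
                      hidden = config$hidden, seed = meta_seed)
  meta_p <- train_mlp(st$oof, features$labels[tr],
                      hidden = config$hidden, seed = meta_seed)
  test_sets <- list(texture = features$texture[te, , drop = FALSE])
  for (nm in names(features$deep)) {
    test_sets[[nm]] <- features$deep[[nm]][te, , drop = FALSE]
  }
  shell <- structure(list(learners = st$learners, weights = w,
                          strategy = "voting", meta = NULL),
                     class = "pcg_stacked_ensemble")
  P <- ensemble_base_posteriors(shell, test_sets)
  scores <- list(
    voting = rowMeans(P),
    plain_stacking = predict(meta_p, P),
    weighted_stacking = predict(meta_w, build_meta_input(P, w))
  )
  y_te <- features$labels[te]
  metrics <- dplyr::bind_rows(lapply(names(scores), function(snm) {
    dplyr::mutate(binary_metrics(scores[[snm]], y_te,
                                 threshold = config$threshold),
                  strategy = snm, .before = 1)
  }))
  pairs <- utils::combn(names(scores), 2, simplify = FALSE)
  delong <- dplyr::bind_rows(lapply(pairs, function(pr) {
    dplyr::mutate(delong_test(scores[[pr[1]]], scores[[pr[2]]], y_te),
                  strategy_a = pr[1], strategy_b = pr[2], .before = 1)
  }))
  list(metrics = metrics, delong = delong, weights = w, scores = scores,
       labels = y_te)
}
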