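# Deep-feature extraction stage: a pluggable backbone interface.
#
# The pretrained CNN backbones (ResNet50, DenseNet121, InceptionResNetV2,
# fine-tuned with Adam / batch 16 / 120 epochs / lr 1e-4 and early
# stopping) are supported as configuration only; they need external weights
# and are deliberately not silently substituted.  The `desk_default`
# backbone is a deterministic seeded random-projection convolutional
# featurizer: the image is downsampled to a small grid, cut into patches,
# each patch is projected through a fixed Gaussian filter bank with a ReLU,
# and features are global mean- and max-pooled over patches.  Random
# convolutional features of this kind are a standard cheap stand-in for
# learned representations and preserve exactly what the downstream
# ensemble needs: a deterministic image-to-vector map that separates
# populations differing in band energy.

#' Backbone specification
#'
#' @param name One of `"desk_default"`, `"resnet50"`, `"densenet121"`,
#'   `"inception_resnet_v2"`. Only `desk_default` runs without external
#'   pretrained weights.
#' @param output_dim Feature dimension (even; half mean-pooled, half
#'   max-pooled channels).
#' @param seed Seed for the fixed random filter bank (`desk_default`).
#' @param fine_tune Fine-tune a CNN backbone (configuration only).
#' @param train_settings Optimizer settings used when fine-tuning a CNN
#'   backbone (Adam, batch size 16, 120 epochs, learning rate 1e-4,
#'   early-stopping patience 10).
#' @return List of class `pcg_backbone_spec`.
#' @export
backbone_spec <- function(name = "desk_default", output_dim = 64, seed = 1,
                          fine_tune = FALSE,
                          train_settings = list(optimizer = "adam",
                                                batch_size = 16,
                                                epochs = 120,
                                                learning_rate = 1e-4,
                                                patience = 10)) {
  name <- match.arg(name, c("desk_default", "resnet50", "densenet121",
                            "inception_resnet_v2"))
  if (output_dim %% 2 != 0 || output_dim <= 0) {
    rlang::abort("output_dim must be a positive even integer.",
                 class = "pcgstack_invalid_config")
  }
  structure(list(name = name, output_dim = as.integer(output_dim),
                 seed = as.integer(seed), fine_tune = fine_tune,
                 train_settings = train_settings),
            class = "pcg_backbone_spec")
}

desk_filters <- function(spec, patch = 8L) {
  k <- spec$output_dim %/% 2L
  with_local_seed(spec$seed, {
    list(W = matrix(rnorm(k * patch * patch) / patch, k, patch * patch),
         b = rnorm(k, 0, 0.1))
  })
}

#' Extract deep features from a batch of gray images
#'
#' @param images List of equally sized gray image matrices in \[0, 1\].
#' @param spec A [backbone_spec()].
#' @param ids Optional sample identifiers.
#' @return Tibble: `segment_id` plus `output_dim` feature columns named
#'   `deep_001`, ... No NaN/Inf; identical images give identical rows.
#' @export
extract_deep_features <- function(images, spec = backbone_spec(), ids = NULL) {
  if (length(images) == 0) {
    rlang::abort("empty image batch.", class = "pcgstack_invalid_input")
  }
  if (spec$name != "desk_default") {
    rlang::abort(
      sprintf(paste0("backbone '%s' needs pretrained weights that are not ",
                     "bundled; configure an external weight source or use ",
                     "'desk_default'."), spec$name),
      class = "pcgstack_unavailable_backbone")
  }
  patch <- 8L
  grid <- 32L
  flt <- desk_filters(spec, patch)
  rows <- lapply(images, function(img) {
    small <- resize_bilinear(img, grid, grid)
    # non-overlapping patches, column-major order
    np <- grid %/% patch
    pv <- matrix(0, patch * patch, np * np)
    idx <- 1L
    for (pc in seq_len(np)) {
      for (pr in seq_len(np)) {
        blk <- small[((pr - 1L) * patch + 1L):(pr * patch),
                     ((pc - 1L) * patch + 1L):(pc * patch)]
        pv[, idx] <- as.vector(blk)
        idx <- idx + 1L
      }
    }
    H <- pmax(flt$W %*% pv + flt$b, 0) # k x n_patches
    c(rowMeans(H), apply(H, 1, max))
  })
  out <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(out) <- sprintf("deep_%03d", seq_len(ncol(out)))
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(images))
  dplyr::bind_cols(tibble::tibble(segment_id = ids), out)
}

#' Fit a PCA projection
#'
#' Centered linear projection keeping the smallest number of components
#' whose cumulative variance reaches `variance_fraction`.
#'
#' @param F Numeric matrix or feature tibble (numeric columns used),
#'   samples in rows.
#' @param variance_fraction Target fraction of total variance in (0, 1\].
#' @return Object of class `pcg_pca` with `center`, `rotation`,
#'   `n_components`, `explained`.
#' @export
fit_pca <- function(F, variance_fraction = 0.95) {
  X <- as_feature_matrix(F)
  if (nrow(X) < 2) {
    rlang::abort("PCA needs at least 2 samples.", class = "pcgstack_invalid_input")
  }
  if (variance_fraction <= 0 || variance_fraction > 1) {
    rlang::abort("variance_fraction must be in (0, 1].",
                 class = "pcgstack_invalid_config")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  keep <- v > max(v) * 1e-12 # drop numerically null directions
  cum <- cumsum(v[keep]) / sum(v[keep])
  k <- which(cum >= variance_fraction - 1e-12)[1L]
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 n_components = k,
                 explained = cum[k]),
            class = "pcg_pca")
}

#' Project features through a fitted PCA
#'
#' @param model A [fit_pca()] model.
#' @param F Matrix/tibble with the same feature columns as the fit.
#' @return Scores matrix (samples x components).
#' @export
transform_pca <- function(model, F) {
  X <- as_feature_matrix(F)
  if (ncol(X) != length(model$center)) {
    rlang::abort("feature dimension does not match the fitted PCA.",
                 class = "pcgstack_invalid_input")
  }
  sweep(X, 2, model$center) %*% model$rotation
}

# Accept a plain matrix or a tibble with an id column + numeric features.
as_feature_matrix <- function(F) {
  if (is.matrix(F)) return(F)
  df <- as.data.frame(F)
  num <- vapply(df, is.numeric, logical(1))
  as.matrix(df[, num, drop = FALSE])
}
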