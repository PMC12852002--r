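# Scalar texture features: the standard radiomics panel over the four
# gray-level matrices — 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM = 70.
# GLCM and GLRLM features are averaged over the four directions.
#
# Conventions for degenerate inputs (single occupied cell, constant image):
# correlation-type features with a zero marginal variance are defined as 0;
# the informational correlations fall back to 0 when the normalizing
# entropy is 0; MCC of a single-level image is 1 (a constant image is
# perfectly "correlated" with itself).  Every feature is finite on every
# valid input.

eps_log <- .Machine$double.eps

# ---- GLCM (24 features, one direction) ----
glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- seq_len(ng)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(i * px)
  mu_y <- sum(i * py)
  var_x <- sum((i - mu_x)^2 * px)
  var_y <- sum((i - mu_y)^2 * py)
  I <- row(P); J <- col(P)
  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- as.numeric(tapply(P, abs(I - J), sum))
  p_diff <- c(p_diff, numeric(ng - length(p_diff)))
  k_sum <- 2:(2 * ng)
  p_sum <- as.numeric(tapply(P, I + J, sum))
  p_sum <- c(p_sum, numeric(2 * ng - 1 - length(p_sum)))

  autoc <- sum(I * J * P)
  corr <- if (var_x > 0 && var_y > 0) {
    (autoc - mu_x * mu_y) / sqrt(var_x * var_y)
  } else 0
  da <- sum(k_diff * p_diff)

  hx <- -sum(px * log2(px + eps_log))
  hy <- -sum(py * log2(py + eps_log))
  hxy <- -sum(P * log2(P + eps_log))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxy + eps_log))
  hxy2 <- -sum(pxy * log2(pxy + eps_log))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  present <- which(px > 0)
  mcc <- if (length(present) < 2) 1 else {
    Ps <- P[present, present, drop = FALSE]
    A <- Ps / px[present]
    B <- sweep(Ps, 2, py[present], "/")
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(min(ev[2], 1), 0))
  }

  c(
    autocorrelation = autoc,
    joint_average = mu_x,
    cluster_prominence = sum((I + J - mu_x - mu_y)^4 * P),
    cluster_shade = sum((I + J - mu_x - mu_y)^3 * P),
    cluster_tendency = sum((I + J - mu_x - mu_y)^2 * P),
    contrast = sum((I - J)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(p_diff * log2(p_diff + eps_log)),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(P / (1 + (I - J)^2)),
    idmn = sum(P / (1 + ((I - J) / ng)^2)),
    id = sum(P / (1 + abs(I - J))),
    idn = sum(P / (1 + abs(I - J) / ng)),
    inverse_variance = sum(P[I != J] / (I[I != J] - J[I != J])^2),
    maximum_probability = max(P),
    sum_average = sum(k_sum * p_sum),
    sum_entropy = -sum(p_sum * log2(p_sum + eps_log)),
    sum_squares = var_x,
    mcc = mcc
  )
}

# ---- shared run/zone feature pattern (16 features) ----
# P: counts, rows = gray level g, cols = run length / zone size m.
run_zone_features <- function(P, n_pixels, prefix_small, prefix_large,
                              m_name) {
  g <- seq_len(nrow(P))
  m <- seq_len(ncol(P))
  N <- sum(P)
  p <- P / N
  pg <- rowSums(P)
  pm <- colSums(P)
  mu_g <- sum(g * rowSums(p))
  mu_m <- sum(m * colSums(p))
  out <- c(
    small = sum(sweep(P, 2, m^2, "/")) / N,
    large = sum(sweep(P, 2, m^2, "*")) / N,
    gray_level_non_uniformity = sum(pg^2) / N,
    gray_level_non_uniformity_normalized = sum(pg^2) / N^2,
    m_non_uniformity = sum(pm^2) / N,
    m_non_uniformity_normalized = sum(pm^2) / N^2,
    m_percentage = N / n_pixels,
    gray_level_variance = sum(outer((g - mu_g)^2, rep(1, length(m))) * p),
    m_variance = sum(outer(rep(1, length(g)), (m - mu_m)^2) * p),
    m_entropy = -sum(p * log2(p + eps_log)),
    low_gray_level = sum(sweep(P, 1, g^2, "/")) / N,
    high_gray_level = sum(sweep(P, 1, g^2, "*")) / N,
    small_low = sum(outer(1 / g^2, 1 / m^2) * P) / N,
    small_high = sum(outer(g^2, 1 / m^2) * P) / N,
    large_low = sum(outer(1 / g^2, m^2) * P) / N,
    large_high = sum(outer(g^2, m^2) * P) / N
  )
  names(out) <- c(
    prefix_small, prefix_large,
    "gray_level_non_uniformity", "gray_level_non_uniformity_normalized",
    paste0(m_name, "_non_uniformity"),
    paste0(m_name, "_non_uniformity_normalized"),
    paste0(m_name, "_percentage"),
    "gray_level_variance", paste0(m_name, "_variance"),
    paste0(m_name, "_entropy"),
    "low_gray_level_emphasis", "high_gray_level_emphasis",
    paste0(prefix_small, "_low_gray_level"),
    paste0(prefix_small, "_high_gray_level"),
    paste0(prefix_large, "_low_gray_level"),
    paste0(prefix_large, "_high_gray_level")
  )
  out
}

glrlm_features_one <- function(P, n_pixels) {
  run_zone_features(P, n_pixels, "short_run_emphasis", "long_run_emphasis",
                    "run_length")
}

glszm_features <- function(P, n_pixels) {
  run_zone_features(P, n_pixels, "small_area_emphasis", "large_area_emphasis",
                    "size_zone")
}

# ---- GLDM (14 features) ----
# Columns hold dependence d = col - 1; feature weights use j = d + 1 so the
# zero-dependence column stays well defined.
gldm_features <- function(P) {
  g <- seq_len(nrow(P))
  j <- seq_len(ncol(P)) # = d + 1
  N <- sum(P)
  p <- P / N
  pg <- rowSums(P)
  pj <- colSums(P)
  mu_g <- sum(g * rowSums(p))
  mu_j <- sum(j * colSums(p))
  c(
    small_dependence_emphasis = sum(sweep(P, 2, j^2, "/")) / N,
    large_dependence_emphasis = sum(sweep(P, 2, j^2, "*")) / N,
    gray_level_non_uniformity = sum(pg^2) / N,
    dependence_non_uniformity = sum(pj^2) / N,
    dependence_non_uniformity_normalized = sum(pj^2) / N^2,
    gray_level_variance = sum(outer((g - mu_g)^2, rep(1, length(j))) * p),
    dependence_variance = sum(outer(rep(1, length(g)), (j - mu_j)^2) * p),
    dependence_entropy = -sum(p * log2(p + eps_log)),
    low_gray_level_emphasis = sum(sweep(P, 1, g^2, "/")) / N,
    high_gray_level_emphasis = sum(sweep(P, 1, g^2, "*")) / N,
    small_dependence_low_gray_level = sum(outer(1 / g^2, 1 / j^2) * P) / N,
    small_dependence_high_gray_level = sum(outer(g^2, 1 / j^2) * P) / N,
    large_dependence_low_gray_level = sum(outer(1 / g^2, j^2) * P) / N,
    large_dependence_high_gray_level = sum(outer(g^2, j^2) * P) / N
  )
}

#' The 70-feature texture panel of a texture-matrix set
#'
#' 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM features in a fixed, documented
#' order. GLCM and GLRLM features are averaged across the four directions.
#'
#' @param m Output of [texture_matrices()].
#' @return Named numeric vector of length 70, all finite.
#' @export
texture_features <- function(m) {
  glcm_f <- rowMeans(vapply(m$glcm, glcm_features_one, numeric(24)))
  glrlm_f <- rowMeans(vapply(m$glrlm, glrlm_features_one, numeric(16),
                             n_pixels = m$n_pixels))
  glszm_f <- glszm_features(m$glszm, m$n_pixels)
  gldm_f <- gldm_features(m$gldm)
  out <- c(
    stats::setNames(glcm_f, paste0("glcm_", names(glcm_f))),
    stats::setNames(glrlm_f, paste0("glrlm_", names(glrlm_f))),
    stats::setNames(glszm_f, paste0("glszm_", names(glszm_f))),
    stats::setNames(gldm_f, paste0("gldm_", names(gldm_f)))
  )
  stopifnot(length(out) == 70L)
  out
}

#' Names of the 70 texture features, in output order
#' @return Character vector of length 70.
#' @export
texture_feature_names <- function() {
  names(texture_features(texture_matrices(quantize_image(diag(4), 4))))
}

#' Texture feature vector of one gray image
#'
#' Quantizes the image and runs the full 70-feature panel.
#'
#' @param image Numeric gray image in \[0, 1\].
#' @param n_levels Gray levels for quantization.
#' @param delta,distance GLDM parameters.
#' @return Named numeric vector of length 70.
#' @export
image_texture_features <- function(image, n_levels = 32, delta = 0,
                                   distance = 1) {
  q <- quantize_image(image, n_levels)
  texture_features(texture_matrices(q, delta = delta, distance = distance))
}

#' Texture features for every image in a list
#'
#' @param images List of gray image matrices.
#' @param ids Optional identifiers (one per image).
#' @inheritParams image_texture_features
#' @return Tibble: `segment_id` plus the 70 feature columns.
#' @export
extract_texture_features <- function(images, ids = NULL, n_levels = 32,
                                     delta = 0, distance = 1) {
  rows <- purrr::map(images, image_texture_features, n_levels = n_levels,
                     delta = delta, distance = distance)
  out <- tibble::as_tibble(do.call(rbind, rows))
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(images))
  dplyr::bind_cols(tibble::tibble(segment_id = ids), out)
}
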