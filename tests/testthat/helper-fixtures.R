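# Shared small fixtures, built once per test session.

tiny_sim_config <- function(...) {
  sim_config(n_subjects_per_class = 6, segments_per_subject = 2,
             duration_s = 2, fs = 4410, effect_size = 2, noise_sd = 0.05,
             seed = 101, ...)
}

# synthetic two-class feature table: first `k_inf` columns informative
make_informative_features <- function(n = 120, p = 50, k_inf = 5,
                                      effect = 0.8, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, seq_len(k_inf)] <- X[, seq_len(k_inf)] + effect * y
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, y = y)
}

# quick image list for feature-extractor tests
make_band_images <- function(n_per_class = 10, size = 32, shift = 0.5,
                             seed = 1) {
  set.seed(seed)
  imgs <- list()
  labels <- integer(0)
  for (cls in c(-1, 1)) {
    for (i in seq_len(n_per_class)) {
      img <- matrix(stats::runif(size * size, 0, 0.3), size, size)
      band <- max(2L, size %/% 3L) # class-dependent bright band
      rows <- if (cls > 0) seq_len(band) else (size - band + 1L):size
      img[rows, ] <- img[rows, ] + shift
      imgs[[length(imgs) + 1]] <- pmin(img, 1)
      labels <- c(labels, cls)
    }
  }
  list(images = imgs, labels = labels)
}

all_binary_3x3 <- function() {
  lapply(0:511, function(k) {
    bits <- as.integer(intToBits(k))[1:9]
    matrix(bits + 1L, 3, 3)
  })
}
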