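test_that("quantization bins the range evenly with endpoints pinned", {
  expect_true(all(quantize_image(matrix(0.7, 5, 5), 8) == 1))
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  q <- quantize_image(ramp, 4)
  expect_equal(as.vector(table(q)), rep(4L, 4), ignore_attr = TRUE)
  img <- matrix(c(0.1, 0.4, 0.9, 0.3), 2, 2)
  q2 <- quantize_image(img, 5)
  expect_equal(q2[which.min(img)], 1L)
  expect_equal(q2[which.max(img)], 5L)
  expect_error(quantize_image(ramp, 1), class = "pcgstack_invalid_config")
})

test_that("texture matrices reproduce hand-computed micro-examples", {
  ones <- matrix(1L, 2, 2)
  P <- glcm(ones, c(1, 0), n_levels = 1)
  expect_equal(P[1, 1], 1)
  two_col <- matrix(c(1L, 1L, 2L, 2L), 2, 2) # rows [1,2],[1,2]
  Pa <- glcm(two_col, c(1, 0), symmetric = FALSE, n_levels = 2)
  expect_equal(Pa[1, 2], 1)
  r <- glrlm(matrix(c(1L, 1L, 2L, 2L), 1, 4), 0, n_levels = 2)
  expect_equal(r[1, 2], 1)
  expect_equal(r[2, 2], 1)
  r4 <- glrlm(matrix(1L, 1, 4), 0, n_levels = 1)
  expect_equal(r4[1, 4], 1)
  expect_equal(sum(r4), 1)
  # checkerboard: the two diagonals are 8-connected zones
  chk <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  Z <- glszm(chk, n_levels = 2)
  expect_equal(Z[1, 2], 1)
  expect_equal(Z[2, 2], 1)
  con <- matrix(1L, 3, 3)
  Zc <- glszm(con, n_levels = 1)
  expect_equal(Zc[1, 9], 1)
  expect_equal(sum(Zc), 1)
  D <- gldm(con, delta = 0, distance = 1, n_levels = 1)
  expect_equal(D[1, 4], 4) # corners: 3 dependent neighbours
  expect_equal(D[1, 6], 4) # edges: 5
  expect_equal(D[1, 9], 1) # center: 8
  expect_error(glcm(ones, c(5, 0), n_levels = 1),
               class = "pcgstack_empty_pairs")
  expect_error(glcm(ones, c(0, 0), n_levels = 1),
               class = "pcgstack_invalid_config")
})

test_that("matrix builders match brute-force oracles on all binary 3x3 images", {
  for (q in all_binary_3x3()) {
    attr(q, "n_levels") <- 2L
    for (d in list(c(1, 0), c(1, -1), c(0, 1), c(1, 1))) {
      expect_equal(glcm(q, d, n_levels = 2),
                   oracle_glcm(q, d[1], d[2], 2), tolerance = 1e-12)
    }
    for (ang in c(0, 45, 90, 135)) {
      got <- glrlm(q, ang, n_levels = 2)
      exp <- oracle_glrlm(q, ang, 2)
      expect_equal(got[, seq_len(ncol(exp)), drop = FALSE], exp,
                   ignore_attr = TRUE)
      if (ncol(got) > ncol(exp)) {
        expect_true(all(got[, (ncol(exp) + 1):ncol(got)] == 0))
      }
    }
    expect_equal(glszm(q, n_levels = 2), oracle_glszm(q, 2),
                 ignore_attr = TRUE)
    expect_equal(gldm(q, n_levels = 2), oracle_gldm(q, 2),
                 ignore_attr = TRUE)
  }
})

test_that("matrix builders match oracles on random 16x16 images at 4 levels", {
  set.seed(77)
  for (rep in 1:25) {
    q <- matrix(sample.int(4, 256, replace = TRUE), 16, 16)
    attr(q, "n_levels") <- 4L
    d <- list(c(1, 0), c(1, -1), c(0, 1), c(1, 1))[[1 + rep %% 4]]
    ang <- c(0, 45, 90, 135)[1 + rep %% 4]
    expect_equal(glcm(q, d, n_levels = 4), oracle_glcm(q, d[1], d[2], 4),
                 tolerance = 1e-12)
    got <- glrlm(q, ang, n_levels = 4)
    exp <- oracle_glrlm(q, ang, 4)
    expect_equal(got[, seq_len(ncol(exp))], exp, ignore_attr = TRUE)
    expect_equal(glszm(q, n_levels = 4), oracle_glszm(q, 4),
                 ignore_attr = TRUE)
    expect_equal(gldm(q, delta = 1, n_levels = 4),
                 oracle_gldm(q, 4, delta = 1), ignore_attr = TRUE)
  }
})

test_that("partition invariants hold on random images", {
  set.seed(31)
  for (rep in 1:5) {
    q <- matrix(sample.int(6, 400, replace = TRUE), 20, 20)
    attr(q, "n_levels") <- 6L
    m <- texture_matrices(q)
    expect_equal(sum(m$glcm[[1]]), 1, tolerance = 1e-12)
    for (R in m$glrlm) {
      expect_equal(sum(sweep(R, 2, seq_len(ncol(R)), "*")), 400)
    }
    expect_equal(sum(sweep(m$glszm, 2, seq_len(ncol(m$glszm)), "*")), 400)
    expect_equal(sum(m$gldm), 400)
  }
})

test_that("a maximal tolerance makes every neighbour dependent", {
  set.seed(41)
  q <- matrix(sample.int(4, 64, replace = TRUE), 8, 8)
  attr(q, "n_levels") <- 4L
  full <- gldm(q, delta = 3, distance = 1, n_levels = 4)
  const_like <- oracle_gldm(matrix(1L, 8, 8), 4, delta = 0)
  expect_equal(colSums(full), colSums(const_like), ignore_attr = TRUE)
})

test_that("the panel has exactly 70 finite features in a stable order", {
  nm <- texture_feature_names()
  expect_length(nm, 70)
  expect_equal(sum(startsWith(nm, "glcm_")), 24)
  expect_equal(sum(startsWith(nm, "glrlm_")), 16)
  expect_equal(sum(startsWith(nm, "glszm_")), 16)
  expect_equal(sum(startsWith(nm, "gldm_")), 14)
  f <- image_texture_features(matrix(0.5, 16, 16))
  expect_equal(names(f), nm)
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["glcm_joint_entropy"]), 0, tolerance = 1e-9)
  set.seed(55)
  for (rep in 1:100) {
    q <- matrix(sample.int(32, 32 * 32, replace = TRUE), 32, 32)
    attr(q, "n_levels") <- 32L
    fv <- texture_features(texture_matrices(q))
    expect_true(all(is.finite(fv)))
  }
})

test_that("direction-averaged features are invariant to 90-degree rotation", {
  set.seed(66)
  img <- matrix(runif(24 * 24), 24, 24)
  rot90 <- function(m) t(m[nrow(m):1, ])
  f1 <- image_texture_features(img, n_levels = 8)
  f2 <- image_texture_features(rot90(img), n_levels = 8)
  sel <- c(grep("^glcm_", names(f1)), grep("^glrlm_", names(f1)))
  expect_equal(f1[sel], f2[sel], tolerance = 1e-9)
})

test_that("feature extraction over image batches yields tidy rows", {
  imgs <- make_band_images(3, size = 24)$images
  tb <- extract_texture_features(imgs, ids = sprintf("s%d", 1:6))
  expect_equal(dim(tb), c(6, 71))
  expect_equal(tb$segment_id, sprintf("s%d", 1:6))
  expect_true(all(vapply(tb[, -1], is.numeric, logical(1))))
})
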