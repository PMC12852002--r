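# Internal helpers: seeded RNG scoping, deterministic seed derivation,
# image resizing, input validation.

#' @importFrom stats approx rnorm runif sd var fft pnorm qnorm predict
#' @importFrom rlang abort %||% .data
NULL

# Evaluate `code` under a temporary RNG state; restores the caller's state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic seed mixing (LCG over the integer stream); stays < 2^31 - 1.
derive_seed <- function(seed, ...) {
  k <- as.numeric(seed) %% 2147483647
  for (x in c(...)) {
    k <- (k * 69069 + as.numeric(x) + 1) %% 2147483647
  }
  as.integer(k)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "pcgstack_invalid_config")
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name),
          class = "pcgstack_invalid_config")
  }
  invisible(x)
}

# Separable bilinear resize with corner alignment. Rows/cols are mapped so
# the first and last samples of each axis coincide in input and output.
resize_bilinear <- function(mat, out_rows, out_cols) {
  stopifnot(is.matrix(mat), out_rows >= 1, out_cols >= 1)
  nr <- nrow(mat)
  nc <- ncol(mat)
  row_at <- if (out_rows == 1L) (nr + 1) / 2 else seq(1, nr, length.out = out_rows)
  col_at <- if (out_cols == 1L) (nc + 1) / 2 else seq(1, nc, length.out = out_cols)
  # interpolate along columns first, then rows
  tmp <- matrix(0, nr, out_cols)
  if (nc == 1L) {
    tmp <- matrix(mat[, 1L], nr, out_cols)
  } else {
    for (i in seq_len(nr)) {
      tmp[i, ] <- approx(seq_len(nc), mat[i, ], xout = col_at)$y
    }
  }
  out <- matrix(0, out_rows, out_cols)
  if (nr == 1L) {
    out <- matrix(tmp[1L, ], out_rows, out_cols, byrow = TRUE)
  } else {
    for (j in seq_len(out_cols)) {
      out[, j] <- approx(seq_len(nr), tmp[, j], xout = row_at)$y
    }
  }
  out
}

# Column scaling to mean 0 / sd 1 with stored statistics (train-fold only).
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

as_label_pm1 <- function(y) {
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (identical(u, c(0, 1))) y <- ifelse(y > 0, 1, -1)
  if (!all(y %in% c(-1, 1))) {
    abort("labels must be coded -1/+1 (or 0/1).", class = "pcgstack_invalid_input")
  }
  y
}

check_two_classes <- function(y) {
  y <- as_label_pm1(y)
  if (length(unique(y)) < 2L) {
    abort("both classes must be present.", class = "pcgstack_invalid_input")
  }
  y
}
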