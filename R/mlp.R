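# A small fully connected network with ReLU hidden layers and a sigmoid
# output, trained with full-batch Adam on binary cross-entropy and early
# stopping on an internal stratified holdout.  Written in plain R: the
# meta-learner sits on a 4-column input, so the matrix work is tiny.

mlp_init <- function(sizes, seed) {
  with_local_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                            sqrt(2 / fan_in)), sizes[l], sizes[l + 1L]),
           b = numeric(sizes[l + 1L]))
    })
  })
}

mlp_forward <- function(params, X) {
  acts <- list(X)
  L <- length(params)
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% params[[l]]$W
    Z <- sweep(Z, 2, params[[l]]$b, "+")
    A <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
    acts[[l + 1L]] <- A
  }
  acts
}

mlp_grad <- function(params, acts, y) {
  L <- length(params)
  n <- length(y)
  grads <- vector("list", L)
  # BCE + sigmoid output: delta = p - y
  delta <- (acts[[L + 1L]] - y) / n
  for (l in rev(seq_len(L))) {
    A_prev <- acts[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

#' Train the MLP meta-learner
#'
#' Architecture: ReLU hidden layers (`hidden`, default 256/128/64) and a
#' sigmoid output; full-batch Adam on binary cross-entropy with early
#' stopping on a 10% stratified internal split. Deterministic given
#' `seed`.
#'
#' @param Z Numeric input matrix (samples x inputs), e.g. weighted base
#'   posteriors.
#' @param y Labels in -1/+1 (or 0/1).
#' @param hidden Hidden layer sizes.
#' @param seed Integer seed.
#' @param lr Adam learning rate.
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @return Object of class `pcg_mlp`.
#' @export
train_mlp <- function(Z, y, hidden = c(256, 128, 64), seed = 1,
                      lr = 1e-3, max_epochs = 500, patience = 25) {
  Z <- as.matrix(Z)
  y <- check_two_classes(y)
  y01 <- matrix(as.numeric(y > 0), ncol = 1)
  sizes <- c(ncol(Z), hidden, 1L)
  params <- mlp_init(sizes, seed)

  # stratified 10% internal validation split
  val_idx <- with_local_seed(derive_seed(seed, 7L), {
    idx <- unlist(lapply(split(seq_along(y), y), function(ii) {
      k <- max(1L, round(0.1 * length(ii)))
      sample(ii, k)
    }))
    sort(idx)
  })
  tr_idx <- setdiff(seq_along(y), val_idx)
  Xtr <- Z[tr_idx, , drop = FALSE]; ytr <- y01[tr_idx, , drop = FALSE]
  Xva <- Z[val_idx, , drop = FALSE]; yva <- y01[val_idx, , drop = FALSE]

  mom <- lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                         mb = p$b * 0, vb = p$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  bce <- function(p, yy) -mean(yy * log(p + 1e-12) + (1 - yy) * log(1 - p + 1e-12))
  for (epoch in seq_len(max_epochs)) {
    acts <- mlp_forward(params, Xtr)
    grads <- mlp_grad(params, acts, ytr)
    for (l in seq_along(params)) {
      mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * grads[[l]]$W
      mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * grads[[l]]$W^2
      mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * grads[[l]]$b
      mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * grads[[l]]$b^2
      mW_hat <- mom[[l]]$mW / (1 - b1^epoch)
      vW_hat <- mom[[l]]$vW / (1 - b2^epoch)
      mb_hat <- mom[[l]]$mb / (1 - b1^epoch)
      vb_hat <- mom[[l]]$vb / (1 - b2^epoch)
      params[[l]]$W <- params[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
      params[[l]]$b <- params[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    }
    val_loss <- bce(mlp_forward(params, Xva)[[length(params) + 1L]], yva)
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(params = best$params, sizes = sizes, seed = seed,
                 epochs_trained = best$epoch, val_loss = best$loss),
            class = "pcg_mlp")
}

#' Predict positive-class probabilities from a trained MLP
#'
#' @param object A `pcg_mlp`.
#' @param newdata Input matrix with the fitted input width.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.pcg_mlp <- function(object, newdata, ...) {
  Z <- as.matrix(newdata)
  if (nrow(Z) == 0) return(numeric(0))
  if (ncol(Z) != object$sizes[1L]) {
    rlang::abort("input width does not match the trained network.",
                 class = "pcgstack_invalid_input")
  }
  as.numeric(mlp_forward(object$params, Z)[[length(object$params) + 1L]])
}
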