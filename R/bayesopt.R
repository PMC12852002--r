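# Gaussian-process Bayesian optimization with expected improvement.
#
# The loss surface is modelled by a zero-mean GP with a squared-exponential
# kernel over hyperparameters encoded into the unit cube (log-scaling where
# requested, continuous relaxation + rounding for integers, one-hot for
# categoricals).  The acquisition is expected improvement for minimization,
#
#   EI(x) = E[max(0, l* - L(x))]
#         = (l* - mu) Phi(z) + sigma phi(z),  z = (l* - mu) / sigma,
#
# maximized over a seeded random candidate set plus perturbations of the
# incumbent.

#' Define a hyperparameter search space
#'
#' @param ... Named parameter definitions from [param_continuous()],
#'   [param_integer()] or [param_categorical()].
#' @return List of class `pcg_search_space`.
#' @export
search_space <- function(...) {
  params <- list(...)
  if (is.null(names(params)) || any(names(params) == "")) {
    rlang::abort("every parameter must be named.", class = "pcgstack_invalid_config")
  }
  structure(params, class = "pcg_search_space")
}

#' @rdname search_space
#' @param lower,upper Finite bounds (`lower < upper`).
#' @param log Optimize on a log scale.
#' @export
param_continuous <- function(lower, upper, log = FALSE) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    rlang::abort("need finite lower < upper.", class = "pcgstack_invalid_config")
  }
  list(type = "continuous", lower = lower, upper = upper, log = log)
}

#' @rdname search_space
#' @export
param_integer <- function(lower, upper) {
  p <- param_continuous(lower, upper)
  p$type <- "integer"
  p
}

#' @rdname search_space
#' @param choices Allowed values.
#' @export
param_categorical <- function(choices) {
  if (length(choices) < 2) {
    rlang::abort("need at least 2 choices.", class = "pcgstack_invalid_config")
  }
  list(type = "categorical", choices = choices)
}

# encoded dimension of each parameter
space_dims <- function(space) {
  vapply(space, function(p) {
    if (p$type == "categorical") length(p$choices) else 1L
  }, integer(1))
}

# unit-cube vector -> named configuration list
decode_config <- function(space, u) {
  cfg <- list()
  pos <- 1L
  for (nm in names(space)) {
    p <- space[[nm]]
    if (p$type == "categorical") {
      k <- length(p$choices)
      cfg[[nm]] <- p$choices[[which.max(u[pos:(pos + k - 1L)])]]
      pos <- pos + k
    } else {
      lo <- p$lower; hi <- p$upper
      v <- if (isTRUE(p$log)) {
        exp(log(lo) + u[pos] * (log(hi) - log(lo)))
      } else {
        lo + u[pos] * (hi - lo)
      }
      if (p$type == "integer") v <- as.integer(round(v))
      cfg[[nm]] <- v
      pos <- pos + 1L
    }
  }
  cfg
}

se_kernel <- function(A, B, lengthscale, sf2) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sf2 * exp(-0.5 * pmax(d2, 0) / lengthscale^2)
}

# fit the GP once: pick the lengthscale maximizing the marginal likelihood
# over a small fixed grid; jitter keeps the solve stable
gp_fit <- function(X, y, jitter = 1e-8) {
  mu <- mean(y)
  yc <- y - mu
  sf2 <- max(stats::var(yc), 1e-12)
  grid <- c(0.05, 0.1, 0.2, 0.5, 1, 2)
  best <- NULL
  for (ls in grid) {
    K <- se_kernel(X, X, ls, sf2) + diag(jitter + 1e-10 * sf2, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    ll <- -0.5 * sum(yc * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ls = ls, chol = ch, alpha = alpha)
    }
  }
  c(best, list(X = X, mu = mu, sf2 = sf2))
}

#' GP posterior mean and variance at a configuration
#'
#' @param state A `pcg_bo_state` (see [bo_optimize()]) or any list with
#'   `X` (encoded observations) and `y` (losses).
#' @param u Encoded point(s): vector or matrix of rows in the unit cube.
#' @return Tibble with `mean` and `variance`.
#' @export
gp_posterior <- function(state, u) {
  U <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  if (is.null(state$gp)) state$gp <- gp_fit(state$X, state$y)
  g <- state$gp
  Ks <- se_kernel(U, g$X, g$ls, g$sf2)
  mean <- g$mu + as.numeric(Ks %*% g$alpha)
  V <- forwardsolve(t(g$chol), t(Ks))
  variance <- pmax(g$sf2 - colSums(V^2), 0)
  tibble::tibble(mean = mean, variance = variance)
}

#' Closed-form expected improvement of a normal posterior
#'
#' `E[max(0, best - L)]` for `L ~ N(mean, sd^2)`; zero when `sd = 0`.
#'
#' @param mean,sd Posterior mean and standard deviation of the loss.
#' @param best Incumbent (smallest observed) loss.
#' @return Non-negative EI.
#' @export
ei_value <- function(mean, sd, best) {
  imp <- best - mean
  z <- ifelse(sd > 0, imp / sd, 0)
  out <- ifelse(sd > 0, imp * pnorm(z) + sd * stats::dnorm(z), 0)
  pmax(out, 0)
}

#' Expected improvement (minimization)
#'
#' @inheritParams gp_posterior
#' @param best Incumbent (smallest observed) loss; defaults to
#'   `min(state$y)`.
#' @return Non-negative EI value(s).
#' @export
expected_improvement <- function(state, u, best = min(state$y)) {
  post <- gp_posterior(state, u)
  ei_value(post$mean, sqrt(post$variance), best)
}

#' Bayesian optimization of a loss function
#'
#' `n_init` Latin-hypercube evaluations followed by EI-maximizing
#' proposals chosen from a seeded random candidate set (plus local
#' perturbations of the incumbent). An objective failure is recorded as
#' the worst loss observed so far and flagged in the history.
#'
#' @param objective Function taking a named configuration list, returning
#'   a scalar loss to minimize.
#' @param space A [search_space()].
#' @param budget Total number of evaluations.
#' @param n_init Initial space-filling evaluations.
#' @param seed Integer seed.
#' @param n_candidates Random candidates scored per iteration.
#' @return List of class `pcg_bo_state`: `best_config`, `best_loss`,
#'   `history` (tibble with one row per evaluation), `X`, `y`.
#' @export
bo_optimize <- function(objective, space, budget = 25, n_init = 5, seed = 1,
                        n_candidates = 512) {
  if (!(budget >= n_init && n_init >= 1)) {
    rlang::abort("need budget >= n_init >= 1.", class = "pcgstack_invalid_config")
  }
  d <- sum(space_dims(space))
  U_init <- with_local_seed(seed, lhs::randomLHS(n_init, d))
  X <- matrix(numeric(0), 0, d)
  y <- numeric(0)
  hist <- list()
  evaluate <- function(u, i) {
    cfg <- decode_config(space, u)
    res <- tryCatch(list(loss = objective(cfg), failed = FALSE),
                    error = function(e) list(loss = NA_real_, failed = TRUE))
    loss <- res$loss
    if (res$failed || !is.finite(loss)) {
      loss <- if (length(y)) max(y) else 1e6
      res$failed <- TRUE
    }
    X <<- rbind(X, u)
    y <<- c(y, loss)
    hist[[i]] <<- tibble::tibble(iteration = i, loss = loss,
                                 failed = res$failed,
                                 config = list(cfg))
  }
  for (i in seq_len(n_init)) evaluate(U_init[i, ], i)
  for (i in seq.int(n_init + 1, length.out = budget - n_init)) {
    state <- list(X = X, y = y, gp = gp_fit(X, y))
    cand <- with_local_seed(derive_seed(seed, i), {
      base <- matrix(runif(n_candidates * d), n_candidates, d)
      inc <- X[which.min(y), ]
      local <- matrix(rep(inc, each = 64), 64, d) +
        matrix(rnorm(64 * d, 0, 0.05), 64, d)
      rbind(base, pmin(pmax(local, 0), 1))
    })
    ei <- expected_improvement(state, cand)
    evaluate(cand[which.max(ei), ], i)
  }
  best_i <- which.min(y)
  history <- dplyr::bind_rows(hist)
  structure(list(best_config = history$config[[best_i]],
                 best_loss = y[best_i],
                 history = history, X = X, y = y, space = space,
                 seed = seed),
            class = "pcg_bo_state")
}

#' @export
print.pcg_bo_state <- function(x, ...) {
  cat(sprintf("<pcg_bo_state: %d evaluations, best loss %.5g>\n",
              nrow(x$history), x$best_loss))
  invisible(x)
}
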