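test_that("the GP posterior interpolates and reverts to the prior", {
  X <- matrix(c(0.2, 0.4, 0.6), 3, 1)
  y <- c(0.5, 0.1, 0.4)
  state <- list(X = X, y = y, gp = pcgstack:::gp_fit(X, y))
  at_obs <- gp_posterior(state, X[2, , drop = FALSE])
  expect_lt(abs(at_obs$mean - 0.1), 1e-3)
  expect_lt(at_obs$variance, 1e-4)
  # far from the data (>= 10 lengthscales) the variance is the prior's
  g <- state$gp
  far <- matrix(0.5 + 20 * g$ls, 1, 1)
  pf <- gp_posterior(state, far)
  expect_lt(abs(pf$variance - g$sf2) / g$sf2, 0.01)
})

test_that("the GP posterior matches a direct linear solve", {
  X <- matrix(c(0.1, 0.5, 0.9), 3, 1)
  y <- c(0.8, 0.2, 0.6)
  state <- list(X = X, y = y, gp = pcgstack:::gp_fit(X, y))
  g <- state$gp
  xstar <- matrix(0.33, 1, 1)
  # independent dense solve of the same GP system
  k <- function(a, b) g$sf2 * exp(-0.5 * (a - b)^2 / g$ls^2)
  K <- outer(as.numeric(X), as.numeric(X), k) + diag(1e-8 + 1e-10 * g$sf2, 3)
  ks <- k(as.numeric(xstar), as.numeric(X))
  mu_direct <- g$mu + ks %*% solve(K, y - g$mu)
  var_direct <- g$sf2 - ks %*% solve(K, ks)
  got <- gp_posterior(state, xstar)
  expect_equal(got$mean, as.numeric(mu_direct), tolerance = 1e-8)
  expect_equal(got$variance, as.numeric(var_direct), tolerance = 1e-8)
})

test_that("expected improvement matches Monte Carlo and is non-negative", {
  set.seed(70)
  draws <- rnorm(1e6, 0.5, 0.1)
  mc <- mean(pmax(0.45 - draws, 0))
  expect_lt(abs(ei_value(0.5, 0.1, 0.45) - mc), 1e-3)
  expect_equal(ei_value(0.3, 0, 0.3), 0)
  X <- matrix(seq(0.1, 0.9, length.out = 5), 5, 1)
  y <- (as.numeric(X) - 0.4)^2
  state <- list(X = X, y = y, gp = pcgstack:::gp_fit(X, y))
  u <- matrix(runif(1000), 1000, 1)
  expect_true(all(expected_improvement(state, u) >= 0))
  # EI vanishes at a noiselessly observed point
  expect_lt(expected_improvement(state, X[3, , drop = FALSE]), 1e-3)
})

test_that("optimization finds a 1-D quadratic minimum within budget", {
  space <- search_space(x = param_continuous(0, 1))
  res <- bo_optimize(function(cfg) (cfg$x - 0.3)^2, space,
                     budget = 25, n_init = 5, seed = 2)
  expect_lte(abs(res$best_config$x - 0.3), 0.05)
  expect_equal(nrow(res$history), 25)
  # incumbent trace is non-increasing
  expect_true(all(diff(cummin(res$history$loss)) <= 0))
  # determinism
  res2 <- bo_optimize(function(cfg) (cfg$x - 0.3)^2, space,
                      budget = 25, n_init = 5, seed = 2)
  expect_identical(res$history$loss, res2$history$loss)
})

test_that("categorical spaces are searched exhaustively at tiny scale", {
  space <- search_space(k = param_categorical(c("a", "b", "c")))
  losses <- c(a = 0.9, b = 0.2, c = 0.5)
  res <- bo_optimize(function(cfg) unname(losses[cfg$k]), space,
                     budget = 12, n_init = 6, seed = 3)
  expect_equal(res$best_config$k, "b")
  expect_equal(res$best_loss, 0.2)
})

test_that("failing objectives are recorded as worst-so-far and flagged", {
  space <- search_space(x = param_continuous(0, 1))
  obj <- function(cfg) {
    if (cfg$x > 0.8) stop("unstable configuration")
    cfg$x
  }
  res <- bo_optimize(obj, space, budget = 15, n_init = 5, seed = 8)
  expect_equal(nrow(res$history), 15)
  if (any(res$history$failed)) {
    expect_true(all(res$history$loss[res$history$failed] >=
                      res$best_loss))
  }
  # integer and log-scaled parameters decode into their ranges
  sp2 <- search_space(n = param_integer(2, 20),
                      lr = param_continuous(1e-4, 1e-1, log = TRUE))
  res2 <- bo_optimize(function(cfg) abs(cfg$n - 7) + abs(log10(cfg$lr) + 2),
                      sp2, budget = 20, n_init = 6, seed = 9)
  expect_true(all(vapply(res2$history$config, function(c)
    c$n >= 2 && c$n <= 20 && c$lr >= 1e-4 && c$lr <= 1e-1, logical(1))))
})
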