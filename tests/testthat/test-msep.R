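test_that("a degenerate constant predictor recovers truncated-normal moments", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.6, n = 10, mu = -1)
  for (tau in c(1.28, 1.96)) for (cc in c(0, 0.8)) {
    r <- msep_binary(ctx, tau, predictor = function(y) rep(cc, length(y)))
    expect_equal(r$msep, truncnorm_mse(cc, tau), tolerance = 1e-10)
  }
  # no-information limit: with the prediction pinned at zero the MSEP is
  # the truncated second moment regardless of sigma_u
  ctx0 <- zpredictor("bernoulli_logit", sigma_u = 1e-8, n = 10, mu = -1)
  r0 <- msep_binary(ctx0, 1.28, predictor = function(y) rep(0, length(y)))
  expect_equal(r0$msep, truncnorm_mse(0, 1.28), tolerance = 1e-9)
})

test_that("binary MSEP matches Monte-Carlo simulation", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 7, mu = -2,
                    weight = weight_spec("AB", 1.6))
  ex <- msep(ctx, 1.28)$msep
  set.seed(303)
  N <- 4e5
  z <- rtrunc_norm(N, 1.28)
  y <- rbinom(N, 7, plogis(-2 + 0.8 * z))
  err <- (z - predict(ctx, 0:7)[y + 1])^2
  expect_lt(abs(ex - mean(err)), 3 * sd(err) / sqrt(N))
})

test_that("generic total-distribution route equals the closed binomial route", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.7, n = 12, mu = -0.5,
                    weight = weight_spec("SQ", 0.3))
  for (tau in c(1.28, 1.96)) {
    expect_equal(msep_generic(ctx, tau)$msep, msep_binary(ctx, tau)$msep,
                 tolerance = 1e-10)
  }
})

test_that("Poisson MSEP: truncated sum, generic equality, small-mean limit", {
  ctx <- zpredictor("poisson_log", sigma_u = 0.5, n = 5, mu = -0.5,
                    weight = weight_spec("AB", 1.2))
  r <- msep_poisson(ctx, 1.28)
  expect_lt(r$truncation_error_bound, 1e-10)
  expect_equal(msep_generic(ctx, 1.28)$msep, r$msep, tolerance = 1e-9)
  # nu -> 0: only the k = 0 term contributes, a constant prediction
  small <- zpredictor("poisson_log", sigma_u = 0.3, n = 1, mu = -12)
  z0 <- predict(small, 0)
  expect_equal(msep_poisson(small, 1.28)$msep, truncnorm_mse(z0, 1.28),
               tolerance = 1e-4)
})

test_that("Poisson MSEP matches Monte-Carlo simulation", {
  ctx <- zpredictor("poisson_log", sigma_u = 0.6, n = 5, mu = -0.5,
                    weight = weight_spec("SQ", 0.3))
  ex <- msep(ctx, 1.645)$msep
  set.seed(404)
  N <- 4e5
  z <- rtrunc_norm(N, 1.645)
  y <- rpois(N, 5 * exp(-0.5 + 0.6 * z))
  zt <- predict(ctx, 0:max(y))
  err <- (z - zt[y + 1])^2
  expect_lt(abs(ex - mean(err)), 3 * sd(err) / sqrt(N))
})

test_that("unit-level covariates: Poisson-binomial route equals 2^8 enumeration", {
  set.seed(15)
  X <- matrix(rnorm(8), 8, 1)
  beta <- 0.6
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.7, beta = beta, X = X,
                    weight = weight_spec("AB", 1.4))
  tau <- 1.28
  pkg <- msep_generic(ctx, tau)$msep
  # brute force: every outcome vector, grouped only through its total
  grid <- as.matrix(expand.grid(rep(list(0:1), 8)))
  zt <- predict(ctx, 0:8)
  rule <- quad_rule(tau, Inf, 64)
  w <- exp(rule$logw) / pnorm(tau, lower.tail = FALSE)
  brute <- 0
  for (r in seq_len(nrow(grid))) {
    v <- grid[r, ]
    lik <- sapply(rule$nodes, function(z) {
      p <- plogis(0.7 * z + beta * drop(X))
      prod(ifelse(v == 1, p, 1 - p))
    })
    brute <- brute + sum(w * lik * (rule$nodes - zt[sum(v) + 1])^2)
  }
  expect_equal(pkg, brute, tolerance = 1e-10)
})

test_that("lower tail follows from the mirror symmetry of the logit family", {
  # z -> -z, y -> n - y, mu -> -mu maps the lower conditioning onto the upper
  s <- 0.8; n <- 9; mu <- -0.7; tau <- -0.5
  for (w in list(weight_spec("BP"), weight_spec("SQ", 0.3), weight_spec("AB", 1.6))) {
    lo <- msep(zpredictor("bernoulli_logit", sigma_u = s, n = n, mu = mu,
                          weight = w), tau, tail = "lower")$msep
    up <- msep(zpredictor("bernoulli_logit", sigma_u = s, n = n, mu = -mu,
                          weight = w), -tau, tail = "upper")$msep
    expect_equal(lo, up, tolerance = 1e-10)
  }
})

test_that("two-sided MSEP is the mixture of the two tail MSEPs", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 10, mu = 0.2,
                    weight = weight_spec("AB", 1.2))
  tau <- 1.28
  both <- msep(ctx, tau, tail = "both")$msep
  up <- msep(ctx, tau, tail = "upper")$msep
  lo_ctx <- msep(ctx, -tau, tail = "lower")$msep
  wgt <- pnorm(tau, lower.tail = FALSE)
  expect_equal(both, (up * wgt + lo_ctx * pnorm(-tau)) / (2 * wgt),
               tolerance = 1e-10)
})

test_that("MSEP differences: zero at lambda zero, errors on mismatched scenarios", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.6, n = 10, mu = -1,
                    weight = weight_spec("SQ", 0))
  expect_equal(msep_difference(ctx, tau = 1.28), 0, tolerance = 1e-12)
  other <- zpredictor("bernoulli_logit", sigma_u = 0.9, n = 10, mu = -1)
  expect_error(msep_difference(ctx, other, tau = 1.28), "share")
  # sign is stable under quadrature refinement
  w <- set_weight(ctx, weight_spec("AB", 1.6))
  d64 <- msep_difference(w, tau = 1.28, n_nodes = 64)
  d128 <- msep_difference(w, tau = 1.28, n_nodes = 128)
  expect_lt(abs(d64 - d128), 1e-8)
  expect_identical(sign(d64), sign(d128))
})

test_that("Gaussian-family MSEP agrees with Monte-Carlo", {
  fam <- glmm_family("gaussian_identity", gamma = 1)
  ctx <- zpredictor(fam, sigma_u = 0.7, n = 6, mu = 0.3,
                    weight = weight_spec("AB", 1.0))
  ex <- msep(ctx, 1.28)$msep
  set.seed(505)
  N <- 2e5
  z <- rtrunc_norm(N, 1.28)
  y <- rnorm(N, 6 * 0.3 + 6 * 0.7 * z, sqrt(6))
  err <- (z - predict(ctx, y))^2
  expect_lt(abs(ex - mean(err)), 3 * sd(err) / sqrt(N))
})
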