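test_that("weight specifications behave as declared", {
  expect_equal(weight_spec("BP")$log_w(c(-3, 0, 3)), c(0, 0, 0))
  sq <- weight_spec("SQ", 0.3)
  ab <- weight_spec("AB", 1.6)
  z <- c(-2.5, -1, 0, 1, 2.5)
  expect_equal(sq$log_w(z), sq$log_w(-z))   # even
  expect_equal(ab$log_w(z), ab$log_w(-z))
  expect_equal(weight_spec("SQ", 0)$log_w(z), rep(0, 5))
  expect_error(weight_spec("SQ", -1), "non-negative")
})

test_that("zero-lambda weighted predictors equal the best predictor", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 7, mu = -1)
  for (kind in c("SQ", "AB")) {
    ctx0 <- set_weight(ctx, weight_spec(kind, 0))
    expect_equal(predict(ctx0, 0:7), predict(ctx, 0:7), tolerance = 1e-12)
  }
})

test_that("symmetric scenarios give zero prediction at the central total", {
  for (w in list(weight_spec("BP"), weight_spec("SQ", 0.3), weight_spec("AB", 1.6))) {
    ctx <- zpredictor("bernoulli_logit", sigma_u = 1, n = 10, mu = 0, weight = w)
    expect_equal(predict(ctx, 5), 0, tolerance = 1e-10)
  }
})

test_that("Gaussian-family predictors match conjugate-normal closed forms", {
  gam <- 2; n <- 6; mu <- 0.3; s <- 0.7
  fam <- glmm_family("gaussian_identity", gamma = gam)
  for (y in c(-1.5, 2, 5.5)) {
    post <- gauss_posterior(y, gam, n, mu, s)
    bp <- zpredictor(fam, sigma_u = s, n = n, mu = mu)
    expect_equal(predict(bp, y), post$m, tolerance = 1e-8)
    for (lam in c(0.1, 0.3))
      expect_equal(predict(set_weight(bp, weight_spec("SQ", lam)), y),
                   sq_weighted_normal(post$m, post$v, lam), tolerance = 1e-8)
    for (lam in c(0.5, 1.6))
      expect_equal(predict(set_weight(bp, weight_spec("AB", lam)), y),
                   ab_weighted_normal(post$m, post$v, lam), tolerance = 1e-8)
  }
})

test_that("posterior kernel has the canonical exponential-family form", {
  # mirror symmetry of the Bernoulli kernel at mu = 0
  ctx <- zpredictor("bernoulli_logit", sigma_u = 1, n = 1, mu = 0)
  z <- seq(-3, 3, by = 0.5)
  k0 <- log_posterior_kernel(ctx, 0, z)
  k1 <- log_posterior_kernel(ctx, 1, rev(z))
  expect_equal(k0 - mean(k0), k1 - mean(k1), tolerance = 1e-12)

  # Gaussian family: kernel is the exact conjugate quadratic
  gam <- 1.5; n <- 4; mu <- -0.2; s <- 0.6; y <- 1.7
  g <- zpredictor(glmm_family("gaussian_identity", gamma = gam),
                  sigma_u = s, n = n, mu = mu)
  post <- gauss_posterior(y, gam, n, mu, s)
  kg <- log_posterior_kernel(g, y, z)
  ref <- -(z - post$m)^2 / (2 * post$v)
  expect_equal(kg - max(kg), ref - max(ref), tolerance = 1e-10)

  # derivative in the total: d log f / dY = gamma sigma_u z exactly
  ctx2 <- zpredictor("poisson_log", sigma_u = 0.5, n = 3, mu = 0.2)
  d <- log_posterior_kernel(ctx2, 5, z) - log_posterior_kernel(ctx2, 4, z)
  expect_equal(d, 0.5 * z, tolerance = 1e-12)
})

test_that("weighted predictors are non-decreasing in the cluster total", {
  weights <- list(weight_spec("BP"), weight_spec("SQ", 0.2), weight_spec("SQ", 0.4),
                  weight_spec("AB", 1.2), weight_spec("AB", 2.0))
  for (mu in c(-1, 0.5)) for (s in c(0.3, 1.0)) for (w in weights) {
    ctx <- zpredictor("bernoulli_logit", sigma_u = s, n = 20, mu = mu, weight = w)
    expect_true(all(diff(predict(ctx, 0:20)) >= -1e-9))
    pctx <- zpredictor("poisson_log", sigma_u = s, n = 5, mu = mu, weight = w)
    expect_true(all(diff(predict(pctx, 0:80)) >= -1e-9))
  }
})

test_that("weighted predictors shrink less than the best predictor", {
  # symmetric setting: |z_BP| <= |z_SQ| and |z_AB| at every total
  for (s in c(0.4, 1.0)) {
    bp <- zpredictor("bernoulli_logit", sigma_u = s, n = 12, mu = 0)
    zb <- predict(bp, 0:12)
    for (w in list(weight_spec("SQ", 0.3), weight_spec("AB", 1.6))) {
      zw <- predict(set_weight(bp, w), 0:12)
      expect_true(all(abs(zw) >= abs(zb) - 1e-9))
    }
  }
})

test_that("the cluster total is sufficient: unit-level and cluster-level routes agree", {
  # identical covariates per unit: Poisson-binomial route must equal the
  # closed binomial route exactly
  cl <- zpredictor("bernoulli_logit", sigma_u = 0.7, n = 6, mu = -0.4,
                   weight = weight_spec("AB", 1.2))
  un <- zpredictor("bernoulli_logit", sigma_u = 0.7, beta = -0.4,
                   X = matrix(1, 6, 1), weight = weight_spec("AB", 1.2))
  expect_equal(predict(cl, 0:6), predict(un, 0:6), tolerance = 1e-12)
})

test_that("best predictor matches the Monte-Carlo posterior mean", {
  set.seed(202)
  N <- 1e6
  z <- rnorm(N)
  y <- rbinom(N, 7, plogis(-1 + 0.8 * z))
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 7, mu = -1)
  for (k in c(3, 5, 7)) {
    sel <- z[y == k]
    expect_lt(abs(predict(ctx, k) - mean(sel)), 3 * sd(sel) / sqrt(length(sel)))
  }
})

test_that("threshold inversion satisfies its defining inequalities", {
  for (w in list(weight_spec("BP"), weight_spec("AB", 1.6))) {
    ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 20, mu = -0.5,
                      weight = w)
    tau <- 1.0
    y <- invert_threshold(ctx, tau)
    expect_true(is.finite(y))
    expect_lt(predict(ctx, y), tau)
    expect_gte(predict(ctx, y + 1), tau)
  }
  # Poisson support
  pctx <- zpredictor("poisson_log", sigma_u = 0.5, n = 10, mu = -1)
  yp <- invert_threshold(pctx, 1.28)
  expect_lt(predict(pctx, yp), 1.28)
  expect_gte(predict(pctx, yp + 1), 1.28)
})

test_that("inversion sentinels mark unreachable and always-flagged thresholds", {
  # weakly informative cluster never reaches a high threshold
  low <- zpredictor("bernoulli_logit", sigma_u = 0.3, n = 5, mu = 0)
  expect_identical(invert_threshold(low, 2.33), Inf)
  expect_error(invert_threshold(zpredictor("bernoulli_logit", sigma_u = 0,
                                           n = 5, mu = 0), 1.28),
               "sigma_u > 0")
})

test_that("continuous outcomes invert to the conjugate closed-form root", {
  gam <- 1; n <- 8; mu <- 0.2; s <- 0.6; tau <- 1.28
  ctx <- zpredictor(glmm_family("gaussian_identity", gamma = gam),
                    sigma_u = s, n = n, mu = mu)
  y <- invert_threshold(ctx, tau)
  # z_BP = v gamma s (y - n mu) with v = 1/(1 + gamma n s^2)
  y_closed <- n * mu + tau * (1 + gam * n * s^2) / (gam * s)
  expect_equal(y, y_closed, tolerance = 1e-8)
  expect_lt(abs(predict(ctx, y) - tau), 1e-9)
})

test_that("inadmissible square weights raise an explicit divergence error", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 7, mu = -1,
                    weight = weight_spec("SQ", 0.5))
  expect_error(predict(ctx, 3), "lambda")
  pctx <- zpredictor("poisson_log", sigma_u = 0.5, n = 5, mu = 0,
                     weight = weight_spec("SQ", 0.6))
  expect_error(predict(pctx, 3), "lambda")
})

test_that("scenario simulation is reproducible and family-correct", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 7, mu = -1)
  d1 <- simulate(ctx, nsim = 50, seed = 3)
  d2 <- simulate(ctx, nsim = 50, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$y_total >= 0 & d1$y_total <= 7))
  pd <- simulate(zpredictor("poisson_log", sigma_u = 0.5, n = 5, mu = 0),
                 z = c(-1, 0, 2), seed = 4)
  expect_identical(nrow(pd), 3L)
})
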