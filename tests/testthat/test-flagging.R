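test_that("flagging rates at boundary thresholds are exact", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.6, n = 10, mu = -1)
  # unreachable threshold: probability exactly zero
  weak <- zpredictor("bernoulli_logit", sigma_u = 0.3, n = 5, mu = 0)
  fr <- flag_rates(weak, 2.33)
  expect_identical(fr$threshold_y, Inf)
  expect_identical(fr$incorrect, 0)
  expect_identical(fr$correct, 0)
  # flag-everything threshold: probability one
  fr1 <- flag_rates(ctx, 1.28, threshold = -1)
  expect_equal(fr1$incorrect, 1, tolerance = 1e-12)
  expect_equal(fr1$correct, 1, tolerance = 1e-12)
  expect_error(flag_rates(zpredictor("bernoulli_logit", sigma_u = 0, n = 5,
                                     mu = 0), 1.28), "sigma_u")
})

test_that("flagging rates match simulated cluster populations", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 20, mu = -1,
                    weight = weight_spec("AB", 1.6))
  tau <- 1.28
  thr <- invert_threshold(ctx, tau)
  fr <- flag_rates(ctx, tau, threshold = thr)
  set.seed(606)
  N <- 4e5
  z <- rnorm(N)
  y <- rbinom(N, 20, plogis(-1 + 0.8 * z))
  flagged <- y > thr
  for (side in c("incorrect", "correct")) {
    sel <- if (side == "incorrect") z < tau else z > tau
    phat <- mean(flagged[sel])
    se <- sqrt(phat * (1 - phat) / sum(sel))
    expect_lt(abs(fr[[side]] - phat), 3 * se + 1e-12)
  }
})

test_that("sensitivity dominates 1-specificity and both fall with the threshold", {
  for (mu in c(-1, 0)) for (s in c(0.5, 1)) {
    ctx <- zpredictor("bernoulli_logit", sigma_u = s, n = 20, mu = mu)
    tau <- 1.28
    incs <- sapply(5:15, function(t) incorrect_rate(ctx, tau, threshold = t))
    cors <- sapply(5:15, function(t) correct_rate(ctx, tau, threshold = t))
    expect_true(all(diff(incs) <= 1e-12))
    expect_true(all(diff(cors) <= 1e-12))
    expect_true(all(cors >= incs - 1e-12))
  }
})

test_that("the conditional quantile y_alpha matches a brute-force oracle", {
  mu <- -0.5; s <- 0.8; tau <- 1.28; n <- 5
  ctx <- zpredictor("bernoulli_logit", sigma_u = s, n = n, mu = mu)
  # naive fine-trapezoid tail probabilities, independent of the package rule
  tail_brute <- sapply(0:n, function(y)
    1 - riemann_phi(function(z) pbinom(y, n, plogis(mu + s * z)), -8, tau) /
      pnorm(tau))
  for (alpha in c(0.05, 0.1, 0.3)) {
    ya <- y_alpha_quantile(ctx, tau, alpha)
    ya_brute <- min(which(tail_brute <= alpha)) - 1L
    expect_identical(as.integer(ya), ya_brute)
    # definitional inequalities
    expect_lte(tail_brute[ya + 1], alpha)
    if (ya > 0) expect_gt(tail_brute[ya], alpha)
  }
  # permissive alpha allows flagging from the support minimum upward
  expect_identical(as.integer(y_alpha_quantile(ctx, tau, 0.99)), 0L)
  expect_error(y_alpha_quantile(ctx, tau, 1.2), "alpha")
})

test_that("self-calibration lands on y_alpha and respects the nominal rate", {
  scenarios <- expand.grid(mu = c(-1, 0), n = c(20, 100), s = c(0.5, 0.9))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    ctx <- zpredictor("bernoulli_logit", sigma_u = sc$s, n = sc$n, mu = sc$mu)
    for (kind in c("AB", "SQ")) {
      cal <- calibrate(ctx, kind, tau = 1.28, alpha = 0.1)
      expect_true(cal$feasible)
      expect_lte(cal$achieved_incorrect, 0.1 + 1e-10)
      if (cal$exact_boundary) {
        expect_identical(cal$threshold_y, cal$y_alpha)
        # the calibrated predictor crosses tau between y_alpha and y_alpha + 1
        ctxs <- set_weight(ctx, weight_spec(kind, cal$lambda_star))
        expect_lt(predict(ctxs, cal$y_alpha), 1.28)
        expect_gte(predict(ctxs, cal$y_alpha + 1), 1.28)
      } else {
        expect_gte(cal$threshold_y, cal$y_alpha)
      }
    }
  }
})

test_that("exactly calibrated square and absolute rules flag identical sets", {
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.5, n = 20, mu = -0.5)
  sq <- calibrate(ctx, "SQ", tau = 1.28, alpha = 0.1)
  ab <- calibrate(ctx, "AB", tau = 1.28, alpha = 0.1)
  expect_true(sq$exact_boundary && ab$exact_boundary)
  expect_identical(sq$threshold_y, ab$threshold_y)
  y <- 0:20
  expect_identical(y > sq$threshold_y, y > ab$threshold_y)
})

test_that("infeasible scenarios are reported, not forced", {
  # small cluster, high mean: even flagging only Y = n exceeds alpha
  ctx <- zpredictor("bernoulli_logit", sigma_u = 0.3, n = 5, mu = 1)
  cal <- calibrate(ctx, "AB", tau = 1.28, alpha = 0.05)
  expect_false(cal$feasible)
  expect_true(is.na(cal$lambda_star))
  # the cause: y_alpha pinned at the support maximum
  expect_identical(as.integer(cal$y_alpha), 5L)
  expect_error(calibrate(ctx, "AB", tau = 1.28, alpha = 0.05,
                         lambda_bracket = c(2, 1)), "bracket")
})

test_that("flag decisions agree between predictor and count comparisons", {
  for (w in list(weight_spec("BP"), weight_spec("AB", 1.6), weight_spec("SQ", 0.3))) {
    ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 20, mu = -0.5,
                      weight = w)
    tau <- 1.0
    thr <- invert_threshold(ctx, tau)
    expect_identical(flag(ctx, tau, 0:20), (0:20) > thr)
    # a total exactly at the threshold is not flagged
    expect_false(flag(ctx, tau, thr))
  }
  # Gaussian family: matches the closed-form rule
  gam <- 1; n <- 8; mu <- 0.2; s <- 0.6; tau <- 1.28
  g <- zpredictor(glmm_family("gaussian_identity", gamma = gam),
                  sigma_u = s, n = n, mu = mu)
  y_star <- n * mu + tau * (1 + gam * n * s^2) / (gam * s)
  ys <- y_star + seq(-2, 2, by = 0.25) + 0.125  # avoid the exact boundary
  expect_identical(flag(g, tau, ys), ys > y_star)
})
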