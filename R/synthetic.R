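#' Simulate clustered outcomes from a canonical-link GLMM
#'
#' Draws standardized random effects \eqn{z_i \sim N(0,1)}, cluster-level
#' covariates (standard normal, then standardized to sample mean 0 and
#' variance 1 when requested) and unit outcomes with linear predictor
#' \eqn{\eta_{ij} = \sigma_u z_i + \beta' x_i}. The result carries both the
#' unit rows and the per-cluster summary (size, covariates, total, true
#' \eqn{z_i}), and is byte-reproducible under a fixed seed.
#'
#' @param family Family name or [glmm_family()] object (binary or Poisson).
#' @param m Number of clusters.
#' @param sizes Cluster sizes: a scalar, a length-`m` vector, or a function
#'   `f(m)` returning sizes.
#' @param mu Intercept of the linear predictor.
#' @param beta Coefficients of the cluster-level covariates (may be empty).
#' @param sigma_u Random-effect scale.
#' @param standardize Standardize simulated covariates to sample mean 0 and
#'   variance 1.
#' @param seed Integer seed.
#' @return An object of class `"clustered_dataset"`: list with `data`
#'   (unit rows: `cluster`, `y`, covariates), `clusters` (per-cluster
#'   frame: `cluster`, `n`, covariates, `y_total`, `z`), `family`, `mu`,
#'   `beta`, `sigma_u`, `seed`.
#' @examples
#' d <- simulate_clusters("bernoulli_logit", m = 20, sizes = 50, mu = -1,
#'                        beta = c(0.2, -0.3), sigma_u = 0.5, seed = 1)
#' head(d$clusters)
#' @export
simulate_clusters <- function(family = "bernoulli_logit", m, sizes, mu,
                              beta = numeric(0), sigma_u,
                              standardize = TRUE, seed = NULL) {
  if (is.character(family)) family <- glmm_family(family)
  if (!family$name %in% c("bernoulli_logit", "binomial_logit", "poisson_log"))
    stop(sprintf("simulation implemented for binary and Poisson outcomes, not '%s'",
                 family$name))
  if (m < 1) stop("'m' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n_i <- if (is.function(sizes)) sizes(m) else
    if (length(sizes) == 1L) rep(as.integer(sizes), m) else as.integer(sizes)
  if (length(n_i) != m || any(n_i < 1)) stop("invalid cluster sizes")
  p <- length(beta)
  X <- if (p > 0) matrix(stats::rnorm(m * p), m, p) else matrix(0, m, 0)
  if (p > 0 && standardize)
    X <- scale(X)  # sample mean 0, sample variance 1
  colnames(X) <- if (p > 0) paste0("x", seq_len(p)) else character(0)
  z <- stats::rnorm(m)
  eta_i <- mu + (if (p > 0) drop(X %*% beta) else 0) + sigma_u * z
  y <- switch(
    family$name,
    bernoulli_logit = ,
    binomial_logit = stats::rbinom(sum(n_i), 1L,
                                   rep(stats::plogis(eta_i), n_i)),
    poisson_log = stats::rpois(sum(n_i), rep(exp(eta_i), n_i))
  )
  cluster <- rep(seq_len(m), n_i)
  data <- data.frame(cluster = cluster, y = y)
  if (p > 0) data <- cbind(data, as.data.frame(X[cluster, , drop = FALSE]))
  clusters <- data.frame(cluster = seq_len(m), n = n_i)
  if (p > 0) clusters <- cbind(clusters, as.data.frame(X))
  clusters$y_total <- as.vector(tapply(y, cluster, sum))
  clusters$z <- z
  structure(list(data = data, clusters = clusters, family = family$name,
                 mu = mu, beta = beta, sigma_u = sigma_u, seed = seed),
            class = "clustered_dataset")
}

#' @export
print.clustered_dataset <- function(x, ...) {
  cat(sprintf("Clustered dataset (%s): %d clusters, %d units, %d cluster covariate(s)\n",
              x$family, nrow(x$clusters), nrow(x$data), length(x$beta)))
  cat(sprintf("  generating values: mu = %g, sigma_u = %g%s\n", x$mu, x$sigma_u,
              if (length(x$beta)) paste0(", beta = ",
                                         paste(x$beta, collapse = ", ")) else ""))
  invisible(x)
}

#' Simulate an asthma-revisit-like dataset
#'
#' Generates a synthetic dataset emulating the structure of a study of
#' asthma-related emergency department revisits clustered within zip
#' codes: 248 clusters, cluster sizes of at least 100 (about 180 on
#' average, roughly 45,000 units in total), a binary revisit outcome, and
#' two cluster-level covariates (a pollution score and average income)
#' standardized to sample mean 0 and variance 1. The generating parameters
#' are this package's choices of a realistic regime - a revisit
#' probability around 12% at the average covariates, modest covariate
#' effects of opposite sign, and between-cluster heterogeneity
#' \eqn{\sigma_u = 0.35} - not estimates from any restricted data source.
#'
#' @param seed Integer seed.
#' @param m Number of clusters.
#' @param mu,beta,sigma_u Generating parameters.
#' @param mean_extra Mean number of units per cluster beyond the minimum
#'   of 100 (Poisson distributed).
#' @return A [simulate_clusters()] result.
#' @export
simulate_asthma_like <- function(seed = 1, m = 248, mu = -2,
                                 beta = c(0.2, -0.2), sigma_u = 0.35,
                                 mean_extra = 80) {
  simulate_clusters("bernoulli_logit", m = m,
                    sizes = function(m) 100L + stats::rpois(m, mean_extra),
                    mu = mu, beta = beta, sigma_u = sigma_u, seed = seed)
}

#' Fit a random-intercept GLMM by maximum likelihood
#'
#' Fits the canonical-link random-intercept model by adaptive Gauss-Hermite
#' maximum likelihood via \pkg{lme4}. With cluster-level covariates the
#' data are aggregated to cluster totals first (binomial totals for the
#' logit link, Poisson totals with a log-size offset for the log link),
#' which is likelihood-equivalent and much faster.
#'
#' @param dataset A [simulate_clusters()] result, or any list with `data`
#'   (columns `cluster`, `y`, covariates `x1`, `x2`, ...) and `clusters`
#'   (columns `cluster`, `n`, covariates).
#' @param family Family name; default taken from the dataset.
#' @param nAGQ Number of adaptive quadrature points (default 25).
#' @return An object of class `"zflag_fit"`: `mu`, `beta`, `sigma_u`,
#'   `gamma`, `loglik`, `converged`, `se` (asymptotic standard errors of
#'   the fixed effects), `vcov`, `family`, and the underlying `fit`.
#' @examples
#' d <- simulate_clusters("bernoulli_logit", m = 30, sizes = 40, mu = -1,
#'                        beta = 0.3, sigma_u = 0.5, seed = 2)
#' fit_glmm(d)
#' @export
fit_glmm <- function(dataset, family = NULL, nAGQ = 25) {
  if (is.null(family)) family <- dataset$family
  if (is.character(family)) family <- glmm_family(family)
  cl <- dataset$clusters
  xnames <- grep("^x[0-9]+$", names(cl), value = TRUE)
  rhs <- paste(c(xnames, "(1 | cluster)"), collapse = " + ")
  fit <- switch(
    family$name,
    bernoulli_logit = ,
    binomial_logit = lme4::glmer(
      stats::as.formula(paste("cbind(y_total, n - y_total) ~", rhs)),
      data = cl, family = stats::binomial(), nAGQ = nAGQ),
    poisson_log = lme4::glmer(
      stats::as.formula(paste("y_total ~", rhs, "+ offset(log(n))")),
      data = cl, family = stats::poisson(), nAGQ = nAGQ),
    stop(sprintf("fitting not implemented for family '%s'", family$name))
  )
  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  sdre <- sqrt(unname(lme4::VarCorr(fit)$cluster[1]))
  conv <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  structure(
    list(mu = unname(fe[1]), beta = unname(fe[-1]), sigma_u = sdre,
         gamma = 1, loglik = as.numeric(stats::logLik(fit)),
         converged = conv, se = sqrt(diag(vc)), vcov = vc,
         family = family$name, fit = fit),
    class = "zflag_fit"
  )
}

#' @export
print.zflag_fit <- function(x, ...) {
  cat(sprintf("Random-intercept GLMM fit (%s)%s\n", x$family,
              if (x$converged) "" else "  [did not converge]"))
  cat(sprintf("  mu = %.4f, sigma_u = %.4f, logLik = %.2f\n",
              x$mu, x$sigma_u, x$loglik))
  if (length(x$beta))
    cat("  beta:", paste(sprintf("%.4f", x$beta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.zflag_fit <- function(object, ...) {
  out <- c(mu = object$mu)
  if (length(object$beta))
    out <- c(out, stats::setNames(object$beta,
                                  paste0("x", seq_along(object$beta))))
  c(out, sigma_u = object$sigma_u)
}

#' @export
logLik.zflag_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2L, class = "logLik")
}

#' Validation-sample estimate of the standardized random effect
#'
#' Converts an observed cluster proportion into an estimate of the
#' standardized random effect under the logit link:
#' \deqn{\hat z = [\mathrm{logit}(\hat p) - \hat\eta] / \hat\sigma_u.}
#' Requires \eqn{0 < \hat p < 1}; restricting attention to large clusters
#' (at least 100 units) keeps the estimated proportions away from the
#' boundary.
#'
#' @param p_hat Observed proportion(s), strictly inside (0, 1).
#' @param eta_hat Fitted cluster linear predictor(s)
#'   \eqn{\hat\mu + \hat\beta' x_i}.
#' @param sigma_hat Fitted random-effect scale, positive.
#' @return Estimated standardized random effect(s).
#' @export
validation_zhat <- function(p_hat, eta_hat, sigma_hat) {
  if (any(p_hat <= 0 | p_hat >= 1))
    stop("'p_hat' must lie strictly inside (0, 1); degenerate cluster proportions cannot be converted")
  if (sigma_hat <= 0) stop("'sigma_hat' must be positive")
  (stats::qlogis(p_hat) - eta_hat) / sigma_hat
}

#' Average squared prediction error by ordered subgroups
#'
#' Orders clusters by their validation-sample random-effect estimates,
#' partitions them into quantile bins, and averages the squared difference
#' between the (training-sample) predictions and the validation estimates
#' within each bin. The extreme bins show how predictors behave for
#' extreme random effects.
#'
#' @param predictions Predicted random effects (training sample).
#' @param zhat_valid Validation-sample estimates, aligned with
#'   `predictions`.
#' @param n_groups Number of quantile bins (default 10).
#' @return Data frame with `group` (1 = lowest), `n` and `msep`; empty
#'   groups carry `n = 0` and `NA`.
#' @export
subgroup_msep <- function(predictions, zhat_valid, n_groups = 10) {
  if (length(predictions) != length(zhat_valid))
    stop("'predictions' and 'zhat_valid' must have equal length")
  m <- length(zhat_valid)
  grp <- as.integer(ceiling(rank(zhat_valid, ties.method = "first") * n_groups / m))
  sq <- (predictions - zhat_valid)^2
  out <- data.frame(group = seq_len(n_groups))
  out$n <- vapply(out$group, function(g) sum(grp == g), integer(1))
  out$msep <- vapply(out$group, function(g)
    if (any(grp == g)) mean(sq[grp == g]) else NA_real_, numeric(1))
  out
}

#' Agreement between flags and extreme labels
#'
#' Cross-tabulates flag decisions against "extreme" labels (e.g. the top
#' 10% of validation-sample proportions) and estimates the realized
#' incorrect flagging rate among non-extreme clusters.
#'
#' @param flags Logical flag decisions.
#' @param extreme_labels Logical extreme labels, same length.
#' @return List with `counts` (2x2 table: flag x extreme) and
#'   `incorrect_rate_estimate` (flagged non-extreme / non-extreme).
#' @export
flag_agreement <- function(flags, extreme_labels) {
  if (length(flags) != length(extreme_labels))
    stop("'flags' and 'extreme_labels' must have equal length")
  counts <- table(factor(flags, levels = c(TRUE, FALSE), labels = c("flag", "noflag")),
                  factor(extreme_labels, levels = c(TRUE, FALSE),
                         labels = c("extreme", "not_extreme")))
  n_not <- sum(!extreme_labels)
  list(counts = counts,
       incorrect_rate_estimate = if (n_not > 0)
         sum(flags & !extreme_labels) / n_not else NA_real_)
}

#' End-to-end train/validate example workflow on synthetic data
#'
#' Runs the complete pipeline on an asthma-revisit-like simulation: split
#' units 50/50 within clusters into training and validation halves, fit
#' the random-intercept logistic model to the training half, compute the
#' best predictor and weighted predictors of each cluster's random effect
#' from the training totals, estimate "true" random effects from the
#' validation proportions, compare prediction accuracy by ordered
#' subgroups, self-calibrate SQ and AB flagging rules at
#' (\eqn{\tau}, \eqn{\alpha}), and tabulate agreement between flags and
#' the top-`extreme_q` fraction of validation proportions. Clusters whose
#' validation proportion is degenerate (0 or 1) are dropped with a
#' message.
#'
#' @param seed Integer seed controlling the simulation and the split.
#' @param dataset Optional [simulate_clusters()] dataset; defaults to
#'   [simulate_asthma_like()] under `seed`.
#' @param tau Flagging threshold (default 1.28, the upper 10% point).
#' @param alpha Nominal incorrect flagging rate (default 0.1).
#' @param sq_lambda,ab_lambda Fixed weight settings evaluated for
#'   prediction accuracy.
#' @param extreme_q Fraction of clusters labelled extreme in the
#'   validation sample (default 0.1).
#' @param train_fraction Fraction of each cluster's units assigned to the
#'   training half.
#' @param n_groups Subgroup count for [subgroup_msep()].
#' @return An object of class `"zflag_example"`: the `fit`, a
#'   `predictions` frame (per cluster: training/validation totals, BP and
#'   weighted predictions, calibrated flags), `subgroups` (MSEP by ordered
#'   subgroup and predictor), `agreement` (per flagging rule), the
#'   calibration summaries, and the settings used.
#' @examples
#' \donttest{
#' ex <- run_example(seed = 7)
#' print(ex)
#' }
#' @export
run_example <- function(seed = 1, dataset = NULL, tau = 1.28, alpha = 0.1,
                        sq_lambda = c(0.3, 0.4), ab_lambda = c(1.0, 1.4, 1.8),
                        extreme_q = 0.1, train_fraction = 0.5,
                        n_groups = 10) {
  if (is.null(dataset)) dataset <- simulate_asthma_like(seed = seed)
  set.seed(seed + 1L)
  dat <- dataset$data
  ## random within-cluster split into training and validation halves
  split_tr <- unlist(lapply(split(seq_len(nrow(dat)), dat$cluster), function(idx) {
    sample(idx, round(length(idx) * train_fraction))
  }), use.names = FALSE)
  is_train <- logical(nrow(dat)); is_train[split_tr] <- TRUE
  tr <- stats::aggregate(cbind(y = dat$y[is_train]),
                         by = list(cluster = dat$cluster[is_train]), FUN = sum)
  tr$n <- as.vector(table(dat$cluster[is_train]))
  va <- stats::aggregate(cbind(y = dat$y[!is_train]),
                         by = list(cluster = dat$cluster[!is_train]), FUN = sum)
  va$n <- as.vector(table(dat$cluster[!is_train]))
  cl <- dataset$clusters
  xnames <- grep("^x[0-9]+$", names(cl), value = TRUE)
  train_set <- list(
    clusters = cbind(data.frame(cluster = tr$cluster, n = tr$n,
                                y_total = tr$y),
                     cl[match(tr$cluster, cl$cluster), xnames, drop = FALSE]),
    family = dataset$family)
  fit <- fit_glmm(train_set)
  eta_hat <- fit$mu + (if (length(xnames))
    drop(as.matrix(cl[, xnames, drop = FALSE]) %*% fit$beta) else 0)
  ## validation "true" z from observed proportions
  p_valid <- va$y / va$n
  ok <- p_valid > 0 & p_valid < 1
  if (any(!ok))
    message(sprintf("dropping %d cluster(s) with degenerate validation proportions",
                    sum(!ok)))
  zhat_valid <- validation_zhat(p_valid[ok], eta_hat[ok], fit$sigma_u)
  ## per-cluster predictor contexts from the training fit
  weights <- c(list(weight_spec("BP")),
               lapply(sq_lambda, function(l) weight_spec("SQ", l)),
               lapply(ab_lambda, function(l) weight_spec("AB", l)))
  wlabs <- vapply(weights, function(w)
    if (w$kind == "BP") "BP" else sprintf("%s_%g", w$kind, w$lambda), character(1))
  preds <- matrix(NA_real_, sum(ok), length(weights),
                  dimnames = list(NULL, wlabs))
  flags_sq <- flags_ab <- logical(sum(ok))
  cal_sq <- cal_ab <- vector("list", sum(ok))
  kept <- which(ok)
  for (r in seq_along(kept)) {
    i <- kept[r]
    ctx <- zpredictor(dataset$family, sigma_u = fit$sigma_u, n = tr$n[i],
                      mu = eta_hat[i])
    for (j in seq_along(weights))
      preds[r, j] <- predict(set_weight(ctx, weights[[j]]), tr$y[i])
    cal_sq[[r]] <- calibrate(ctx, "SQ", tau, alpha)
    cal_ab[[r]] <- calibrate(ctx, "AB", tau, alpha)
    flags_sq[r] <- tr$y[i] > cal_sq[[r]]$threshold_y
    flags_ab[r] <- tr$y[i] > cal_ab[[r]]$threshold_y
  }
  flags_bp <- preds[, "BP"] > tau
  extreme <- rank(-p_valid[ok], ties.method = "first") <=
    round(extreme_q * sum(ok))
  subgroups <- do.call(rbind, lapply(wlabs, function(lb) {
    cbind(predictor = lb, subgroup_msep(preds[, lb], zhat_valid, n_groups))
  }))
  agreement <- list(BP = flag_agreement(flags_bp, extreme),
                    SQ = flag_agreement(flags_sq, extreme),
                    AB = flag_agreement(flags_ab, extreme))
  predictions <- cbind(
    data.frame(cluster = tr$cluster[kept], n_train = tr$n[kept],
               y_train = tr$y[kept], n_valid = va$n[kept],
               p_valid = p_valid[kept], zhat_valid = zhat_valid),
    as.data.frame(preds),
    data.frame(flag_bp = flags_bp, flag_sq = flags_sq, flag_ab = flags_ab,
               extreme = extreme))
  structure(
    list(fit = fit, predictions = predictions, subgroups = subgroups,
         agreement = agreement,
         calibrations = list(SQ = cal_sq, AB = cal_ab),
         settings = list(seed = seed, tau = tau, alpha = alpha,
                         extreme_q = extreme_q,
                         train_fraction = train_fraction),
         dropped = sum(!ok)),
    class = "zflag_example"
  )
}

#' @export
print.zflag_example <- function(x, ...) {
  cat("Synthetic train/validate workflow\n")
  print(x$fit)
  s <- x$settings
  cat(sprintf("  flagging at tau = %g, alpha = %g; %d clusters analysed%s\n",
              s$tau, s$alpha, nrow(x$predictions),
              if (x$dropped) sprintf(" (%d dropped)", x$dropped) else ""))
  for (nm in names(x$agreement)) {
    ct <- x$agreement[[nm]]$counts
    cat(sprintf("  %s: flagged %d extreme and %d non-extreme (incorrect rate %.3f)\n",
                nm, ct["flag", "extreme"], ct["flag", "not_extreme"],
                x$agreement[[nm]]$incorrect_rate_estimate))
  }
  ext <- x$subgroups[x$subgroups$group %in% c(1, max(x$subgroups$group)), ]
  cat("  MSEP in extreme subgroups:\n")
  for (g in unique(ext$group)) {
    rows <- ext[ext$group == g, ]
    cat(sprintf("    group %d: %s\n", g,
                paste(sprintf("%s %.3f", rows$predictor, rows$msep),
                      collapse = ", ")))
  }
  invisible(x)
}
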