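#' Exact incorrect and correct flagging probabilities
#'
#' A cluster is flagged as extreme when its predicted random effect exceeds
#' the threshold \eqn{\tau}; by monotonicity of the weighted predictor in
#' the cluster total this is the count rule \eqn{Y_\cdot > y_{\cdot,\tau}}
#' with \eqn{y_{\cdot,\tau}} from [invert_threshold()]. The incorrect
#' flagging probability (1 - specificity) is
#' \deqn{\Pr\{\tilde z_w > \tau \mid z < \tau\} = 1 -
#'   \int_{-\infty}^{\tau} F(y_{\cdot,\tau} \mid z)\,\phi(z)\,dz / \Phi(\tau)}
#' and the correct flagging probability (sensitivity) is
#' \deqn{\Pr\{\tilde z_w > \tau \mid z > \tau\} = 1 -
#'   \int_{\tau}^{\infty} F(y_{\cdot,\tau} \mid z)\,\phi(z)\,dz /
#'   [1 - \Phi(\tau)],}
#' where \eqn{F(\cdot \mid z)} is the conditional cdf of the cluster total.
#' Both integrals are evaluated with the bounded quadrature rule; the
#' normalizers use the exact normal cdf. An unreachable threshold (the
#' `Inf` sentinel from inversion) gives probability 0 exactly.
#'
#' @param object A [zpredictor()] object with `sigma_u > 0`.
#' @param tau Flagging threshold on the standardized random-effect scale.
#' @param threshold Optional precomputed count threshold
#'   \eqn{y_{\cdot,\tau}}; defaults to `invert_threshold(object, tau)`.
#' @param n_nodes Nodes for the bounded quadrature (default 64).
#' @return `flag_rates()` returns a list with `incorrect`, `correct` and
#'   `threshold_y`; `incorrect_rate()` and `correct_rate()` return the
#'   single probability.
#' @examples
#' ctx <- zpredictor("bernoulli_logit", sigma_u = 0.6, n = 20, mu = -1,
#'                   weight = weight_spec("AB", 1.6))
#' flag_rates(ctx, tau = 1.28)
#' @export
flag_rates <- function(object, tau, threshold = NULL, n_nodes = 64L) {
  stopifnot(inherits(object, "zpredictor"))
  if (object$lp$sigma_u <= 0) stop("flagging rates require sigma_u > 0")
  if (is.null(threshold)) threshold <- invert_threshold(object, tau)
  if (is.infinite(threshold) && threshold > 0)
    return(list(incorrect = 0, correct = 0, threshold_y = threshold))
  lo <- quad_rule(-Inf, tau, n_nodes)
  hi <- quad_rule(tau, Inf, n_nodes)
  Fcdf <- function(z) total_cdf_z(object$family, object$lp, threshold, z)
  inc <- 1 - sum(exp(lo$logw) * Fcdf(lo$nodes)) / stats::pnorm(tau)
  cor <- 1 - sum(exp(hi$logw) * Fcdf(hi$nodes)) /
    stats::pnorm(tau, lower.tail = FALSE)
  list(incorrect = min(max(inc, 0), 1), correct = min(max(cor, 0), 1),
       threshold_y = threshold)
}

#' @rdname flag_rates
#' @export
incorrect_rate <- function(object, tau, threshold = NULL, n_nodes = 64L)
  flag_rates(object, tau, threshold, n_nodes)$incorrect

#' @rdname flag_rates
#' @export
correct_rate <- function(object, tau, threshold = NULL, n_nodes = 64L)
  flag_rates(object, tau, threshold, n_nodes)$correct

#' Upper quantile of the cluster total conditional on a non-extreme effect
#'
#' Returns the smallest count \eqn{y_\alpha} with
#' \eqn{\Pr\{Y_\cdot > y_\alpha \mid z < \tau\} \le \alpha}, where the
#' conditional distribution mixes the family's total distribution over the
#' truncated-normal law of \eqn{z} below \eqn{\tau} (bounded quadrature,
#' normalized by the exact \eqn{\Phi(\tau)}). This is the count threshold a
#' self-calibrated flagging rule must reproduce.
#'
#' @inheritParams flag_rates
#' @param alpha Nominal incorrect flagging rate, in (0, 1).
#' @return The count \eqn{y_\alpha} (possibly `min(support) - 1` when
#'   `alpha` is close to 1).
#' @export
y_alpha_quantile <- function(object, tau, alpha, n_nodes = 64L) {
  stopifnot(inherits(object, "zpredictor"))
  if (object$lp$sigma_u <= 0) stop("'sigma_u' must be positive")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  tailp <- make_tailp(object, tau, n_nodes)
  y_alpha_search(object, tailp, alpha)
}

## Pr{Y. > y | z < tau} as a function of the count threshold y.
make_tailp <- function(object, tau, n_nodes) {
  lo <- quad_rule(-Inf, tau, n_nodes)
  w <- exp(lo$logw)
  ptau <- stats::pnorm(tau)
  function(y) {
    1 - sum(w * total_cdf_z(object$family, object$lp, y, lo$nodes)) / ptau
  }
}

## Smallest y with tailp(y) <= alpha, by monotone bisection over the support.
y_alpha_search <- function(object, tailp, alpha) {
  if (tailp(0) <= alpha) {
    if (tailp(-1) <= alpha) return(-1L) else return(0L)
  }
  hi <- if (object$family$name == "poisson_log") {
    h <- max(8L, as.integer(ceiling(sum(exp(object$lp$xb)))))
    cap <- poisson_truncation(sum(exp(object$lp$xb)) *
                                exp(object$lp$sigma_u * 8), 1e-12)
    while (tailp(h) > alpha && h < cap) h <- h * 2L
    min(h, cap)
  } else object$lp$n
  if (tailp(hi) > alpha) return(hi)   # flagging beyond the support: rate 0
  lo <- 0L
  ## invariant: tailp(lo) > alpha >= tailp(hi)
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (tailp(mid) > alpha) lo <- mid else hi <- mid
  }
  hi
}

#' Self-calibrate a weighted predictor's tuning parameter
#'
#' Finds the weighting parameter \eqn{\lambda^*} for which the simple rule
#' "flag when \eqn{\tilde z_{\lambda^*} > \tau}" has incorrect flagging
#' probability at most \eqn{\alpha}, and comes as close to \eqn{\alpha} as
#' the discreteness of the cluster total allows. The calibration equates
#' the predictor's count threshold with the conditional quantile
#' \eqn{y_\alpha} of [y_alpha_quantile()] by solving
#' \eqn{\tilde z_\lambda(y_\alpha) = \tau} (root-finding over
#' \eqn{\lambda}; the map \eqn{\lambda \mapsto y_{\cdot,\tau}(\lambda)} is a
#' non-increasing step function because larger \eqn{\lambda} shrinks less).
#'
#' A scenario is infeasible (`feasible = FALSE`, returned with the BP
#' rule's rates) in two situations: the best predictor's rule already
#' exceeds \eqn{\alpha} (weighted predictors shrink less, so every
#' calibrated rule would be worse), or \eqn{y_\alpha} equals the support
#' maximum - with a bounded, highly discrete total even the smallest
#' nonempty flag set \eqn{\{Y_\cdot = n\}} can have conditional tail
#' probability above \eqn{\alpha}, so the calibrated rule could only flag
#' the empty set. If no \eqn{\lambda} inside the bracket reaches
#' \eqn{y_\alpha}, the bracket edge - the largest achievable incorrect
#' rate still at or below \eqn{\alpha} - is returned with
#' `exact_boundary = FALSE`.
#'
#' @param object A [zpredictor()] object describing the scenario (its own
#'   weight is ignored; the BP baseline and the calibrated weight are
#'   derived from it).
#' @param weight_kind `"AB"` or `"SQ"`.
#' @param tau Flagging threshold.
#' @param alpha Nominal incorrect flagging rate in (0, 1).
#' @param lambda_bracket Search bracket for \eqn{\lambda}; defaults to
#'   `c(0, 0.49)` for SQ (the admissibility bound for Gaussian-tailed
#'   posteriors is \eqn{\lambda < 1/2}) and `c(0, 8)` for AB.
#' @param n_nodes Bounded-quadrature nodes (default 64).
#' @return An object of class `"zflag_calibration"`: `lambda_star`,
#'   `weight_kind`, `y_alpha`, `threshold_y`, `achieved_incorrect`,
#'   `achieved_correct`, `feasible`, `exact_boundary`, `bp_incorrect`,
#'   `bp_correct`, `tau`, `alpha`.
#' @examples
#' ctx <- zpredictor("bernoulli_logit", sigma_u = 0.6, n = 100, mu = -1)
#' calibrate(ctx, "AB", tau = 1.28, alpha = 0.1)
#' @export
calibrate <- function(object, weight_kind = c("AB", "SQ"), tau, alpha,
                      lambda_bracket = NULL, n_nodes = 64L) {
  stopifnot(inherits(object, "zpredictor"))
  weight_kind <- match.arg(weight_kind)
  if (is.null(lambda_bracket))
    lambda_bracket <- if (weight_kind == "SQ") c(0, 0.49) else c(0, 8)
  if (length(lambda_bracket) != 2L || lambda_bracket[1] < 0 ||
      diff(lambda_bracket) <= 0)
    stop("'lambda_bracket' must be an increasing non-negative pair")
  tailp <- make_tailp(object, tau, n_nodes)
  bp <- set_weight(object, weight_spec("BP"))
  thr_bp <- invert_threshold(bp, tau)
  calibrate_core(object, weight_kind, tau, alpha, lambda_bracket, n_nodes,
                 tailp, thr_bp)
}

## Core calibration given the shared conditional tail function and the BP
## threshold (the grid engine reuses these across predictors).
##
## Feasibility requires two things. First, the BP rule must not already
## exceed alpha: weighted predictors shrink less, so every achievable
## weighted threshold sits at or below the BP one and its rate at or above
## the BP rate. Second, the quantile y_alpha must lie strictly inside the
## support: with a bounded, highly discrete total (binary outcomes, small
## n) even the smallest nonempty flag set {Y = n} can have tail
## probability above alpha, in which case y_alpha = n, the calibrated rule
## could only flag the empty set, and no self-calibrated predictor exists.
calibrate_core <- function(object, weight_kind, tau, alpha, lambda_bracket,
                           n_nodes, tailp, thr_bp) {
  bp_rates <- flag_rates(set_weight(object, weight_spec("BP")), tau,
                         threshold = thr_bp, n_nodes = n_nodes)
  y_alpha <- y_alpha_search(object, tailp, alpha)
  sup_max <- if (object$family$name %in% c("bernoulli_logit", "binomial_logit"))
    object$lp$n else Inf
  feasible <- bp_rates$incorrect <= alpha + 1e-12 && y_alpha < sup_max
  base <- list(weight_kind = weight_kind, y_alpha = y_alpha, tau = tau,
               alpha = alpha, bp_incorrect = bp_rates$incorrect,
               bp_correct = bp_rates$correct)
  if (!feasible) {
    return(structure(c(list(
      lambda_star = NA_real_, threshold_y = thr_bp,
      achieved_incorrect = bp_rates$incorrect,
      achieved_correct = bp_rates$correct,
      feasible = FALSE, exact_boundary = FALSE), base),
      class = "zflag_calibration"))
  }
  ## z-tilde at a count, as a function of lambda; a diverging weighted
  ## integral means the predictor has escaped upward past any threshold
  zt <- function(lambda, y) {
    ctx <- set_weight(object, weight_spec(weight_kind, lambda))
    tryCatch(predict(ctx, y), error = function(e) 1e6)
  }
  lam_max <- lambda_bracket[2]
  g <- function(lambda) zt(lambda, y_alpha + 1) - tau   # want >= 0
  inv_at <- function(lambda) tryCatch(
    invert_threshold(set_weight(object, weight_spec(weight_kind, lambda)), tau),
    error = function(e) NA_real_)
  ## z-tilde need not be monotone in lambda (the absolute weight can tip
  ## posterior mass into the negative tail at extreme lambda), so locate a
  ## sign change of g on a coarse grid first; at ANY root of g the
  ## crossing sits exactly between y_alpha and y_alpha + 1 because the
  ## predictor is monotone in the total at fixed lambda
  grid_l <- seq(lambda_bracket[1], lam_max, length.out = 9L)
  gv <- vapply(grid_l, g, numeric(1))
  exact <- TRUE
  lambda_star <- NA_real_
  thr <- NA_real_
  if (gv[1] >= 0) {
    lambda_star <- grid_l[1]
  } else if (any(gv >= 0)) {
    j <- which(gv >= 0)[1]
    lambda_star <- stats::uniroot(g, grid_l[c(j - 1L, j)], tol = 1e-9)$root
  } else {
    exact <- FALSE
  }
  if (exact) {
    ## nudge minimally upward so the achieved threshold lands on y_alpha
    eps <- (lam_max - lambda_bracket[1]) * 1e-9
    for (i in 1:40) {
      thr <- inv_at(lambda_star)
      if (isTRUE(thr == y_alpha) || isTRUE(thr < y_alpha)) break
      lambda_star <- lambda_star + eps
      eps <- eps * 2
      if (lambda_star > lam_max) break
    }
    exact <- isTRUE(thr == y_alpha)
  }
  if (!exact) {
    ## closest achievable fallback: the smallest attainable threshold that
    ## is still at or above y_alpha, i.e. the largest incorrect rate <= alpha
    best <- list(l = 0, th = thr_bp)
    for (l in unique(c(lambda_star, grid_l))) {
      if (is.na(l)) next
      th <- inv_at(l)
      if (!is.na(th) && th >= y_alpha && th < best$th) best <- list(l = l, th = th)
    }
    lambda_star <- best$l
    thr <- best$th
    exact <- isTRUE(thr == y_alpha)
  }
  rates <- flag_rates(object, tau, threshold = thr, n_nodes = n_nodes)
  structure(c(list(
    lambda_star = lambda_star, threshold_y = thr,
    achieved_incorrect = rates$incorrect,
    achieved_correct = rates$correct,
    feasible = TRUE, exact_boundary = exact), base),
    class = "zflag_calibration")
}

#' @export
print.zflag_calibration <- function(x, ...) {
  cat(sprintf("Self-calibrated %s flagging rule (tau = %g, alpha = %g)\n",
              x$weight_kind, x$tau, x$alpha))
  if (!x$feasible) {
    cat(if (x$bp_incorrect > x$alpha)
      sprintf("  infeasible: BP incorrect rate %.4f exceeds alpha\n", x$bp_incorrect)
      else "  infeasible: no nonempty flagging rule attains the nominal rate (y_alpha at the support maximum)\n")
    return(invisible(x))
  }
  cat(sprintf("  lambda* = %.4g, count threshold y = %s (y_alpha = %s%s)\n",
              x$lambda_star, format(x$threshold_y), format(x$y_alpha),
              if (x$exact_boundary) ", exact" else ", closest achievable"))
  cat(sprintf("  incorrect rate %.4f (BP: %.4f), correct rate %.4f (BP: %.4f)\n",
              x$achieved_incorrect, x$bp_incorrect,
              x$achieved_correct, x$bp_correct))
  invisible(x)
}

#' Flag clusters as extreme
#'
#' Applies the simple rule: flag when the predicted random effect exceeds
#' \eqn{\tau}, i.e. \eqn{\tilde z_w(Y_\cdot) > \tau} (strict). By
#' monotonicity this coincides with \eqn{Y_\cdot > y_{\cdot,\tau}}.
#'
#' @param object A [zpredictor()] object.
#' @param tau Flagging threshold.
#' @param y_total Cluster total(s).
#' @return Logical vector of flag decisions.
#' @export
flag <- function(object, tau, y_total) {
  predict(object, y_total) > tau
}
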