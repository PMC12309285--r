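#' Conditional mean square error of prediction for extreme random effects
#'
#' Computes \eqn{E[(z - \tilde z_w)^2 \mid z \in T]} exactly by quadrature,
#' where the conditioning tail \eqn{T} is \eqn{z > \tau} (`"upper"`),
#' \eqn{z < \tau} (`"lower"`) or \eqn{|z| > \tau} (`"both"`). For discrete
#' outcomes the double integral reduces to a sum over cluster totals
#' \deqn{\sum_{y_\cdot} \int_T [z - \tilde z_w(y_\cdot)]^2
#'   f(y_\cdot \mid z)\, f(z \mid z \in T)\, dz,}
#' with \eqn{f(z \mid z > \tau) = \phi(z) I_{z>\tau} / [1 - \Phi(\tau)]};
#' the normalizing constant uses the exact normal cdf, not quadrature.
#' `msep()` routes to the closed binomial form (logit link, cluster-level
#' covariates), the truncated Poisson sum (log link), or the generic
#' total-distribution route (Poisson-binomial totals for unit-level
#' covariates, normal totals for the Gaussian family).
#'
#' @param object A [zpredictor()] object (its weight defines \eqn{\tilde z_w}).
#' @param tau Extremeness threshold on the standardized random-effect scale.
#' @param tail Conditioning tail: `"upper"`, `"lower"` or `"both"`.
#' @param n_nodes Nodes for the bounded tail quadrature (default 64).
#' @param predictor Optional function `f(y_total)` overriding the predictor
#'   values (used for diagnostics, e.g. a degenerate constant predictor);
#'   by default `predict(object, y_total)`.
#' @return An object of class `"msep_result"` with elements `msep`, `tau`,
#'   `tail`, `weight`, `truncation_error_bound`.
#' @examples
#' ctx <- zpredictor("bernoulli_logit", sigma_u = 0.8, n = 7, mu = -2,
#'                   weight = weight_spec("AB", 1.6))
#' msep(ctx, tau = 1.28)
#' @export
msep <- function(object, tau, tail = c("upper", "lower", "both"),
                 n_nodes = 64L, predictor = NULL) {
  stopifnot(inherits(object, "zpredictor"))
  tail <- match.arg(tail)
  fam <- object$family
  if (fam$name %in% c("bernoulli_logit", "binomial_logit") && object$lp$cluster_level)
    msep_binary(object, tau, tail, n_nodes, predictor)
  else if (fam$name == "poisson_log")
    msep_poisson(object, tau, tail, n_nodes, predictor)
  else
    msep_generic(object, tau, tail, n_nodes, predictor)
}

## Tail region(s) and exact normalizer for the conditioning event.
tail_region <- function(tau, tail, n_nodes) {
  switch(
    tail,
    upper = list(rules = list(quad_rule(tau, Inf, n_nodes)),
                 norm = stats::pnorm(tau, lower.tail = FALSE)),
    lower = list(rules = list(quad_rule(-Inf, tau, n_nodes)),
                 norm = stats::pnorm(tau)),
    both = {
      if (tau <= 0) stop("two-sided conditioning |z| > tau requires tau > 0")
      list(rules = list(quad_rule(-Inf, -tau, n_nodes),
                        quad_rule(tau, Inf, n_nodes)),
           norm = 2 * stats::pnorm(tau, lower.tail = FALSE))
    }
  )
}

## Shared reduction: given z nodes/weights on the tail, a support vector,
## a log-pmf matrix [support x nodes] and predictor values over the support,
## return sum_k sum_q w_q (z_q - zt_k)^2 pmf[k, q] / norm.
msep_reduce <- function(z, w, support, log_pmf, zt, norm) {
  D <- outer(zt, z, function(a, b) (b - a)^2)
  sum(t(w * t(exp(log_pmf) * D))) / norm
}

msep_result <- function(msep, tau, tail, weight, trunc_bound = 0) {
  structure(list(msep = msep, tau = tau, tail = tail, weight = weight,
                 truncation_error_bound = trunc_bound),
            class = "msep_result")
}

#' @export
print.msep_result <- function(x, ...) {
  lab <- switch(x$tail, upper = "z > tau", lower = "z < tau", both = "|z| > tau")
  cat(sprintf("MSEP conditional on %s (tau = %g): %.6g\n", lab, x$tau, x$msep))
  cat(sprintf("  predictor: %s%s\n", x$weight$kind,
              if (x$weight$kind == "BP") "" else sprintf(" (lambda = %g)", x$weight$lambda)))
  if (x$truncation_error_bound > 0)
    cat(sprintf("  support truncation error bound: %.2g\n", x$truncation_error_bound))
  invisible(x)
}

#' @rdname msep
#' @export
msep_binary <- function(object, tau, tail = c("upper", "lower", "both"),
                        n_nodes = 64L, predictor = NULL) {
  tail <- match.arg(tail)
  fam <- object$family
  lp <- object$lp
  if (!fam$name %in% c("bernoulli_logit", "binomial_logit"))
    stop("msep_binary requires a logit-link binary family")
  if (!lp$cluster_level) return(msep_generic(object, tau, tail, n_nodes, predictor))
  reg <- tail_region(tau, tail, n_nodes)
  support <- 0:lp$n
  zt <- if (is.null(predictor)) predict(object, support) else predictor(support)
  total <- 0
  for (r in reg$rules) {
    z <- r$nodes
    eta <- lp$xb[1L] + lp$sigma_u * z
    log_pmf <- lchoose(lp$n, support) + outer(support, eta) -
      matrix(lp$n * log1pexp(eta), length(support), length(z), byrow = TRUE)
    total <- total + msep_reduce(z, exp(r$logw), support, log_pmf, zt, reg$norm)
  }
  msep_result(total, tau, tail, object$weight)
}

#' @rdname msep
#' @export
msep_poisson <- function(object, tau, tail = c("upper", "lower", "both"),
                         n_nodes = 64L, predictor = NULL) {
  tail <- match.arg(tail)
  fam <- object$family
  lp <- object$lp
  if (fam$name != "poisson_log") stop("msep_poisson requires the poisson_log family")
  reg <- tail_region(tau, tail, n_nodes)
  S <- sum(exp(lp$xb))
  zmax <- max(vapply(reg$rules, function(r) max(r$nodes), numeric(1)))
  K <- poisson_truncation(S * exp(lp$sigma_u * zmax), 1e-14)
  support <- 0:K
  zt <- if (is.null(predictor)) predict(object, support) else predictor(support)
  total <- 0
  bound <- 0
  for (r in reg$rules) {
    z <- r$nodes
    nu <- S * exp(lp$sigma_u * z)
    log_pmf <- outer(support, log(nu)) -
      matrix(nu, length(support), length(z), byrow = TRUE) - lgamma(support + 1)
    total <- total + msep_reduce(z, exp(r$logw), support, log_pmf, zt, reg$norm)
    tailmass <- sum(exp(r$logw) * stats::ppois(K, nu, lower.tail = FALSE))
    bound <- bound + tailmass * (max(abs(z)) + max(abs(zt)))^2 / reg$norm
  }
  if (bound > 1e-10)
    stop(sprintf("Poisson support truncation error bound %.3g exceeds 1e-10", bound))
  msep_result(total, tau, tail, object$weight, trunc_bound = bound)
}

#' @rdname msep
#' @param total_fn Optional function `f(z)` returning a
#'   [total_distribution()] for the cluster total at random effect `z`;
#'   defaults to the family's own exact total. Only used by `msep_generic`.
#' @export
msep_generic <- function(object, tau, tail = c("upper", "lower", "both"),
                         n_nodes = 64L, predictor = NULL, total_fn = NULL) {
  tail <- match.arg(tail)
  fam <- object$family
  lp <- object$lp
  reg <- tail_region(tau, tail, n_nodes)
  if (fam$support == "continuous")
    return(msep_gaussian(object, reg, tau, tail, predictor))
  if (is.null(total_fn)) {
    args <- list(family = fam, sigma_u = lp$sigma_u)
    if (lp$cluster_level) { args$n <- lp$n; args$mu <- lp$xb[1L] }
    else { args$X <- matrix(lp$xb, ncol = 1L); args$beta <- 1 }
    total_fn <- function(z) do.call(total_distribution, c(args, list(z = z)))
  }
  zmax <- max(vapply(reg$rules, function(r) max(r$nodes), numeric(1)))
  K <- length(total_fn(zmax)$support) - 1L
  support <- 0:K
  zt <- if (is.null(predictor)) predict(object, support) else predictor(support)
  total <- 0
  for (r in reg$rules) {
    z <- r$nodes
    pmf <- vapply(z, function(zi) {
      p <- total_fn(zi)$pmf
      if (length(p) >= K + 1L) p[seq_len(K + 1L)]
      else c(p, rep(0, K + 1L - length(p)))
    }, numeric(K + 1L))
    log_pmf <- log(pmf)
    log_pmf[pmf == 0] <- -Inf
    total <- total + msep_reduce(z, exp(r$logw), support, log_pmf, zt, reg$norm)
  }
  msep_result(total, tau, tail, object$weight)
}

## Gaussian-total branch: inner expectation over the continuous total by
## Gauss-Hermite in y around its conditional mean.
msep_gaussian <- function(object, reg, tau, tail, predictor, n_y = 50L) {
  lp <- object$lp
  m0 <- sum(lp$xb)
  s <- sqrt(lp$n / object$family$gamma)
  gh <- pracma::gaussHermite(n_y)
  zt_fun <- if (is.null(predictor)) function(y) predict(object, y) else predictor
  total <- 0
  for (r in reg$rules) {
    z <- r$nodes
    ## y nodes for each z: m(z) + sqrt(2) s t_j
    Y <- outer(m0 + lp$n * lp$sigma_u * z, sqrt(2) * s * gh$x, `+`)
    ZT <- matrix(zt_fun(as.vector(Y)), nrow = length(z))
    inner <- as.vector(((z - ZT)^2 %*% gh$w) / sqrt(pi))
    total <- total + sum(exp(r$logw) * inner) / reg$norm
  }
  msep_result(total, tau, tail, object$weight)
}

#' Difference in conditional MSEP between a weighted and the best predictor
#'
#' Convenience wrapper computing `msep(weighted) - msep(best predictor)` on
#' the identical family and cluster scenario; negative values mean the
#' weighted predictor is more accurate for extreme random effects.
#'
#' @param object A [zpredictor()] with a weighted (`SQ`/`AB`) weight.
#' @param object_bp Optional best-predictor counterpart; defaults to
#'   `object` with the BP weight. Must share family and linear predictor.
#' @inheritParams msep
#' @return Numeric difference in MSEP.
#' @export
msep_difference <- function(object, object_bp = NULL, tau,
                            tail = c("upper", "lower", "both"), n_nodes = 64L) {
  tail <- match.arg(tail)
  if (is.null(object_bp)) object_bp <- set_weight(object, weight_spec("BP"))
  if (!identical(object$family$name, object_bp$family$name) ||
      !identical(object$lp[c("sigma_u", "n", "xb")],
                 object_bp$lp[c("sigma_u", "n", "xb")]))
    stop("the two predictors must share family and cluster scenario")
  msep(object, tau, tail, n_nodes)$msep - msep(object_bp, tau, tail, n_nodes)$msep
}
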