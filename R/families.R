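#' Canonical-link GLMM family specifications
#'
#' A family object collects the ingredients of a canonical-link generalized
#' linear mixed model for clustered outcomes: the cumulant function
#' \eqn{a(\eta)} of the exponential-family density
#' \eqn{f(y \mid z, x) = \exp[\{y\eta - a(\eta)\}\gamma + b(y, \gamma)]},
#' the inverse link \eqn{g^{-1} = a'}, the positive scale \eqn{\gamma}
#' (fixed at 1 for Bernoulli and Poisson), and the support of the outcome.
#' The cluster-total distribution induced by each family is what the
#' prediction and flagging machinery consumes; see [total_distribution()].
#'
#' Supported families: `"bernoulli_logit"`, `"binomial_logit"` (identical
#' mathematics, unit rows vs. grouped counts), `"poisson_log"`, and
#' `"gaussian_identity"`. Gamma outcomes are not implemented.
#'
#' @param name Family name, one of the four above.
#' @param gamma Positive scale factor; for Gaussian outcomes this is the
#'   reciprocal unit-level error variance \eqn{1/\sigma_e^2}. Must be 1 for
#'   Bernoulli/binomial and Poisson families.
#' @return An object of class `"glmm_family"` with elements `name`,
#'   `cumulant` (\eqn{a}), `inv_link` (\eqn{g^{-1}}), `gamma`, `support`
#'   (`"discrete"` or `"continuous"`).
#' @examples
#' fam <- glmm_family("bernoulli_logit")
#' fam$inv_link(0)  # 0.5
#' @export
glmm_family <- function(name = c("bernoulli_logit", "binomial_logit",
                                 "poisson_log", "gaussian_identity"),
                        gamma = 1) {
  name <- match.arg(name)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a positive scalar")
  spec <- switch(
    name,
    bernoulli_logit = ,
    binomial_logit = list(
      cumulant = log1pexp,
      inv_link = stats::plogis,
      support = "discrete",
      fixed_gamma = TRUE
    ),
    poisson_log = list(
      cumulant = exp,
      inv_link = exp,
      support = "discrete",
      fixed_gamma = TRUE
    ),
    gaussian_identity = list(
      cumulant = function(eta) eta^2 / 2,
      inv_link = identity,
      support = "continuous",
      fixed_gamma = FALSE
    )
  )
  if (spec$fixed_gamma && gamma != 1)
    stop(sprintf("family '%s' has fixed scale gamma = 1", name))
  structure(
    list(name = name, cumulant = spec$cumulant, inv_link = spec$inv_link,
         gamma = gamma, support = spec$support),
    class = "glmm_family"
  )
}

#' @export
print.glmm_family <- function(x, ...) {
  cat(sprintf("GLMM family: %s (gamma = %g, %s outcome)\n",
              x$name, x$gamma, x$support))
  invisible(x)
}

## ---- linear predictor specification -------------------------------------

## Internal container for the cluster linear predictor eta_j(z) =
## sigma_u z + x_j' beta. Either an intercept `mu` with cluster size `n`
## (cluster-level covariates absorbed into mu), or a covariate matrix X with
## coefficient vector beta (one row per unit). `xb` holds the fixed part
## x_j' beta for each unit; `cluster_level` records whether all units share
## the same fixed part, in which case closed-form totals apply.
lp_spec <- function(sigma_u, n = NULL, mu = NULL, beta = NULL, X = NULL) {
  if (!is.numeric(sigma_u) || length(sigma_u) != 1L || is.na(sigma_u) || sigma_u < 0)
    stop("'sigma_u' must be a non-negative scalar")
  if (!is.null(mu)) {
    if (!is.null(beta) || !is.null(X))
      stop("give either 'mu' (with 'n') or 'beta' with 'X', not both")
    if (is.null(n) || n < 1) stop("'n' (cluster size >= 1) is required with 'mu'")
    n <- as.integer(n)
    xb <- rep(as.numeric(mu), n)
  } else {
    if (is.null(beta) || is.null(X)) stop("either 'mu' or both 'beta' and 'X' are required")
    X <- as.matrix(X)
    beta <- as.numeric(beta)
    if (ncol(X) != length(beta))
      stop(sprintf("dimension mismatch: X has %d columns, beta has length %d",
                   ncol(X), length(beta)))
    if (!is.null(n) && n != nrow(X)) stop("'n' disagrees with nrow(X)")
    n <- nrow(X)
    xb <- drop(X %*% beta)
  }
  list(sigma_u = sigma_u, n = n, xb = xb,
       cluster_level = (n == 1L) || (max(xb) - min(xb) < 1e-12))
}

## Sum of cumulants over units, vectorized over z: sum_j a(sigma_u z + xb_j).
## Closed forms per family avoid the O(n * n_nodes) outer product when
## possible.
sum_cumulant <- function(family, lp, z) {
  s <- lp$sigma_u * z
  switch(
    family$name,
    bernoulli_logit = ,
    binomial_logit = {
      if (lp$cluster_level) lp$n * log1pexp(lp$xb[1L] + s)
      else rowSums(log1pexp(outer(s, lp$xb, `+`)))
    },
    poisson_log = sum(exp(lp$xb)) * exp(s),
    gaussian_identity = (lp$n * s^2 + 2 * s * sum(lp$xb) + sum(lp$xb^2)) / 2
  )
}

## ---- exact total distributions ------------------------------------------

#' Binomial probability of a cluster total given the random effect
#'
#' With a logit link and cluster-level covariates only, the cluster total
#' \eqn{Y_\cdot} given the standardized random effect \eqn{z} is binomial:
#' \deqn{f(y_\cdot \mid z) = \binom{n}{y_\cdot}
#'   \exp\{y_\cdot(\mu + \sigma_u z) - n\log(1 + e^{\mu + \sigma_u z})\}.}
#' Computed in log space with a log-gamma binomial coefficient.
#'
#' @param k Count(s) in `0..n`.
#' @param n Cluster size.
#' @param mu Cluster-level linear predictor (intercept plus covariate terms).
#' @param sigma_u Random-effect scale, non-negative.
#' @param z Standardized random effect (scalar).
#' @return Probabilities, one per element of `k`.
#' @examples
#' binomial_total_pmf(1, n = 1, mu = 0, sigma_u = 1, z = 0)  # 0.5
#' @export
binomial_total_pmf <- function(k, n, mu, sigma_u, z) {
  if (any(k < 0 | k > n | k != floor(k)))
    stop(sprintf("'k' must be an integer in [0, %d]", as.integer(n)))
  eta <- mu + sigma_u * z
  exp(lchoose(n, k) + k * eta - n * log1pexp(eta))
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of a sum of independent, non-identically distributed
#' Bernoulli variables, which the cluster total follows under a logit link
#' with unit-level covariates. Computed by the exact dynamic-programming
#' convolution (O(n^2)); Hong (2013) gives an equivalent closed form via the
#' discrete Fourier transform of the characteristic function.
#'
#' @param probs Vector of per-unit success probabilities in `[0, 1]`.
#' @return The pmf over counts `0..length(probs)` (length `n + 1`).
#' @examples
#' poisson_binomial_pmf(c(0.2, 0.7))
#' @references Hong, Y. (2013). On computing the distribution function for
#'   the Poisson binomial distribution. Computational Statistics & Data
#'   Analysis 59, 41-51.
#' @export
poisson_binomial_pmf <- function(probs) {
  if (length(probs) == 0L) stop("'probs' must be non-empty")
  if (any(!is.finite(probs) | probs < 0 | probs > 1))
    stop("'probs' must lie in [0, 1]")
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

#' Mean of a Poisson cluster total
#'
#' Under a log link the units are conditionally Poisson with means
#' \eqn{\nu_j = \exp(x_j'\beta + \sigma_u z)}, so the cluster total is
#' Poisson with mean \eqn{\nu_\cdot = \sum_j \exp(x_j'\beta + \sigma_u z)}.
#'
#' @param X Unit-level covariate matrix (n x p).
#' @param beta Coefficient vector (length p).
#' @param sigma_u Random-effect scale.
#' @param z Standardized random effect (may be a vector).
#' @return \eqn{\nu_\cdot}, one value per element of `z`.
#' @export
poisson_total_mean <- function(X, beta, sigma_u, z) {
  X <- as.matrix(X)
  beta <- as.numeric(beta)
  if (ncol(X) != length(beta))
    stop(sprintf("dimension mismatch: X has %d columns, beta has length %d",
                 ncol(X), length(beta)))
  sum(exp(drop(X %*% beta))) * exp(sigma_u * z)
}

#' Distribution of the cluster total given the random effect
#'
#' Dispatches to the family's exact total distribution: binomial for the
#' logit link with cluster-level covariates, Poisson-binomial for the logit
#' link with unit-level covariates, Poisson for the log link (support
#' truncated where the upper-tail mass falls below `truncation_tolerance`),
#' and normal for the Gaussian identity-link family (total mean
#' \eqn{\sum_j x_j'\beta + n\sigma_u z}, variance \eqn{n/\gamma}).
#'
#' @param family A [glmm_family()] object.
#' @param sigma_u,n,mu,beta,X Linear predictor specification: either an
#'   intercept `mu` with cluster size `n`, or unit-level `X` and `beta`.
#' @param z Standardized random effect (scalar).
#' @param truncation_tolerance Upper-tail mass allowed beyond the truncated
#'   Poisson support.
#' @return An object of class `"total_distribution"`: for discrete families
#'   a list with integer `support`, `pmf` (vector over the support), `cdf`
#'   (function of counts), and `truncation_tolerance`; for the Gaussian
#'   family `mean`, `sd` and `pdf`/`cdf` functions.
#' @examples
#' td <- total_distribution(glmm_family("bernoulli_logit"), sigma_u = 0.5,
#'                          n = 5, mu = -1, z = 1)
#' sum(td$pmf)  # 1
#' @export
total_distribution <- function(family, sigma_u, n = NULL, mu = NULL,
                               beta = NULL, X = NULL, z,
                               truncation_tolerance = 1e-12) {
  stopifnot(inherits(family, "glmm_family"))
  lp <- lp_spec(sigma_u, n = n, mu = mu, beta = beta, X = X)
  out <- switch(
    family$name,
    bernoulli_logit = ,
    binomial_logit = {
      if (lp$cluster_level) {
        support <- 0:lp$n
        pmf <- binomial_total_pmf(support, lp$n, lp$xb[1L], lp$sigma_u, z)
      } else {
        support <- 0:lp$n
        pmf <- poisson_binomial_pmf(stats::plogis(lp$sigma_u * z + lp$xb))
      }
      list(support = support, pmf = pmf,
           cdf = local({
             cp <- cumsum(pmf); nn <- lp$n
             function(y) {
               y <- floor(y)
               ifelse(y < 0, 0, cp[pmin(y, nn) + 1L])
             }
           }))
    },
    poisson_log = {
      nu <- sum(exp(lp$xb + lp$sigma_u * z))
      K <- poisson_truncation(nu, truncation_tolerance)
      support <- 0:K
      list(support = support, pmf = stats::dpois(support, nu),
           cdf = function(y) stats::ppois(floor(y), nu))
    },
    gaussian_identity = {
      m <- sum(lp$xb) + lp$n * lp$sigma_u * z
      s <- sqrt(lp$n / family$gamma)
      list(mean = m, sd = s,
           pdf = function(y) stats::dnorm(y, m, s),
           cdf = function(y) stats::pnorm(y, m, s))
    },
    stop(sprintf("family '%s' is not implemented", family$name))
  )
  out$family <- family$name
  out$truncation_tolerance <- truncation_tolerance
  structure(out, class = "total_distribution")
}

## Smallest K with Poisson upper-tail mass beyond K below tol.
poisson_truncation <- function(nu, tol = 1e-12, cap = 2e6) {
  K <- suppressWarnings(stats::qpois(tol, nu, lower.tail = FALSE))
  if (!is.finite(K) || K >= cap)
    stop(sprintf("Poisson support truncation not attainable below the cap %g (mean %g)",
                 cap, nu))
  while (stats::ppois(K, nu, lower.tail = FALSE) > tol && K < cap) K <- K + 10L
  if (stats::ppois(K, nu, lower.tail = FALSE) > tol)
    stop(sprintf("Poisson support truncation could not attain tolerance %g (mean %g); attained %g",
                 tol, nu, stats::ppois(K, nu, lower.tail = FALSE)))
  as.integer(K)
}

## Conditional cdf F(y | z) of the cluster total, vectorized over a vector
## of z values (the quadrature nodes). `y` is a scalar threshold; Inf and
## below-support values are handled (cdf 1 and 0). Used by the flagging
## rates and self-calibration quantile.
total_cdf_z <- function(family, lp, y, z) {
  if (is.infinite(y)) return(rep(if (y > 0) 1 else 0, length(z)))
  switch(
    family$name,
    bernoulli_logit = ,
    binomial_logit = {
      if (lp$cluster_level) {
        stats::pbinom(y, lp$n, stats::plogis(lp$xb[1L] + lp$sigma_u * z))
      } else {
        vapply(z, function(zi) {
          pmf <- poisson_binomial_pmf(stats::plogis(lp$sigma_u * zi + lp$xb))
          if (y < 0) 0 else sum(pmf[seq_len(min(floor(y), lp$n) + 1L)])
        }, numeric(1))
      }
    },
    poisson_log = stats::ppois(y, sum(exp(lp$xb)) * exp(lp$sigma_u * z)),
    gaussian_identity = stats::pnorm(y, sum(lp$xb) + lp$n * lp$sigma_u * z,
                                     sqrt(lp$n / family$gamma))
  )
}
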