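#' Gauss-Hermite-type quadrature rules against the standard normal density
#'
#' Builds a rule for integrals of the form \eqn{\int_a^b f(z)\phi(z)\,dz},
#' where \eqn{\phi} is the standard normal density. A doubly infinite range
#' uses classical Gauss-Hermite quadrature with the change of variable
#' \eqn{z = \sqrt{2}\,t}; any finite or half-infinite range uses
#' Gauss-Legendre nodes on the (clipped) interval with \eqn{\phi(z)} folded
#' into the weights, the standard construction for bounded Gauss-Hermite
#' integration. Effectively infinite endpoints are clipped at \eqn{\pm 8}
#' (standard-normal mass beyond is below 1e-15).
#'
#' @param lower,upper Integration limits; may be infinite. `lower < upper`.
#' @param n_nodes Number of nodes (at least 2). Defaults: 50 for the
#'   unbounded rule, 64 for bounded rules (see [zpredictor()]).
#' @return An object of class `"quad_rule"`: a list with `nodes`, `logw`
#'   (log weights, normal density included), `lower`, `upper`, `n_nodes`.
#' @examples
#' r <- quad_rule(-Inf, 1.28, 64)
#' quad_int(r, function(z) rep(1, length(z)))  # ~ pnorm(1.28)
#' @export
quad_rule <- function(lower = -Inf, upper = Inf, n_nodes = 50L) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L ||
      length(upper) != 1L || is.na(lower) || is.na(upper) || lower >= upper)
    stop("'lower' must be strictly less than 'upper'")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("'n_nodes' must be at least 2")
  if (is.infinite(lower) && is.infinite(upper)) {
    gh <- pracma::gaussHermite(n_nodes)
    nodes <- sqrt(2) * gh$x
    logw <- log(gh$w) - 0.5 * log(pi)
  } else {
    lo <- max(lower, -8)
    hi <- min(upper, 8)
    if (lo >= hi) stop("'lower' must be strictly less than 'upper' after clipping at +/-8")
    gl <- pracma::gaussLegendre(n_nodes, lo, hi)
    nodes <- gl$x
    logw <- log(gl$w) + stats::dnorm(gl$x, log = TRUE)
  }
  structure(
    list(nodes = nodes, logw = logw, lower = lower, upper = upper,
         n_nodes = n_nodes),
    class = "quad_rule"
  )
}

#' @export
print.quad_rule <- function(x, ...) {
  cat(sprintf("Quadrature rule against phi(z) on (%s, %s), %d nodes\n",
              format(x$lower), format(x$upper), x$n_nodes))
  invisible(x)
}

#' Integrate a function against the standard normal density
#'
#' Evaluates \eqn{\sum_i w_i f(z_i)} for a rule from [quad_rule()]. With
#' `log = TRUE` the integrand must return log values and the log of the
#' integral is returned, accumulated with a stable log-sum-exp.
#'
#' @param rule A `"quad_rule"` object.
#' @param f Vectorized integrand `f(z)`; must be finite at every node
#'   (or return finite log values, `-Inf` allowed, when `log = TRUE`).
#' @param log Logical; operate in log space.
#' @return The integral \eqn{\int f(z)\phi(z)dz} over the rule's range
#'   (its log when `log = TRUE`).
#' @examples
#' quad_int(quad_rule(), function(z) z^2)  # variance of N(0,1): 1
#' @export
quad_int <- function(rule, f, log = FALSE) {
  stopifnot(inherits(rule, "quad_rule"))
  fv <- f(rule$nodes)
  if (length(fv) != length(rule$nodes))
    stop("integrand must return one value per node")
  bad <- if (log) is.na(fv) | fv == Inf else !is.finite(fv)
  if (any(bad))
    stop(sprintf("integrand not finite at node(s) %s (z = %s)",
                 paste(which(bad), collapse = ", "),
                 paste(signif(rule$nodes[bad], 4), collapse = ", ")))
  if (log) logsumexp(rule$logw + fv) else sum(exp(rule$logw) * fv)
}

## numerically stable log(sum(exp(x))); -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## rowwise logsumexp for a matrix of log terms
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  fin <- is.finite(mx)
  out <- mx
  out[fin] <- mx[fin] + log(rowSums(exp(m[fin, , drop = FALSE] - mx[fin])))
  out
}

## log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  lo <- x <= 37
  out[lo] <- log1p(exp(x[lo]))
  out
}
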