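## Independent closed-form and brute-force oracles used across test files.
## These never call the package's quadrature path for the quantity they
## check.

## Conjugate-normal posterior of z given the cluster total for the
## Gaussian identity-link family: precision 1 + gamma n sigma^2,
## mean v * gamma * sigma * (y - n mu).
gauss_posterior <- function(y, gamma, n, mu, sigma) {
  v <- 1 / (1 + gamma * n * sigma^2)
  list(m = v * gamma * sigma * (y - n * mu), v = v)
}

## Closed-form square-weighted predictor for a N(m, v) posterior:
## exp(lambda z^2) tilts to N(m', v') with 1/v' = 1/v - 2 lambda.
sq_weighted_normal <- function(m, v, lambda) {
  vp <- 1 / (1 / v - 2 * lambda)
  m / v * vp
}

## Closed-form absolute-weighted predictor for a N(m, v) posterior:
## split exp(lambda |z|) at zero; each half is a tilted normal truncated
## to a half line, with mass and mean available from Phi and phi.
ab_weighted_normal <- function(m, v, lambda) {
  s <- sqrt(v)
  mp <- m + lambda * v
  mm <- m - lambda * v
  wp <- exp(m * lambda + lambda^2 * v / 2)
  wm <- exp(-m * lambda + lambda^2 * v / 2)
  Zp <- wp * pnorm(mp / s)
  Zm <- wm * pnorm(-mm / s)
  Ep <- wp * (mp * pnorm(mp / s) + s * dnorm(mp / s))
  Em <- wm * (mm * pnorm(-mm / s) - s * dnorm(mm / s))
  (Ep + Em) / (Zp + Zm)
}

## Hazard (inverse Mills ratio) of the standard normal upper tail.
mills <- function(tau) dnorm(tau) / pnorm(tau, lower.tail = FALSE)

## E[(z - c)^2 | z > tau] for standard normal z: second moment
## 1 + tau * h(tau) minus cross terms, with E[z | z > tau] = h(tau).
truncnorm_mse <- function(c, tau) {
  h <- mills(tau)
  1 + tau * h - 2 * c * h + c^2
}

## Fine-trapezoid integral of f(z) phi(z) over [lo, hi]; deliberately
## naive (independent of the package quadrature).
riemann_phi <- function(f, lo, hi, step = 1e-4) {
  z <- seq(lo, hi, by = step)
  v <- f(z) * dnorm(z)
  step * (sum(v) - (v[1] + v[length(v)]) / 2)
}

## Draws from the standard normal truncated to z > tau (or z < tau).
rtrunc_norm <- function(n, tau, upper = TRUE) {
  u <- runif(n)
  if (upper) qnorm(pnorm(tau) + u * pnorm(tau, lower.tail = FALSE))
  else qnorm(u * pnorm(tau))
}
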