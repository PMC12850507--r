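# Independent brute-force oracles used to check the model-fitting routines.
# These deliberately share no code with the implementation paths they test.

# NB log-likelihood for log(mu) = b0 + b1*group + log(n)
nb_loglik <- function(par, k, n, group, theta) {
  mu <- exp(par[1] + par[2] * group + log(n))
  sum(dnbinom(k, size = theta, mu = mu, log = TRUE))
}

# Profile-likelihood grid/refine search over theta, maximizing (b0, b1) by
# direct optimization at each theta.
nb_profile_oracle <- function(k, n, group,
                              theta_grid = 10^seq(-3, 6, length.out = 120)) {
  prof <- function(theta) {
    start <- c(log(sum(k[group == 0]) / sum(n[group == 0]) + 1e-6),
               log((sum(k[group == 1]) / sum(n[group == 1]) + 1e-6) /
                     (sum(k[group == 0]) / sum(n[group == 0]) + 1e-6)))
    opt <- optim(start, nb_loglik, k = k, n = n, group = group,
                 theta = theta, control = list(fnscale = -1, maxit = 2000,
                                               reltol = 1e-12))
    list(ll = opt$value, beta = opt$par)
  }
  ll <- vapply(theta_grid, function(t) prof(t)$ll, numeric(1))
  i <- which.max(ll)
  lo <- theta_grid[max(i - 1L, 1L)]
  hi <- theta_grid[min(i + 1L, length(theta_grid))]
  ref <- optimize(function(lt) prof(exp(lt))$ll, c(log(lo), log(hi)),
                  maximum = TRUE, tol = 1e-10)
  theta <- exp(ref$maximum)
  best <- prof(theta)
  list(beta0 = best$beta[1], beta1 = best$beta[2], theta = theta,
       loglik = best$ll)
}

# Exact two-sided rank-sum p-value by enumeration of all label assignments.
ranksum_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(pooled), nx)
  stats_all <- apply(combs, 2, function(i) sum(r[i]))
  mu <- mean(stats_all)
  # two-sided: as or more extreme in distance from the mean rank sum
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# OLS via the normal equations.
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Logistic MLE by Newton-Raphson on the log-likelihood.
logistic_newton_oracle <- function(X, y, iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    W <- p * (1 - p)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - p))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

# Exact central binomial interval bounds for a pooled fraction check.
binom_interval <- function(p, n, conf = 0.99) {
  a <- (1 - conf) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}
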