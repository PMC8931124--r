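# Independent oracles used across the suite. Each deliberately avoids the
# package's own code paths: grid search instead of the closed-form
# allocation, root finding instead of the threshold formula, factorial
# enumeration instead of the hypergeometric density, quadrature-free
# integration instead of Gauss-Hermite.

# Numeric root of the indifference condition u(x0) = beta delta^k u(xk)
# in delta, bracketed on (1e-6, 1).
oracle_delta_root <- function(x0, xk, k, alpha = 1, beta = 1) {
  f <- function(d) x0^alpha - beta * d^k * xk^alpha
  # the root can exceed 1 when beta < 1; bracket generously
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

# Brute-force maximiser of the CBT objective over a fine token grid.
oracle_grid_tokens <- function(alpha, beta, delta, a_t, a_tk, t_days,
                               k_days, budget = 50, step = 1e-4) {
  n <- seq(0, budget, by = step)
  bias <- if (t_days == 0) beta else 1
  v <- delta^t_days * (n * a_t)^alpha / alpha +
    bias * delta^(t_days + k_days) * ((budget - n) * a_tk)^alpha / alpha
  n[which.max(v)]
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins, probabilities from factorial ratios (lchoose), not dhyper.
oracle_fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
    lchoose(n, r1)
  p <- exp(logp)
  obs <- exp(lchoose(c1, tab[1, 1]) + lchoose(n - c1, r1 - tab[1, 1]) -
               lchoose(n, r1))
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Random-intercept logit log-likelihood by adaptive numeric integration
# (stats::integrate) of each subject's conditional likelihood.
oracle_ri_loglik <- function(dat, beta_fixed, x, sd_u) {
  ll <- 0
  for (sid in unique(dat$subject_id)) {
    i <- dat$subject_id == sid
    eta <- drop(x[i, , drop = FALSE] %*% beta_fixed)
    y <- dat$choice_later[i]
    f <- function(u) {
      sapply(u, function(ui) {
        p <- stats::plogis(eta + ui)
        prod(p^y * (1 - p)^(1 - y)) * stats::dnorm(ui, 0, sd_u)
      })
    }
    ll <- ll + log(stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  ll
}

# Default-moment population used by several property tests.
default_population <- function(n, seed) sample_population(n, seed = seed)
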