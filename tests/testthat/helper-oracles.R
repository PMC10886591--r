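# Independent oracles used across tests. These are deliberately coded from
# first principles (closed forms, normal equations, direct quantiles) and
# never call the package functions they check.

# Grubbs critical value straight from the t quantile.
oracle_grubbs_crit <- function(n, alpha = 0.05) {
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

# One-shot Grubbs decision: index of the value to remove, or NA.
oracle_grubbs_step <- function(x, alpha = 0.05) {
  s <- stats::sd(x)
  if (s == 0) return(NA_integer_)
  dev <- abs(x - mean(x))
  if (max(dev) / s > oracle_grubbs_crit(length(x), alpha)) which.max(dev)
  else NA_integer_
}

# OLS by explicit normal equations.
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)[, 1]

# Rigid-rod turbidity at a single wavelength, re-derived scalar-by-scalar
# (vacuum-wavelength convention, matching the package default).
oracle_tau_single <- function(mu, r_nm, conc, lambda_nm, n_s = 1.333,
                              dndc = 0.186, k2 = (184 / 154) * pi^2) {
  NA_const <- 6.02214076e23
  k1 <- (88 / 15) * pi^3 * n_s * dndc^2 / NA_const
  lam <- lambda_nm * 1e-7
  r <- r_nm * 1e-7
  k1 * conc * mu / lam^3 * (1 - k2 * r^2 / lam^2)
}

# Analytic logistic turbidity curve.
oracle_logistic <- function(times, plateau, rate, lag, baseline = 0) {
  P <- plateau - baseline
  k <- 4 * rate / P
  t0 <- lag + 2 / k
  baseline + P / (1 + exp(-k * (times - t0)))
}

make_logistic_curve <- function(plateau, rate, lag, baseline = 0,
                                t_end = 3600, dt = 15, path = 0.3) {
  times <- seq(0, t_end, by = dt)
  turbidity_curve(times, oracle_logistic(times, plateau, rate, lag, baseline),
                  path)
}
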